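#' Specification of a synthetic benchmark
#'
#' Defines the planted-truth conditions the pipeline is validated against:
#' a 5-feature AHPRR pharmacophore shared by all actives, per-site
#' coordinate jitter, distractor sites, a planted linear activity model on
#' substituent occupancy, and property-matched decoys. Defaults emulate the
#' composition of a hERG blocker panel: actives spanning several log units
#' of Ki (the affinity window runs from ~3.3 nM to 54 uM) and decoys that
#' share the actives' atom-count and class composition but not their site
#' geometry.
#'
#' @param seed Master seed; all generators are pure functions of (spec,
#'   seed).
#' @param n_actives Number of actives (>= 5; default 200).
#' @param n_decoys Number of decoys (default 2000).
#' @param site_jitter_sigma Per-coordinate site jitter, Angstrom
#'   (default 0.3).
#' @param n_distractor_sites Extra non-planted feature sites per molecule
#'   (default 3).
#' @param activity_intercept Baseline pKi (default 6.3).
#' @param activity_coefficients Named-by-position pKi contributions of the
#'   planted substituents (default 8 values spanning -1 to +1.2).
#' @param noise_sigma Gaussian pKi noise (default 0.3).
#' @param ki_range Allowed Ki range in molar units
#'   (default `c(3.3e-9, 5.4e-5)`).
#' @return Object of class `ph_synthspec`.
#' @export
synthetic_spec <- function(seed = 42L, n_actives = 200L, n_decoys = 2000L,
                           site_jitter_sigma = 0.3,
                           n_distractor_sites = 3L,
                           activity_intercept = 6.3,
                           activity_coefficients =
                             c(1.2, -1.0, 0.9, -0.8, 0.7, -0.6, 0.5, -0.4),
                           noise_sigma = 0.3,
                           ki_range = c(3.3e-9, 5.4e-5)) {
  if (n_actives < 5L) stop("n_actives must be >= 5")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  stopifnot(length(ki_range) == 2L, all(ki_range > 0),
            ki_range[1] < ki_range[2])
  structure(list(seed = as.integer(seed), n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 site_jitter_sigma = site_jitter_sigma,
                 n_distractor_sites = as.integer(n_distractor_sites),
                 activity_intercept = activity_intercept,
                 activity_coefficients = activity_coefficients,
                 noise_sigma = noise_sigma, ki_range = ki_range),
            class = "ph_synthspec")
}

.site_kinds <- c("A", "D", "H", "N", "P", "R")
# element standing in for each atom class in serialized point-set molecules
.class_elem <- c(D = "O", H = "C", N = "O", P = "N", W = "O", X = "S")
.kind_class <- c(A = "W", D = "D", H = "H", N = "N", P = "P", R = "H")

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Plant a 5-feature AHPRR hypothesis
#'
#' Draws five feature sites of kinds A, H, P, R, R with all pairwise
#' distances in 3-12 Angstrom and a non-degenerate (non-coplanar) geometry;
#' acceptor and ring sites get random unit direction vectors. Deterministic
#' per seed.
#'
#' @param seed Integer seed.
#' @param tol Matching tolerance stored on the hypothesis (default 2).
#' @return A [ph_hypothesis] labeled `AHPRR`.
#' @export
plant_hypothesis <- function(seed = 42L, tol = 2.0) {
  kinds <- c("A", "H", "P", "R", "R")
  withr::with_seed(as.integer(seed), {
    repeat {
      pts <- matrix(stats::runif(15, 0, 8), 5, 3)
      dd <- stats::dist(pts)
      sv <- svd(sweep(pts, 2, colMeans(pts)))$d
      if (min(dd) >= 3 && max(dd) <= 12 && sv[3] > 0.8) break
    }
    pts <- sweep(pts, 2, colMeans(pts))
    dirs <- matrix(NA_real_, 5, 3)
    for (i in which(kinds %in% c("A", "R"))) {
      v <- stats::rnorm(3); dirs[i, ] <- v / sqrt(sum(v^2))
    }
    sites <- data.frame(kind = kinds, x = pts[, 1], y = pts[, 2],
                        z = pts[, 3], dx = dirs[, 1], dy = dirs[, 2],
                        dz = dirs[, 3], atoms = "")
    ord <- order(sites$kind)
    ph_hypothesis(sites[ord, , drop = FALSE], tol = tol,
                  id = "AHPRR.planted",
                  provenance = sprintf("synthetic planted, seed %d", seed))
  })
}

# deterministic substituent anchors: offset 1.5-2.5 A from planted sites
substituent_anchors <- function(spec, hyp) {
  m <- length(spec$activity_coefficients)
  withr::with_seed(spec$seed + 101L, {
    xyz <- site_coords(hyp$sites)
    anchors <- matrix(0, m, 3)
    cls <- character(m)
    for (j in seq_len(m)) {
      base <- xyz[((j - 1L) %% nrow(xyz)) + 1L, ]
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      anchors[j, ] <- base + v * stats::runif(1, 1.5, 2.5)
      cls[j] <- sample(c("D", "H", "W", "X"), 1)
    }
    list(pos = anchors, class = cls)
  })
}

point_mol <- function(id, positions, classes, ki = NA_real_,
                      set_label = "unlabeled", sites = NULL,
                      substituents = NULL) {
  atoms <- data.frame(elem = unname(.class_elem[classes]),
                      x = positions[, 1], y = positions[, 2],
                      z = positions[, 3], charge = 0L, nh = 0L)
  n <- nrow(atoms)
  bonds <- if (n >= 2L) data.frame(a1 = seq_len(n - 1L),
                                   a2 = seq(2L, n), order = 1L) else NULL
  mol <- phmol(id, atoms, bonds, ki = ki, set_label = set_label,
               sites = sites, atom_class = classes)
  mol$substituents <- substituents
  mol
}

#' Generate synthetic active ligands
#'
#' Each active is a rigid classed point-set molecule carrying the planted
#' hypothesis's five sites jittered by `N(0, site_jitter_sigma^2)` per
#' coordinate, a subset of the planted substituent atoms (each present with
#' probability 1/2; presence drives activity), `n_distractor_sites` random
#' extra sites, and an anchor atom at every site. Every molecule is posed
#' with a random rigid transform so nothing is pre-aligned. Deterministic
#' per spec.
#'
#' @param spec A [synthetic_spec()].
#' @param hyp Optional planted hypothesis (default
#'   `plant_hypothesis(spec$seed)`).
#' @param anchors Planted substituent anchors; part of the ground truth, so
#'   sets of actives drawn for different purposes (training vs screening)
#'   against the same hypothesis must share them.
#' @return List of [phmol] actives with planted `sites`, `atom_class` and
#'   `substituents` fields.
#' @export
generate_actives <- function(spec, hyp = plant_hypothesis(spec$seed),
                             anchors = substituent_anchors(spec, hyp)) {
  anch <- anchors
  hxyz <- site_coords(hyp$sites)
  hkinds <- hyp$sites$kind
  m <- length(spec$activity_coefficients)
  withr::with_seed(spec$seed + 202L, {
    lapply(seq_len(spec$n_actives), function(i) {
      id <- sprintf("act_%04d", i)
      jit <- matrix(stats::rnorm(15, 0, spec$site_jitter_sigma), 5, 3)
      sxyz <- hxyz + jit
      present <- stats::runif(m) < 0.5
      sub_xyz <- anch$pos[present, , drop = FALSE] +
        matrix(stats::rnorm(3 * sum(present), 0, spec$site_jitter_sigma),
               ncol = 3)
      nd <- spec$n_distractor_sites
      lo <- apply(hxyz, 2, min) - 2; hi <- apply(hxyz, 2, max) + 2
      repeat {
        dis_xyz <- cbind(stats::runif(nd, lo[1], hi[1]),
                         stats::runif(nd, lo[2], hi[2]),
                         stats::runif(nd, lo[3], hi[3]))
        if (nd == 0L || min(as.matrix(stats::dist(rbind(sxyz, dis_xyz)))[
          seq_len(5), 5 + seq_len(nd)]) > 1.5) break
      }
      dis_kinds <- sample(.site_kinds, nd, replace = TRUE)
      pos <- rbind(sxyz, sub_xyz, dis_xyz)
      cls <- c(unname(.kind_class[hkinds]), anch$class[present],
               unname(.kind_class[dis_kinds]))
      site_df <- data.frame(
        kind = c(hkinds, dis_kinds),
        x = c(sxyz[, 1], dis_xyz[, 1]),
        y = c(sxyz[, 2], dis_xyz[, 2]),
        z = c(sxyz[, 3], dis_xyz[, 3]),
        dx = NA_real_, dy = NA_real_, dz = NA_real_, atoms = "")
      # pose randomly: same rigid transform for atoms and sites
      rot <- random_rotation()
      trans <- stats::runif(3, -15, 15)
      pos <- sweep(pos %*% rot, 2, trans, `+`)
      site_df[, c("x", "y", "z")] <-
        sweep(as.matrix(site_df[, c("x", "y", "z")]) %*% rot, 2, trans, `+`)
      point_mol(id, pos, cls, set_label = "active", sites = site_df,
                substituents = present)
    })
  })
}

#' Generate property-matched synthetic decoys
#'
#' Each decoy clones the atom count, class composition and bounding-box
#' extent of one active, but its site geometry is resampled uniformly; a
#' candidate that still matches the planted hypothesis (at the default
#' 4-of-5 sites, 2 Angstrom tolerance) is rejected and redrawn, so at most
#' a vanishing fraction of emitted decoys match. Deterministic per spec.
#'
#' @param spec A [synthetic_spec()].
#' @param hyp Planted hypothesis (default `plant_hypothesis(spec$seed)`).
#' @param actives Optional actives to clone compositions from (default
#'   `generate_actives(spec, hyp)`).
#' @param max_tries Redraws per decoy before accepting (default 25).
#' @return List of [phmol] decoys with ids disjoint from the actives'.
#' @export
generate_decoys <- function(spec, hyp = plant_hypothesis(spec$seed),
                            actives = NULL, max_tries = 25L) {
  if (is.null(actives)) actives <- generate_actives(spec, hyp)
  withr::with_seed(spec$seed + 303L, {
    lapply(seq_len(spec$n_decoys), function(i) {
      id <- sprintf("dec_%05d", i)
      proto <- actives[[((i - 1L) %% length(actives)) + 1L]]
      cls <- proto$atom_class
      kinds <- proto$sites$kind
      ext <- apply(heavy_coords(proto), 2, function(v) diff(range(v)))
      for (try in seq_len(max_tries)) {
        pos <- cbind(stats::runif(length(cls), 0, ext[1]),
                     stats::runif(length(cls), 0, ext[2]),
                     stats::runif(length(cls), 0, ext[3]))
        sxyz <- cbind(stats::runif(length(kinds), 0, ext[1]),
                      stats::runif(length(kinds), 0, ext[2]),
                      stats::runif(length(kinds), 0, ext[3]))
        site_df <- data.frame(kind = kinds, x = sxyz[, 1], y = sxyz[, 2],
                              z = sxyz[, 3], dx = NA_real_, dy = NA_real_,
                              dz = NA_real_, atoms = "")
        cand <- point_mol(id, pos, cls,
                          ki = 10^(-stats::runif(1, ki_to_pki(5.4e-5),
                                                 ki_to_pki(5e-6))),
                          set_label = "decoy", sites = site_df)
        entry <- ligand_entries(list(cand))[[1]]
        # Reject candidates presenting the complete planted pharmacophore.
        # The 0.5 A safety margin makes the no-match property hold not just
        # for the planted geometry but for any hypothesis recovered from
        # jittered actives (recovery error < margin). Partial (<k-site)
        # arrangements are allowed -- as with real property-matched decoys,
        # fragments of the pharmacophore occur by chance; the complete
        # arrangement is what decoys must lack.
        if (is.null(match_ligand(hyp, entry, min_sites = nrow(hyp$sites),
                                 tol = hyp$tol + 0.5))) break
      }
      cand
    })
  })
}

#' Assign planted activities
#'
#' Active pKi is the planted linear model `intercept + sum(coefficients *
#' substituent presence) + N(0, noise_sigma^2)`, clipped to the spec's Ki
#' range; decoys keep their generated inactive Ki (>= 5 uM). Deterministic
#' per spec.
#'
#' @param actives,decoys Molecule lists from the generators.
#' @param spec The [synthetic_spec()].
#' @return List with updated `actives`, `decoys` and a combined `table`
#'   (id, ki, pki, activity_class, set_label, true_signal).
#' @export
assign_activities <- function(actives, decoys, spec) {
  lo <- ki_to_pki(spec$ki_range[2]); hi <- ki_to_pki(spec$ki_range[1])
  withr::with_seed(spec$seed + 404L, {
    actives <- lapply(actives, function(mol) {
      signal <- spec$activity_intercept +
        sum(spec$activity_coefficients[mol$substituents])
      pki <- signal + stats::rnorm(1, 0, spec$noise_sigma)
      pki <- min(max(pki, lo), hi)
      mol$ki <- pki_to_ki(pki)
      mol$pki <- pki
      mol$activity_class <- classify_activity(mol$ki)
      mol$true_signal <- signal
      mol
    })
  })
  tab <- do.call(rbind, lapply(c(actives, decoys), function(m) {
    data.frame(id = m$id, ki = m$ki, pki = m$pki,
               activity_class = m$activity_class, set_label = m$set_label,
               true_signal = if (is.null(m$true_signal)) NA_real_
                             else m$true_signal)
  }))
  list(actives = actives, decoys = decoys, table = tab)
}

#' Build a self-contained synthetic benchmark bundle
#'
#' Generates the planted hypothesis, actives (split 60/40 into train and
#' test), activities and decoys, and optionally writes them to a directory
#' as SDF + CSV + truth JSON consumable by the rest of the pipeline.
#' Deterministic per spec.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory, or `NULL` to skip writing.
#' @param force Overwrite a non-empty directory (default `FALSE`).
#' @return Bundle list: `spec`, `hypothesis`, `actives`, `train`, `test`,
#'   `decoys`, `activity_table`, `anchors`.
#' @export
make_benchmark <- function(spec = synthetic_spec(), dir = NULL,
                           force = FALSE) {
  hyp <- plant_hypothesis(spec$seed)
  actives <- generate_actives(spec, hyp)
  act <- assign_activities(actives,
                           generate_decoys(spec, hyp, actives), spec)
  split <- split_train_test(act$actives, 0.6, seed = spec$seed)
  bundle <- list(spec = spec, hypothesis = hyp,
                 actives = c(split$train, split$test),
                 train = split$train, test = split$test,
                 decoys = act$decoys, activity_table = act$table,
                 anchors = substituent_anchors(spec, hyp))
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) && !force) {
      stop("directory '", dir, "' is not empty (use force = TRUE)")
    }
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_molecules_sdf(bundle$actives, file.path(dir, "actives.sdf"))
    write_molecules_sdf(bundle$decoys, file.path(dir, "decoys.sdf"))
    utils::write.csv(act$table, file.path(dir, "activities.csv"),
                     row.names = FALSE)
    write_hypothesis(hyp, file.path(dir, "hypothesis_truth.json"))
    jsonlite::write_json(
      list(schema = "phore3d-benchmark-truth-1",
           spec = unclass(spec),
           substituent_anchors = bundle$anchors,
           train_ids = vapply(split$train, `[[`, "", "id"),
           test_ids = vapply(split$test, `[[`, "", "id")),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}
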