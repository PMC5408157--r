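#' Pharmacophore hypothesis object
#'
#' A k-feature common pharmacophore: feature sites in a reference frame, the
#' inter-site distance matrix, a per-site matching tolerance and a score.
#' The label is the alphabetically sorted string of site kinds (e.g. a
#' 5-feature acceptor/hydrophobic/positive/ring/ring hypothesis is "AHPRR").
#'
#' @param sites Feature-site data frame (see [perceive_features()]), ordered
#'   canonically (kinds ascending).
#' @param tol Per-site matching tolerance in Angstrom (default 2).
#' @param score Numeric score (see [score_hypothesis()]).
#' @param id Identifier; defaults to `<label>.0`.
#' @param provenance Free-text origin note.
#' @return Object of class `ph_hypothesis` with fields `id`, `label`,
#'   `sites`, `dist` (k x k matrix), `tol`, `score`, `provenance`.
#' @export
ph_hypothesis <- function(sites, tol = 2.0, score = NA_real_, id = NULL,
                          provenance = "") {
  stopifnot(nrow(sites) >= 3L)
  label <- hypothesis_label(sites$kind)
  xyz <- site_coords(sites)
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- NULL
  structure(list(id = if (is.null(id)) paste0(label, ".0") else id,
                 label = label, sites = sites, dist = d, tol = tol,
                 score = score, provenance = provenance),
            class = "ph_hypothesis")
}

#' @export
print.ph_hypothesis <- function(x, ...) {
  cat(sprintf("<ph_hypothesis %s> %d sites, tol %.1f A, score %s\n",
              x$id, nrow(x$sites), x$tol,
              if (is.na(x$score)) "NA" else sprintf("%.3f", x$score)))
  invisible(x)
}

#' Hypothesis label from feature kinds
#' @param kinds Character vector of site kinds.
#' @return Alphabetically sorted kind string, e.g. `"AHPRR"`.
#' @export
hypothesis_label <- function(kinds) paste(sort(kinds), collapse = "")

#' Bundle molecules into ligand entries for matching and hypothesis search
#'
#' Each entry carries, per conformer, the perceived (or planted) feature
#' sites, all-atom coordinates, heavy-atom indices and the conformer's
#' relative energy.
#'
#' @param mols List of [phmol].
#' @param ensembles Optional list of [ph_ensemble] aligned with `mols`;
#'   when omitted each molecule contributes its own single conformer.
#' @return List of ligand entries.
#' @export
ligand_entries <- function(mols, ensembles = NULL) {
  lapply(seq_along(mols), function(i) {
    mol <- mols[[i]]
    confs <- if (is.null(ensembles)) {
      list(list(coords = as.matrix(mol$atoms[, c("x", "y", "z")]),
                rel_energy = 0))
    } else {
      ensembles[[i]]$conformers
    }
    list(molecule_id = mol$id,
         heavy = heavy_index(mol),
         elems = mol$atoms$elem,
         conformers = lapply(confs, function(cf) {
           list(sites = perceive_features(mol, cf$coords),
                coords = cf$coords, energy = cf$rel_energy)
         }))
  })
}

# all permutations of a small vector
.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# canonical ordering of a site subset: kinds ascending, and among orderings
# that tie on kinds the lexicographically smallest inter-site distance
# vector (upper triangle, row-major)
canonical_subset <- function(xyz, kinds) {
  ord <- order(kinds)
  groups <- split(ord, kinds[ord])
  group_perms <- lapply(groups, .perms)
  combos <- expand.grid(lapply(group_perms, seq_along))
  dmat <- as.matrix(stats::dist(xyz))
  k <- length(kinds)
  ut <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  best <- NULL; best_ord <- NULL
  for (ci in seq_len(nrow(combos))) {
    full <- unlist(lapply(seq_along(groups),
                          function(gi) group_perms[[gi]][[combos[ci, gi]]]))
    dv <- dmat[cbind(full[ut[, 1]], full[ut[, 2]])]
    if (is.null(best) || .lex_less(dv, best)) { best <- dv; best_ord <- full }
  }
  list(order = best_ord, dvec = best)
}

.lex_less <- function(a, b) {
  i <- which(a != b)
  if (!length(i)) return(FALSE)
  a[i[1]] < b[i[1]]
}

# enumerate all k-subsets of each conformer's sites as labeled variants
enumerate_variants <- function(entries, k) {
  out <- list()
  for (mi in seq_along(entries)) {
    en <- entries[[mi]]
    for (ci in seq_along(en$conformers)) {
      sites <- en$conformers[[ci]]$sites
      n <- nrow(sites)
      if (n < k) next
      xyz <- site_coords(sites)
      subsets <- utils::combn(n, k)
      for (s in seq_len(ncol(subsets))) {
        idx <- subsets[, s]
        can <- canonical_subset(xyz[idx, , drop = FALSE], sites$kind[idx])
        out[[length(out) + 1L]] <- list(
          molecule = en$molecule_id, mi = mi, conformer = ci,
          sites_idx = idx[can$order],
          label = hypothesis_label(sites$kind[idx]),
          dvec = can$dvec)
      }
    }
  }
  out
}

# Recursive tree partitioning of distance space. Splits the axis with the
# largest variant range at the midpoint of its largest empty gap; a leaf is
# reached when every axis range is <= bin_size, i.e. a data-centred box of
# edge <= bin_size.
partition_variants <- function(dmatrix, bin_size) {
  recurse <- function(rows) {
    if (length(rows) == 1L) return(list(rows))
    sub <- dmatrix[rows, , drop = FALSE]
    rng <- apply(sub, 2, function(v) max(v) - min(v))
    if (all(rng <= bin_size)) return(list(rows))
    ax <- which.max(rng)
    v <- sub[, ax]
    us <- sort(unique(v))
    gaps <- diff(us)
    gi <- which.max(gaps)
    cut <- (us[gi] + us[gi + 1]) / 2
    c(recurse(rows[v <= cut]), recurse(rows[v > cut]))
  }
  recurse(seq_len(nrow(dmatrix)))
}

#' Find common pharmacophore hypotheses across active ligands
#'
#' Enumerates all k-site combinations of every conformer of every ligand,
#' encodes each as its sorted kind label plus canonical inter-site distance
#' vector, and tree-partitions each label's distance space into boxes of
#' final edge `bin_size`. A box whose variants cover at least a `must_match`
#' fraction of the input molecules yields one hypothesis, whose geometry is
#' the box's medoid variant. Hypotheses are scored with
#' [score_hypothesis()] and returned best-first. Deterministic for a fixed
#' input ordering.
#'
#' @param entries Ligand entries from [ligand_entries()] (>= 2 molecules).
#' @param n_features Number of sites k (>= 3; default 5).
#' @param must_match Minimum fraction of molecules a box must cover
#'   (in (0, 1]; default 0.9).
#' @param bin_size Final partition box edge in Angstrom (default 1).
#' @param tol Per-site tolerance stored on emitted hypotheses (default 2).
#' @param score Compute scores (default `TRUE`; scoring matches every
#'   molecule against every candidate and dominates runtime).
#' @return List of `ph_hypothesis`, ranked by score (descending) when
#'   scored. Empty (with a warning) when no molecule has k sites.
#' @export
find_common_hypotheses <- function(entries, n_features = 5L,
                                   must_match = 0.9, bin_size = 1.0,
                                   tol = 2.0, score = TRUE) {
  if (length(entries) < 2L) stop("need at least 2 ligand entries")
  if (n_features < 3L) stop("n_features must be >= 3")
  if (bin_size <= 0) stop("bin_size must be positive")
  if (!(must_match > 0 && must_match <= 1)) stop("must_match must be in (0,1]")
  variants <- enumerate_variants(entries, n_features)
  if (!length(variants)) {
    warning("no molecule has ", n_features, " feature sites")
    return(list())
  }
  n_mol <- length(entries)
  need <- ceiling(must_match * n_mol)
  labels <- vapply(variants, `[[`, "", "label")
  hyps <- list()
  for (lb in sort(unique(labels))) {
    vi <- which(labels == lb)
    mols_lb <- unique(vapply(variants[vi], `[[`, "", "molecule"))
    if (length(mols_lb) < need) next
    dm <- do.call(rbind, lapply(variants[vi], `[[`, "dvec"))
    leaves <- partition_variants(dm, bin_size)
    for (leaf in leaves) {
      vv <- variants[vi[leaf]]
      mols_in <- unique(vapply(vv, `[[`, "", "molecule"))
      if (length(mols_in) < need) next
      sub <- dm[leaf, , drop = FALSE]
      # medoid in distance-vector space; deterministic tie-break
      ss <- as.matrix(stats::dist(sub))
      tot <- rowSums(ss)
      cand <- which(tot <= min(tot) + 1e-12)
      keyo <- order(vapply(vv[cand], `[[`, "", "molecule"),
                    vapply(vv[cand], `[[`, 0, "conformer"),
                    vapply(vv[cand], function(v) paste(v$sites_idx,
                                                       collapse = ","), ""))
      med <- vv[[cand[keyo[1]]]]
      en <- entries[[med$mi]]
      sites <- en$conformers[[med$conformer]]$sites[med$sites_idx, ,
                                                   drop = FALSE]
      ctr <- colMeans(site_coords(sites))
      sites[, c("x", "y", "z")] <- sweep(site_coords(sites), 2, ctr)
      hyp <- ph_hypothesis(sites, tol = tol,
                           provenance = sprintf(
                             "medoid %s conf %d; %d/%d molecules",
                             med$molecule, med$conformer,
                             length(mols_in), n_mol))
      hyp$n_molecules <- length(mols_in)
      hyps[[length(hyps) + 1L]] <- hyp
    }
  }
  if (!length(hyps)) return(list())
  if (score) {
    sc <- vapply(hyps, function(h) {
      tryCatch(score_hypothesis(h, entries), error = function(e) -Inf)
    }, 0)
    ord <- order(-sc, vapply(hyps, `[[`, "", "label"))
    hyps <- hyps[ord]
    for (i in seq_along(hyps)) hyps[[i]]$score <- sc[ord][i]
  }
  for (i in seq_along(hyps)) {
    hyps[[i]]$id <- paste0(hyps[[i]]$label, ".", i)
  }
  hyps
}

# injective kind-preserving assignments of hypothesis-site slots to ligand
# sites: list of integer vectors (ligand site index per slot)
.kind_assignments <- function(hyp_kinds, lig_kinds) {
  slots_by_kind <- split(seq_along(hyp_kinds), hyp_kinds)
  cand_by_kind <- lapply(names(slots_by_kind),
                         function(kk) which(lig_kinds == kk))
  names(cand_by_kind) <- names(slots_by_kind)
  for (kk in names(slots_by_kind)) {
    if (length(cand_by_kind[[kk]]) < length(slots_by_kind[[kk]])) {
      return(list())
    }
  }
  per_kind <- lapply(names(slots_by_kind), function(kk) {
    slots <- slots_by_kind[[kk]]; cands <- cand_by_kind[[kk]]
    picks <- utils::combn(cands, length(slots), simplify = FALSE)
    unlist(lapply(picks, .perms), recursive = FALSE)
  })
  combos <- expand.grid(lapply(per_kind, seq_along))
  out <- vector("list", nrow(combos))
  slot_order <- unlist(slots_by_kind, use.names = FALSE)
  for (i in seq_len(nrow(combos))) {
    asg <- integer(length(hyp_kinds))
    picked <- unlist(lapply(seq_along(per_kind),
                            function(gi) per_kind[[gi]][[combos[i, gi]]]))
    asg[slot_order] <- picked
    out[[i]] <- asg
  }
  out
}

#' Match a ligand against a hypothesis
#'
#' Searches all conformers and all kind-consistent site correspondences of
#' size at least `min_sites`. A correspondence is feasible when, after
#' least-squares superposition of the matched ligand sites onto the
#' hypothesis sites, every site pair lies within the per-site tolerance.
#' Among feasible correspondences the winner has maximal matched-site count,
#' then minimal RMSD, then lowest conformer energy. "No match" is an
#' explicit `NULL` result, not an error.
#'
#' @param hyp A [ph_hypothesis].
#' @param entry One ligand entry from [ligand_entries()].
#' @param min_sites Minimum matched sites (default 4).
#' @param tol Per-site tolerance in Angstrom (default `hyp$tol`).
#' @return A `ph_match` list (`molecule_id`, `conformer`, `hyp_sites`,
#'   `lig_sites`, `n_matched`, `rmsd`, `transform`) or `NULL`.
#' @export
match_ligand <- function(hyp, entry, min_sites = 4L, tol = hyp$tol) {
  k <- nrow(hyp$sites)
  if (min_sites > k) stop("min_sites exceeds hypothesis size")
  if (min_sites < 3L) stop("min_sites must be >= 3 for a rigid alignment")
  hxyz <- site_coords(hyp$sites)
  hdist <- hyp$dist
  hkinds <- hyp$sites$kind
  best <- NULL
  for (m in seq(k, min_sites)) {
    hyp_subsets <- utils::combn(k, m, simplify = FALSE)
    for (ci in seq_along(entry$conformers)) {
      cf <- entry$conformers[[ci]]
      sites <- cf$sites
      if (!nrow(sites)) next
      lxyz <- site_coords(sites)
      ldist <- as.matrix(stats::dist(lxyz))
      for (hs in hyp_subsets) {
        asgs <- .kind_assignments_cached(hkinds[hs], sites$kind)
        href <- hxyz[hs, , drop = FALSE]
        hc <- colMeans(href)
        hcen <- sweep(href, 2, hc)
        hd <- hdist[hs, hs]
        for (asg in asgs) {
          # cheap rigid-compatibility prefilter on inter-site distances
          if (max(abs(ldist[asg, asg] - hd)) > 2 * tol) next
          A <- lxyz[asg, , drop = FALSE]
          cm <- colMeans(A)
          a <- sweep(A, 2, cm)
          s <- svd(crossprod(a, hcen))
          dsgn <- sign(det(tcrossprod(s$v, s$u)))
          if (dsgn == 0) dsgn <- 1
          rot <- t(s$v %*% diag(c(1, 1, dsgn)) %*% t(s$u))
          moved <- sweep(a %*% rot, 2, hc, `+`)
          dev2 <- rowSums((moved - href)^2)
          if (max(dev2) > tol^2) next
          rmsd <- sqrt(mean(dev2))
          if (is.null(best) || rmsd < best$rmsd - 1e-12 ||
              (abs(rmsd - best$rmsd) <= 1e-12 &&
               cf$energy < best$energy)) {
            trans <- hc - cm %*% rot
            best <- list(molecule_id = entry$molecule_id, conformer = ci,
                         hyp_sites = hs, lig_sites = asg,
                         n_matched = m, rmsd = rmsd,
                         energy = cf$energy, rotation = rot,
                         translation = as.numeric(trans))
          }
        }
      }
    }
    if (!is.null(best)) break  # larger correspondences always win
  }
  if (!is.null(best)) {
    rot <- best$rotation; trans <- best$translation
    best$transform <- function(x) sweep(as.matrix(x) %*% rot, 2, trans,
                                        `+`)
    class(best) <- "ph_match"
  }
  best
}

.asg_cache <- new.env(parent = emptyenv())

.kind_assignments_cached <- function(hyp_kinds, lig_kinds) {
  key <- paste(paste(hyp_kinds, collapse = ""),
               paste(lig_kinds, collapse = ""), sep = "|")
  hit <- .asg_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- .kind_assignments(hyp_kinds, lig_kinds)
  .asg_cache[[key]] <- val
  val
}

#' Align a matched ligand onto a hypothesis
#'
#' Applies the least-squares rigid transform of the match to the full
#' conformer coordinates.
#'
#' @param hyp A [ph_hypothesis].
#' @param match A `ph_match` from [match_ligand()] with >= 3 sites.
#' @param entry The ligand entry the match came from.
#' @return List: `molecule_id`, `conformer`, `coords_aligned` (all atoms),
#'   `sites_aligned`, `match`, `transform`.
#' @export
align_ligand <- function(hyp, match, entry) {
  if (is.null(match)) stop("cannot align: no match")
  if (match$n_matched < 3L) stop("need >= 3 matched sites for alignment")
  cf <- entry$conformers[[match$conformer]]
  lxyz <- site_coords(cf$sites)[match$lig_sites, , drop = FALSE]
  sv <- svd(sweep(lxyz, 2, colMeans(lxyz)))
  if (sv$d[2] < 1e-6) stop("degenerate (collinear) site set for '",
                           entry$molecule_id, "'")
  sites_al <- cf$sites
  sites_al[, c("x", "y", "z")] <- match$transform(site_coords(cf$sites))
  dirs <- site_dirs(cf$sites)
  ok <- stats::complete.cases(dirs)
  if (any(ok)) {
    sites_al[ok, c("dx", "dy", "dz")] <-
      dirs[ok, , drop = FALSE] %*% match$rotation
  }
  list(molecule_id = match$molecule_id, conformer = match$conformer,
       coords_aligned = match$transform(cf$coords),
       sites_aligned = sites_al, match = match,
       transform = match$transform)
}

#' Score a hypothesis against a set of active ligands
#'
#' `score = w_align * (1 - mean match RMSD / rmsd_norm) + w_vec * mean
#' direction cosine over matched A/R sites + w_vol * mean pairwise
#' heavy-atom volume overlap of the aligned actives`. Sites without stored
#' directions contribute a cosine of 1 (tolerant default); ring-normal signs
#' are ignored. The volume term uses at most `max_overlap_ligands` ligands.
#'
#' @param hyp A [ph_hypothesis].
#' @param entries Ligand entries; every entry must match at all k sites.
#' @param w_align,w_vec,w_vol Term weights (defaults 1).
#' @param rmsd_norm RMSD normalization in Angstrom (default 1.2).
#' @param max_overlap_ligands Cap for the quadratic volume term (default 20).
#' @return Numeric score (higher is better).
#' @export
score_hypothesis <- function(hyp, entries, w_align = 1, w_vec = 1,
                             w_vol = 1, rmsd_norm = 1.2,
                             max_overlap_ligands = 20L) {
  k <- nrow(hyp$sites)
  matches <- list(); aligned <- list()
  for (en in entries) {
    m <- match_ligand(hyp, en, min_sites = k)
    if (is.null(m)) next
    matches[[length(matches) + 1L]] <- m
    al <- align_ligand(hyp, m, en)
    heavy <- en$heavy
    aligned[[length(aligned) + 1L]] <-
      list(coords = al$coords_aligned[heavy, , drop = FALSE],
           elems = en$elems[heavy],
           sites = al$sites_aligned, match = m)
  }
  if (!length(matches)) stop("no ligand matches hypothesis ", hyp$id)
  mean_rmsd <- mean(vapply(matches, `[[`, 0, "rmsd"))
  # direction-cosine term over A and R sites
  hdirs <- site_dirs(hyp$sites)
  cosines <- numeric()
  for (al in aligned) {
    m <- al$match
    for (j in seq_along(m$hyp_sites)) {
      hs <- m$hyp_sites[j]
      if (!hyp$sites$kind[hs] %in% c("A", "R")) next
      hv <- hdirs[hs, ]
      lv <- unlist(al$sites[m$lig_sites[j], c("dx", "dy", "dz")])
      cosines <- c(cosines,
                   if (anyNA(hv) || anyNA(lv)) 1
                   else abs(sum(hv * lv)))
    }
  }
  vec_term <- if (length(cosines)) mean(cosines) else 1
  # pairwise volume-overlap surrogate: fraction of atoms of one ligand
  # within mean-vdW contact of any atom of the other, symmetrized
  use <- aligned[seq_len(min(length(aligned), max_overlap_ligands))]
  ov <- numeric()
  if (length(use) >= 2L) {
    for (i in seq_len(length(use) - 1L)) {
      for (j in seq(i + 1L, length(use))) {
        ov <- c(ov, .pair_overlap(use[[i]], use[[j]]))
      }
    }
  } else ov <- 1
  w_align * (1 - mean_rmsd / rmsd_norm) + w_vec * vec_term + w_vol * mean(ov)
}

.pair_overlap <- function(a, b) {
  ra <- vdw_radius(a$elems); rb <- vdw_radius(b$elems)
  dd <- outer(rowSums(a$coords^2), rowSums(b$coords^2), `+`) -
    2 * a$coords %*% t(b$coords)
  dd[dd < 0] <- 0
  thr <- outer(ra, rb, `+`) / 2
  hit_a <- apply(sqrt(dd) <= thr, 1, any)
  hit_b <- apply(sqrt(dd) <= thr, 2, any)
  (mean(hit_a) + mean(hit_b)) / 2
}

#' Write a hypothesis to JSON
#' @param hyp A [ph_hypothesis].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hypothesis <- function(hyp, path) {
  jsonlite::write_json(
    list(schema = "phore3d-hypothesis-1", id = hyp$id, label = hyp$label,
         tol = hyp$tol, score = hyp$score, provenance = hyp$provenance,
         sites = hyp$sites, dist = hyp$dist),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a hypothesis from JSON
#' @param path File written by [write_hypothesis()].
#' @return A [ph_hypothesis].
#' @export
read_hypothesis <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sites <- as.data.frame(j$sites)
  for (cc in c("dx", "dy", "dz")) {
    if (is.null(sites[[cc]])) sites[[cc]] <- NA_real_
    sites[[cc]] <- as.numeric(sites[[cc]])
  }
  h <- ph_hypothesis(sites, tol = j$tol,
                     score = if (is.null(j$score)) NA_real_ else j$score,
                     id = j$id, provenance = j$provenance %||% "")
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a
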