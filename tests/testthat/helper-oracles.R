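# Independent oracle implementations used to check the package's
# numerical routines. These deliberately share no code with the package.

# Horn's quaternion closed-form rigid superposition (second, independent
# solution of the least-squares superposition problem)
quaternion_superpose_rmsd <- function(moving, fixed) {
  a <- sweep(moving, 2, colMeans(moving))
  b <- sweep(fixed, 2, colMeans(fixed))
  M <- t(a) %*% b
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- sum(a^2) + sum(b^2) - 2 * lam
  sqrt(max(e2, 0) / nrow(a))
}

# brute-force pairwise Mann-Whitney AUC with half credit for ties
pairwise_auc <- function(scores, is_active) {
  pos <- scores[is_active]; neg <- scores[!is_active]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# trapezoidal area under an ROC polyline
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# direct greedy reference for conformer retention (O(n^2), no ordering
# tricks): keep ascending-energy conformers within the window whose RMSD to
# every kept one is >= cutoff
reference_prune <- function(coord_list, energies, window, cutoff) {
  ord <- order(energies)
  rel <- energies[ord] - min(energies)
  kept <- integer()
  for (i in seq_along(ord)) {
    if (rel[i] > window) next
    ok <- TRUE
    for (j in kept) {
      if (phore3d::heavy_atom_rmsd(coord_list[[ord[i]]],
                                   coord_list[[ord[j]]]) < cutoff) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  ord[kept]
}

# a rigid classed point-set molecule for matching/encoding tests
point_set_mol <- function(id, xyz, classes, kinds = NULL, ki = NA_real_) {
  xyz <- as.matrix(xyz)
  elem_of <- c(D = "O", H = "C", N = "O", P = "N", W = "O", X = "S")
  atoms <- data.frame(elem = unname(elem_of[classes]),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = 0L, nh = 0L)
  n <- nrow(atoms)
  bonds <- if (n >= 2) data.frame(a1 = seq_len(n - 1), a2 = 2:n, order = 1L)
  sites <- if (!is.null(kinds)) {
    data.frame(kind = kinds, x = xyz[seq_along(kinds), 1],
               y = xyz[seq_along(kinds), 2], z = xyz[seq_along(kinds), 3],
               dx = NA_real_, dy = NA_real_, dz = NA_real_, atoms = "")
  }
  phmol(id, atoms, bonds, ki = ki, sites = sites, atom_class = classes)
}

random_rot3 <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Brute-force common-hypothesis enumerator: a direct, unoptimized
# implementation of the published procedure (enumerate k-subsets, canonical
# kind-sorted minimal distance vector, recursive largest-gap partition,
# emit boxes covering >= must_match of the molecules). Written for tiny
# instances only.
brute_force_hypotheses <- function(entries, k, must_match, bin_size) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  vars <- list()
  for (mi in seq_along(entries)) {
    en <- entries[[mi]]
    for (ci in seq_along(en$conformers)) {
      st <- en$conformers[[ci]]$sites
      if (nrow(st) < k) next
      xyz <- as.matrix(st[, c("x", "y", "z")])
      for (ss in utils::combn(nrow(st), k, simplify = FALSE)) {
        lbl <- paste(sort(st$kind[ss]), collapse = "")
        # canonical: try every permutation of the subset whose kinds are
        # sorted ascending; keep the lexicographically smallest dvec
        best <- NULL
        for (p in perms(ss)) {
          if (is.unsorted(st$kind[p])) next
          pts <- xyz[p, , drop = FALSE]
          dv <- c()
          for (i in 1:(k - 1)) for (j in (i + 1):k)
            dv <- c(dv, sqrt(sum((pts[i, ] - pts[j, ])^2)))
          if (is.null(best)) best <- dv
          else {
            w <- which(dv != best)
            if (length(w) && dv[w[1]] < best[w[1]]) best <- dv
          }
        }
        vars[[length(vars) + 1]] <- list(mol = en$molecule_id, lbl = lbl,
                                         dvec = best)
      }
    }
  }
  if (!length(vars)) return(list())
  need <- ceiling(must_match * length(entries))
  out <- list()
  for (lbl in sort(unique(sapply(vars, `[[`, "lbl")))) {
    vv <- vars[sapply(vars, `[[`, "lbl") == lbl]
    dm <- do.call(rbind, lapply(vv, `[[`, "dvec"))
    boxes <- list(seq_len(nrow(dm)))
    repeat {
      changed <- FALSE
      nb <- list()
      for (bx in boxes) {
        sub <- dm[bx, , drop = FALSE]
        rng <- apply(sub, 2, function(v) max(v) - min(v))
        if (all(rng <= bin_size)) { nb[[length(nb) + 1]] <- bx; next }
        ax <- which.max(rng)
        us <- sort(unique(sub[, ax]))
        gi <- which.max(diff(us))
        cut <- (us[gi] + us[gi + 1]) / 2
        nb[[length(nb) + 1]] <- bx[sub[, ax] <= cut]
        nb[[length(nb) + 1]] <- bx[sub[, ax] > cut]
        changed <- TRUE
      }
      boxes <- nb
      if (!changed) break
    }
    for (bx in boxes) {
      mols <- unique(sapply(vv[bx], `[[`, "mol"))
      if (length(mols) >= need) {
        out[[length(out) + 1]] <- list(label = lbl, molecules = sort(mols),
                                       dvecs = dm[bx, , drop = FALSE])
      }
    }
  }
  out
}

# minimal distance-matrix difference over within-kind permutations
hyp_dist_gap <- function(hyp_a, hyp_b) {
  stopifnot(hyp_a$label == hyp_b$label)
  k <- nrow(hyp_a$sites)
  kinds <- hyp_a$sites$kind
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(k))) {
    if (!identical(kinds[p], kinds)) next
    best <- min(best, max(abs(hyp_a$dist[p, p] - hyp_b$dist)))
  }
  best
}
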