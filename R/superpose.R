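#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid-body superposition of `moving` onto `fixed`:
#' the rotation is the closed-form SVD solution with the determinant
#' correction that excludes reflections, applied after centering both point
#' sets on their centroids.
#'
#' @param moving,fixed n x 3 coordinate matrices with corresponding rows.
#' @param weights Optional non-negative per-point weights.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% rotation + translation`), `rmsd`, and `transform`,
#'   a function applying the fitted transform to any m x 3 matrix.
#' @export
superpose <- function(moving, fixed, weights = NULL) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)) || ncol(moving) != 3L) {
    stop("superpose: coordinate sets must share dimensions n x 3")
  }
  n <- nrow(moving)
  if (n < 1L) stop("superpose: empty coordinate sets")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  w <- w / sum(w)
  cm <- colSums(moving * w)
  cf <- colSums(fixed * w)
  a <- sweep(moving, 2, cm)
  b <- sweep(fixed, 2, cf)
  h <- t(a * w) %*% b
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rot <- t(rot)  # row-vector convention: x %*% rot
  trans <- cf - cm %*% rot
  moved <- sweep(a %*% rot, 2, cf, `+`)
  rmsd <- sqrt(sum(w * rowSums((moved - fixed)^2)))
  list(rotation = rot, translation = as.numeric(trans), rmsd = rmsd,
       transform = function(x) sweep(as.matrix(x) %*% rot, 2,
                                     as.numeric(trans), `+`))
}

#' Heavy-atom RMSD between two conformers
#'
#' Root-mean-square deviation over corresponding heavy atoms, optionally
#' after optimal rigid superposition. This is the distance used by the
#' conformer redundancy rule (default cutoff 0.5 Angstrom).
#'
#' @param conf_a,conf_b n x 3 coordinate matrices with identical atom
#'   ordering (heavy atoms only).
#' @param superpose_first If `TRUE` (default), minimize over rigid
#'   transforms first.
#' @return RMSD in Angstrom.
#' @export
heavy_atom_rmsd <- function(conf_a, conf_b, superpose_first = TRUE) {
  conf_a <- as.matrix(conf_a); conf_b <- as.matrix(conf_b)
  if (!all(dim(conf_a) == dim(conf_b))) {
    stop("heavy_atom_rmsd: atom count/ordering mismatch")
  }
  if (nrow(conf_a) < 1L) stop("heavy_atom_rmsd: need at least one atom")
  if (superpose_first) {
    superpose(conf_a, conf_b)$rmsd
  } else {
    sqrt(mean(rowSums((conf_a - conf_b)^2)))
  }
}
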