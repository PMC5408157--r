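#' Assign per-atom pharmacophore classes for atom-based QSAR
#'
#' Classes follow the atom-based 3D-QSAR convention: `D` donor-H bearing
#' heavy atom, `P` positive ionizable, `N` negative ionizable, `W`
#' electron-withdrawing (polar non-donor O/N, fluorine), `H`
#' hydrophobic/nonpolar (carbon, sulfur, heavy halogens), `X` miscellaneous.
#' Precedence: P, N, D, W, H, X. Synthetic molecules carry planted classes,
#' returned unchanged. Hydrogens are not classed (encoding is heavy-atom).
#'
#' @param mol A [phmol] with formal charges.
#' @return List: `class` (per heavy atom), `radius` (van der Waals, A),
#'   `heavy` (atom indices).
#' @export
assign_atom_classes <- function(mol) {
  heavy <- heavy_index(mol)
  if (!is.null(mol$atom_class)) {
    cls <- mol$atom_class[heavy]
  } else {
    atoms <- mol$atoms
    arom <- aromatic_atoms(mol)
    cls <- vapply(heavy, function(a) {
      el <- atoms$elem[a]; chg <- atoms$charge[a]; nh <- atoms$nh[a]
      if (chg > 0) return("P")
      if (el == "N" && chg == 0 && all(bond_orders_of(mol, a) == 1L) &&
          !arom[a] && !is_amide_n(mol, a) &&
          !any(arom[neighbors_of(mol, a)])) return("P")
      if (chg < 0) return("N")
      if (el %in% c("N", "O", "S") && nh >= 1L) return("D")
      if (el %in% c("O", "N", "F")) return("W")
      if (el %in% c("C", "S", "Cl", "Br", "I", "P")) return("H")
      warning("unsupported element '", el, "' classed X")
      "X"
    }, "")
  }
  list(class = cls, radius = vdw_radius(mol$atoms$elem[heavy]),
       heavy = heavy)
}

.grid_classes <- c("D", "H", "N", "P", "W", "X")

#' Build the occupancy grid over aligned ligands
#'
#' Axis-aligned cubic grid with the given spacing covering the union
#' bounding box of the ligands' heavy atoms inflated by `margin`. The origin
#' (first cube center) is snapped down to a multiple of the spacing so that
#' matrices rebuilt from the same alignment are bit-identical regardless of
#' ligand order.
#'
#' @param aligned_coords List of heavy-atom coordinate matrices in the
#'   hypothesis frame.
#' @param spacing Cube edge in Angstrom (default 0.5).
#' @param margin Bounding-box inflation in Angstrom (default 2).
#' @return Grid spec: `origin`, `spacing`, `dims`, `classes`.
#' @export
build_grid <- function(aligned_coords, spacing = 0.5, margin = 2.0) {
  if (!length(aligned_coords)) stop("no aligned ligands")
  all_xyz <- do.call(rbind, aligned_coords)
  lo <- apply(all_xyz, 2, min) - margin
  hi <- apply(all_xyz, 2, max) + margin
  origin <- floor(lo / spacing) * spacing
  dims <- as.integer(floor((hi - origin) / spacing)) + 1L
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 classes = .grid_classes),
            class = "ph_grid")
}

grid_ncubes <- function(grid) prod(grid$dims)

grid_cube_centers <- function(grid, cube_idx) {
  d <- grid$dims
  i0 <- cube_idx - 1L
  ix <- i0 %% d[1]
  iy <- (i0 %/% d[1]) %% d[2]
  iz <- i0 %/% (d[1] * d[2])
  cbind(grid$origin[1] + ix * grid$spacing,
        grid$origin[2] + iy * grid$spacing,
        grid$origin[3] + iz * grid$spacing)
}

#' Encode an aligned ligand as binary grid occupancy
#'
#' A bit (cube c, class k) is set iff some heavy atom of class k lies within
#' its van der Waals radius of the cube center. Atoms falling outside the
#' grid contribute nothing and are counted in the `n_outside` attribute.
#'
#' @param coords Heavy-atom coordinates in the hypothesis frame.
#' @param classing Result of [assign_atom_classes()] (fields `class`,
#'   `radius` aligned with `coords` rows).
#' @param grid Grid spec from [build_grid()].
#' @return Sorted integer vector of set column ids
#'   (`(class_index - 1) * n_cubes + cube_index`), attribute `n_outside`.
#' @export
encode_ligand <- function(coords, classing, grid) {
  coords <- as.matrix(coords)
  sp <- grid$spacing; org <- grid$origin; d <- grid$dims
  ncube <- grid_ncubes(grid)
  ids <- integer(0)
  n_outside <- 0L
  for (a in seq_len(nrow(coords))) {
    kidx <- match(classing$class[a], grid$classes)
    if (is.na(kidx)) next
    r <- classing$radius[a]
    p <- coords[a, ]
    lo <- ceiling((p - r - org) / sp)
    hi <- floor((p + r - org) / sp)
    if (any(hi < 0) || any(lo > d - 1L)) { n_outside <- n_outside + 1L; next }
    lo <- pmax(lo, 0); hi <- pmin(hi, d - 1L)
    xs <- seq(lo[1], hi[1]); ys <- seq(lo[2], hi[2]); zs <- seq(lo[3], hi[3])
    dx2 <- (org[1] + xs * sp - p[1])^2
    dy2 <- (org[2] + ys * sp - p[2])^2
    dz2 <- (org[3] + zs * sp - p[3])^2
    ok <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
    if (!any(ok)) next
    w <- which(ok, arr.ind = TRUE)
    cube <- (xs[w[, 1]]) + (ys[w[, 2]]) * d[1] +
      (zs[w[, 3]]) * d[1] * d[2] + 1L
    ids <- c(ids, (kidx - 1L) * ncube + cube)
  }
  structure(sort(unique(as.integer(ids))), n_outside = n_outside)
}

#' Assemble the ligands-by-cubes feature matrix
#'
#' Stacks encoded rows and drops columns occupied by fewer than
#' `min_occupancy` ligands (pruning is idempotent). Column metadata (cube
#' center and atom class) is retained for coefficient-volume export.
#'
#' @param rows List of encoded id vectors from [encode_ligand()].
#' @param row_ids Molecule ids aligned with `rows`.
#' @param grid Grid spec the rows were encoded on.
#' @param min_occupancy Minimum ligands per surviving column (default 2).
#' @return Object of class `ph_featmat`: sparse binary matrix `X`,
#'   `row_ids`, `col_ids`, `grid`.
#' @export
assemble_matrix <- function(rows, row_ids, grid, min_occupancy = 2L) {
  stopifnot(length(rows) == length(row_ids))
  all_ids <- unlist(rows)
  occ <- table(all_ids)
  keep <- sort(as.integer(names(occ)[occ >= min_occupancy]))
  if (!length(keep)) stop("all columns dropped at min_occupancy ",
                          min_occupancy)
  ii <- integer(0); jj <- integer(0)
  for (r in seq_along(rows)) {
    j <- match(rows[[r]], keep)
    j <- j[!is.na(j)]
    ii <- c(ii, rep.int(r, length(j)))
    jj <- c(jj, j)
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj,
                            dims = c(length(rows), length(keep)))
  structure(list(X = X, row_ids = row_ids, col_ids = keep, grid = grid),
            class = "ph_featmat")
}

#' Column metadata of a feature matrix
#' @param fm A `ph_featmat`.
#' @return Data frame: column id, cube center `x`,`y`,`z`, atom `class`.
#' @export
featmat_columns <- function(fm) {
  ncube <- grid_ncubes(fm$grid)
  kidx <- (fm$col_ids - 1L) %/% ncube + 1L
  cube <- (fm$col_ids - 1L) %% ncube + 1L
  ctr <- grid_cube_centers(fm$grid, cube)
  data.frame(col_id = fm$col_ids, x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
             class = fm$grid$classes[kidx])
}

#' Fit an atom-based PLS (PLS1/NIPALS) model
#'
#' Partial least squares on the mean-centered binary occupancy matrix and
#' mean-centered pKi (binary columns are centered, not variance-scaled).
#' Factors are extracted iteratively; models for every factor count from 1
#' to `n_factors` are exposed. Extraction stops early, with a warning, if
#' the residual X carries no covariance with y (rank exhausted).
#'
#' @param fm A `ph_featmat` (or plain numeric matrix).
#' @param y pKi vector aligned with the rows.
#' @param n_factors Maximum factors (default 7).
#' @return Object of class `ph_pls`: per-factor coefficient vectors (on the
#'   original binary columns) and intercepts, fitted values, loadings, and
#'   training metadata. Prediction via factor scores and via the collapsed
#'   coefficients agree to numerical precision.
#' @export
fit_pls <- function(fm, y, n_factors = 7L) {
  X0 <- if (inherits(fm, "ph_featmat")) as.matrix(fm$X * 1) else as.matrix(fm)
  y <- as.numeric(y)
  n <- nrow(X0)
  if (length(y) != n) stop("y length must match matrix rows")
  if (n_factors >= n) stop("n_factors must be < number of rows")
  if (stats::sd(y) < 1e-12) stop("constant y: nothing to regress")
  mx <- colMeans(X0); my <- mean(y)
  X <- sweep(X0, 2, mx); yr <- y - my
  p <- ncol(X0)
  A <- n_factors
  W <- matrix(0, p, A); P <- matrix(0, p, A); qv <- numeric(A)
  Tm <- matrix(0, n, A)
  a_done <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(X, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning("PLS rank exhausted after ", a_done, " factor(s)")
      break
    }
    w <- w / nw
    t_ <- X %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) {
      warning("PLS rank exhausted after ", a_done, " factor(s)")
      break
    }
    pl <- crossprod(X, t_) / tt
    q <- sum(yr * t_) / tt
    X <- X - t_ %*% t(pl)
    yr <- yr - q * t_
    W[, a] <- w; P[, a] <- pl; qv[a] <- q; Tm[, a] <- t_
    a_done <- a
  }
  if (a_done == 0L) stop("no PLS factor could be extracted")
  coefs <- vector("list", a_done); intercepts <- numeric(a_done)
  fitted <- matrix(0, n, a_done)
  for (a in seq_len(a_done)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    B <- Wa %*% solve(crossprod(Pa, Wa), qv[seq_len(a)])
    coefs[[a]] <- as.numeric(B)
    intercepts[a] <- my - sum(mx * B)
    fitted[, a] <- as.numeric(X0 %*% B) + intercepts[a]
  }
  structure(list(n_factors = a_done, coefs = coefs,
                 intercepts = intercepts, fitted = fitted,
                 means_x = mx, mean_y = my, W = W[, seq_len(a_done),
                                                 drop = FALSE],
                 P = P[, seq_len(a_done), drop = FALSE],
                 q = qv[seq_len(a_done)],
                 scores = Tm[, seq_len(a_done), drop = FALSE],
                 col_ids = if (inherits(fm, "ph_featmat")) fm$col_ids
                           else seq_len(p),
                 grid = if (inherits(fm, "ph_featmat")) fm$grid else NULL,
                 row_ids = if (inherits(fm, "ph_featmat")) fm$row_ids
                           else NULL,
                 y = y),
            class = "ph_pls")
}

#' @export
print.ph_pls <- function(x, ...) {
  cat(sprintf("<ph_pls> %d factor(s), %d columns, %d training ligands\n",
              x$n_factors, length(x$coefs[[x$n_factors]]), length(x$y)))
  invisible(x)
}

#' Predict pKi for encoded ligands
#'
#' `y_hat = intercept + coefficients . row`. Rows are given either as
#' encoded id vectors (from [encode_ligand()], matched against the model's
#' surviving columns) or as plain numeric vectors over the model columns.
#' An all-zero row predicts the intercept-only value. Ligands that failed
#' the minimum-site match are handled upstream ([rank_database()]) with the
#' floor-prediction policy.
#'
#' @param model A `ph_pls`.
#' @param rows List of encoded id vectors, or a numeric matrix.
#' @param n_factors Factor count to use (default: the model's maximum).
#' @return Numeric vector of predicted pKi.
#' @export
predict_pls <- function(model, rows, n_factors = model$n_factors) {
  if (n_factors < 1L || n_factors > model$n_factors) {
    stop("n_factors out of range")
  }
  B <- model$coefs[[n_factors]]; b0 <- model$intercepts[n_factors]
  if (is.matrix(rows)) {
    if (ncol(rows) != length(B)) stop("grid mismatch: row length ",
                                      ncol(rows), " vs ", length(B))
    return(as.numeric(rows %*% B) + b0)
  }
  vapply(rows, function(ids) {
    j <- match(ids, model$col_ids)
    sum(B[j[!is.na(j)]]) + b0
  }, 0)
}

#' Regression statistics panel
#'
#' The per-model statistics reported for each PLS factor count:
#' `r2 = 1 - RSS/TSS`, `RMSE = sqrt(RSS/n)`, `SD = sqrt(RSS/(n-k-1))`,
#' variance ratio `F = (r2/k) / ((1-r2)/(n-k-1))` with upper-tail
#' probability `P` at `(k, n-k-1)` degrees of freedom, and the Pearson
#' product-moment correlation between observed and predicted.
#'
#' @param y_obs,y_pred Observed and predicted response (length >= 3).
#' @param n_factors Number of PLS factors k used.
#' @return List: `r2`, `sd`, `f`, `p`, `rmse`, `pearson_r`, `n`.
#' @export
regression_stats <- function(y_obs, y_pred, n_factors) {
  n <- length(y_obs)
  if (n != length(y_pred) || n < 3L) stop("need equal-length vectors, n >= 3")
  if (stats::sd(y_obs) < 1e-12) stop("zero variance in observed values")
  k <- n_factors
  rss <- sum((y_obs - y_pred)^2)
  tss <- sum((y_obs - mean(y_obs))^2)
  r2 <- 1 - rss / tss
  f <- (r2 / k) / ((1 - r2) / (n - k - 1))
  list(r2 = r2,
       sd = sqrt(rss / (n - k - 1)),
       f = f,
       p = stats::pf(f, k, n - k - 1, lower.tail = FALSE),
       rmse = sqrt(rss / n),
       pearson_r = stats::cor(y_obs, y_pred),
       n = n)
}

#' F statistic from a (possibly rounded) r-squared
#' @param r2 Coefficient of determination.
#' @param n Observations; @param k regression factors.
#' @return Variance ratio F at `(k, n - k - 1)` degrees of freedom.
#' @export
f_from_r2 <- function(r2, n, k) (r2 / k) / ((1 - r2) / (n - k - 1))

#' Leave-n-out cross-validation of the PLS model
#'
#' Leave-n-out realized as seeded k-fold with `n = ceiling(rows/folds)`:
#' rows are shuffled once, split into `folds` blocks, and each block is
#' predicted by a model fitted on the remainder.
#' `Q2 = 1 - sum((y_held - y_hat)^2) / sum((y_held - mean(y_train))^2)`
#' aggregated over folds, reported per factor count together with held-out
#' RMSE and Pearson r.
#'
#' @param fm A `ph_featmat` (or numeric matrix).
#' @param y Response vector.
#' @param n_factors Maximum factors (default 7).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @return List: `q2` (vector, one per factor count), `stats` (data frame
#'   with factor count, q2, held-out rmse and pearson), `folds`, `seed`,
#'   `pred` (held-out predictions, rows x factors).
#' @export
cross_validate <- function(fm, y, n_factors = 7L, folds = 10L, seed = 42L) {
  X <- if (inherits(fm, "ph_featmat")) as.matrix(fm$X * 1) else as.matrix(fm)
  y <- as.numeric(y)
  n <- nrow(X)
  if (folds < 2L) stop("folds must be >= 2")
  fold_of <- withr::with_seed(as.integer(seed), {
    sample(rep(seq_len(folds), length.out = n))
  })
  press <- numeric(n_factors); denom <- numeric(n_factors)
  pred <- matrix(NA_real_, n, n_factors)
  a_min <- n_factors
  for (f in seq_len(folds)) {
    held <- which(fold_of == f)
    if (!length(held)) next
    tr <- setdiff(seq_len(n), held)
    if (length(tr) < 2L) stop("fold ", f, " leaves <2 training rows")
    model <- suppressWarnings(
      fit_pls(X[tr, , drop = FALSE], y[tr],
              n_factors = min(n_factors, length(tr) - 1L)))
    a_min <- min(a_min, model$n_factors)
    for (a in seq_len(model$n_factors)) {
      yh <- predict_pls(model, X[held, , drop = FALSE], n_factors = a)
      pred[held, a] <- yh
      press[a] <- press[a] + sum((y[held] - yh)^2)
      denom[a] <- denom[a] + sum((y[held] - mean(y[tr]))^2)
    }
  }
  a_use <- seq_len(a_min)
  q2 <- 1 - press[a_use] / denom[a_use]
  stats_df <- do.call(rbind, lapply(a_use, function(a) {
    data.frame(factors = a, q2 = q2[a],
               rmse = sqrt(mean((y - pred[, a])^2)),
               pearson_r = stats::cor(y, pred[, a]))
  }))
  list(q2 = q2, stats = stats_df, folds = folds, seed = as.integer(seed),
       pred = pred[, a_use, drop = FALSE])
}

#' Extract high-magnitude coefficient volumes
#'
#' Emits the grid cubes whose absolute PLS coefficient exceeds the given
#' quantile of the nonzero magnitudes, with sign — the volume elements
#' rendered as positive/negative cubes around aligned ligands.
#'
#' @param model A `ph_pls` fitted on a `ph_featmat`.
#' @param quantile_threshold Quantile of nonzero |coefficient| (default 0.9).
#' @param n_factors Factor count (default model maximum).
#' @return Data frame: cube center `x`,`y`,`z`, `class`, `sign`, `magnitude`.
#' @export
coefficient_volumes <- function(model, quantile_threshold = 0.9,
                                n_factors = model$n_factors) {
  if (is.null(model$grid)) stop("model was not fitted on a ph_featmat")
  B <- model$coefs[[n_factors]]
  nz <- which(abs(B) > 0)
  if (!length(nz)) return(data.frame(x = numeric(), y = numeric(),
                                     z = numeric(), class = character(),
                                     sign = integer(),
                                     magnitude = numeric()))
  thr <- stats::quantile(abs(B[nz]), quantile_threshold, names = FALSE)
  sel <- nz[abs(B[nz]) > thr]
  fmcols <- featmat_columns(list(col_ids = model$col_ids,
                                 grid = model$grid))
  out <- data.frame(x = fmcols$x[sel], y = fmcols$y[sel], z = fmcols$z[sel],
                    class = fmcols$class[sel],
                    sign = as.integer(sign(B[sel])),
                    magnitude = abs(B[sel]))
  out[order(-out$magnitude), , drop = FALSE]
}
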