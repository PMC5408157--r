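test_that("grid construction covers the box and snaps the origin", {
  g <- build_grid(list(matrix(0, 1, 3)), spacing = 1, margin = 2)
  expect_true(all(g$dims >= 5L))
  expect_true(all(g$origin <= -2))
  expect_equal(g$origin, round(g$origin / 1) * 1)
  g2 <- build_grid(list(matrix(0, 1, 3)), spacing = 0.5, margin = 2)
  expect_true(all(g2$dims >= 2 * g$dims - 2))
  # order invariance
  set.seed(41)
  cs <- lapply(1:4, function(i) matrix(stats::rnorm(9, sd = 3), 3, 3))
  ga <- build_grid(cs); gb <- build_grid(rev(cs))
  expect_identical(ga, gb)
  expect_error(build_grid(list()), "no aligned")
})

test_that("occupancy encoding matches the lattice-point closed form", {
  # an atom of radius 1.7 exactly on a cube center of a 1.0-spaced grid
  # covers the lattice points with squared distance <= 2.89: 1 + 6 + 12
  g <- build_grid(list(matrix(0, 1, 3)), spacing = 1, margin = 3)
  ids <- encode_ligand(matrix(0, 1, 3),
                       list(class = "H", radius = 1.7), g)
  expect_length(ids, 19L)
  # brute-force oracle over the whole lattice
  ctr <- phore3d:::grid_cube_centers(g, seq_len(prod(g$dims)))
  expect_equal(sum(rowSums(ctr^2) <= 1.7^2), 19L)
  # all bits live in the H-class block
  ncube <- prod(g$dims)
  kidx <- (ids - 1L) %/% ncube + 1L
  expect_true(all(g$classes[kidx] == "H"))
})

test_that("encoding is co-variant with joint translation and class-local", {
  set.seed(42)
  xyz <- matrix(stats::rnorm(12, sd = 2), 4, 3)
  cl <- list(class = c("H", "P", "W", "H"), radius = rep(1.5, 4))
  g <- build_grid(list(xyz), spacing = 0.5, margin = 2.5)
  ids <- encode_ligand(xyz, cl, g)
  shift <- c(2, -1.5, 3)  # multiples of the spacing
  g2 <- g; g2$origin <- g$origin + shift
  ids2 <- encode_ligand(sweep(xyz, 2, shift, `+`), cl, g2)
  expect_identical(ids, ids2)
  # no D-class atoms: no D-class bits
  ncube <- prod(g$dims)
  expect_false(any(g$classes[(ids - 1L) %/% ncube + 1L] == "D"))
})

test_that("matrix assembly prunes rare columns idempotently", {
  g <- build_grid(list(matrix(0, 1, 3)), spacing = 1, margin = 2)
  rows <- list(c(1L, 5L, 9L), c(1L, 5L), c(5L, 9L))
  fm <- assemble_matrix(rows, c("a", "b", "c"), g, min_occupancy = 2L)
  expect_equal(fm$col_ids, c(1L, 5L, 9L))
  fm1 <- assemble_matrix(rows, c("a", "b", "c"), g, min_occupancy = 1L)
  expect_equal(fm1$col_ids, sort(unique(unlist(rows))))
  rows2 <- list(c(1L, 2L), c(1L, 3L))
  fm2 <- assemble_matrix(rows2, c("a", "b"), g, min_occupancy = 2L)
  expect_equal(fm2$col_ids, 1L)
  expect_error(assemble_matrix(list(1L, 2L), c("a", "b"), g, 2L),
               "dropped")
})

test_that("full-factor PLS reproduces least squares on full-rank data", {
  set.seed(43)
  X <- matrix(stats::rnorm(20 * 8), 20, 8)
  y <- X %*% stats::rnorm(8) + stats::rnorm(20, sd = 0.3)
  model <- fit_pls(X, y, n_factors = 8L)
  ols <- stats::lm.fit(cbind(1, X), y)
  expect_equal(model$fitted[, 8], unname(ols$fitted.values),
               tolerance = 1e-6)
  # one informative column, one factor = simple regression on it
  X1 <- cbind(stats::rnorm(30))
  y1 <- 2 + 3 * X1[, 1] + stats::rnorm(30, sd = 0.1)
  m1 <- fit_pls(X1, y1, n_factors = 1L)
  slr <- stats::lm.fit(cbind(1, X1), y1)
  expect_equal(m1$fitted[, 1], unname(slr$fitted.values), tolerance = 1e-8)
  # exact linear response: r2 = 1, rmse = 0
  yy <- X %*% c(1, -1, 0.5, 0, 0, 2, 0, -0.5)
  mm <- fit_pls(X, yy, n_factors = 8L)
  st <- regression_stats(as.numeric(yy), mm$fitted[, 8], 8)
  expect_equal(st$r2, 1, tolerance = 1e-9)
  expect_lt(st$rmse, 1e-9)
  expect_error(fit_pls(X, rep(1, 20), 3L), "constant")
  expect_error(fit_pls(X, y, 20L), "< number of rows")
})

test_that("factor-score and collapsed-coefficient predictions agree", {
  set.seed(44)
  X <- matrix(stats::rnorm(25 * 10), 25, 10)
  y <- X %*% stats::rnorm(10) + stats::rnorm(25, sd = 0.5)
  model <- fit_pls(X, y, n_factors = 5L)
  Xc <- sweep(X, 2, model$means_x)
  for (a in 1:5) {
    scores <- Xc %*% model$W[, 1:a, drop = FALSE] %*%
      solve(crossprod(model$P[, 1:a, drop = FALSE],
                      model$W[, 1:a, drop = FALSE]))
    via_scores <- model$mean_y + scores %*% model$q[1:a]
    expect_equal(as.numeric(via_scores), model$fitted[, a],
                 tolerance = 1e-8)
  }
})

test_that("prediction policies: centering identity and training consistency", {
  set.seed(45)
  rows <- lapply(1:12, function(i) sort(sample(1:40, 8)))
  g <- build_grid(list(matrix(0, 1, 3)), spacing = 1, margin = 4)
  fm <- assemble_matrix(rows, sprintf("m%02d", 1:12), g,
                        min_occupancy = 2L)
  y <- stats::rnorm(12, 6, 1)
  model <- fit_pls(fm, y, n_factors = 3L)
  # all-zero row predicts the intercept
  expect_equal(predict_pls(model, list(integer(0))),
               model$intercepts[3], tolerance = 1e-10)
  # a training row reproduces its stored fitted value
  expect_equal(predict_pls(model, rows[3]), model$fitted[3, 3],
               tolerance = 1e-10)
  # column permutation of the input leaves predictions unchanged
  perm <- sample(length(fm$col_ids))
  fmp <- fm; fmp$X <- fm$X[, perm]; fmp$col_ids <- fm$col_ids[perm]
  # reorder back to ascending ids as assemble_matrix guarantees
  ord <- order(fmp$col_ids)
  fmp$X <- fmp$X[, ord]; fmp$col_ids <- fmp$col_ids[ord]
  mp <- fit_pls(fmp, y, n_factors = 3L)
  expect_equal(predict_pls(mp, rows), predict_pls(model, rows),
               tolerance = 1e-9)
  expect_error(predict_pls(model, matrix(0, 1, 3)), "grid mismatch")
})

test_that("the statistics panel matches hand-evaluated formulas", {
  st <- regression_stats(c(6, 7, 8), c(6.1, 6.9, 8.0), 1)
  expect_equal(st$rmse, sqrt(0.02 / 3), tolerance = 1e-9)
  expect_equal(st$rmse, 0.0816, tolerance = 1e-3)
  expect_equal(st$pearson_r, 0.9959, tolerance = 1e-4)
  expect_equal(st$r2, 1 - 0.02 / 2, tolerance = 1e-9)
  ident <- regression_stats(c(6, 7, 8, 9), c(6, 7, 8, 9), 2)
  expect_equal(ident$r2, 1)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$pearson_r, 1)
  expect_error(regression_stats(c(1, 1, 1), c(1, 2, 3), 1), "variance")
  # the variance-ratio F recomputed from the rounded headline r2 of a
  # 253-compound, 7-factor fit lands within 1% of the printed 357.9
  expect_equal(f_from_r2(0.911, 253, 7), 357.9, tolerance = 0.01)
})

test_that("cross-validation Q2 behaves at both extremes and is seeded", {
  set.seed(46)
  X <- matrix(stats::rnorm(40 * 6), 40, 6)
  y_perf <- as.numeric(X %*% c(2, -1, 1, 0.5, -0.5, 1))
  cv <- cross_validate(X, y_perf, n_factors = 6L, folds = 5L, seed = 1)
  expect_equal(cv$q2[6], 1, tolerance = 1e-8)
  # pure noise: Q2 stays near or below zero (definition-based oracle:
  # PRESS can only exceed the fold-mean baseline in expectation)
  q2_noise <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      Xn <- matrix(stats::rnorm(200 * 10), 200, 10)
      yn <- stats::rnorm(200)
      cross_validate(Xn, yn, n_factors = 3L, folds = 10L, seed = s)$q2[3]
    })
  }, 0)
  expect_lt(max(q2_noise), 0.1)
  cv2 <- cross_validate(X, y_perf, n_factors = 6L, folds = 5L, seed = 1)
  expect_identical(cv$q2, cv2$q2)
  expect_error(cross_validate(X, y_perf, folds = 1L), "folds")
})

test_that("Q2 equals a from-scratch evaluation of its definition", {
  set.seed(47)
  X <- matrix(stats::rnorm(30 * 5), 30, 5)
  y <- as.numeric(X %*% c(1, 2, 0, -1, 0.5)) + stats::rnorm(30, sd = 0.5)
  folds <- 5L; seed <- 9L
  cv <- cross_validate(X, y, n_factors = 2L, folds = folds, seed = seed)
  fold_of <- withr::with_seed(seed, sample(rep(seq_len(folds),
                                               length.out = 30)))
  press <- 0; denom <- 0
  for (f in seq_len(folds)) {
    held <- which(fold_of == f); tr <- setdiff(1:30, held)
    m <- fit_pls(X[tr, ], y[tr], n_factors = 2L)
    yh <- predict_pls(m, X[held, , drop = FALSE], n_factors = 2L)
    press <- press + sum((y[held] - yh)^2)
    denom <- denom + sum((y[held] - mean(y[tr]))^2)
  }
  expect_equal(cv$q2[2], 1 - press / denom, tolerance = 1e-12)
})

test_that("coefficient volumes carry planted signs and flip with y", {
  set.seed(48)
  rows <- lapply(1:14, function(i) sort(sample(1:60, 10)))
  g <- build_grid(list(matrix(0, 1, 3)), spacing = 1, margin = 4)
  fm <- assemble_matrix(rows, sprintf("m%02d", 1:14), g,
                        min_occupancy = 2L)
  target <- fm$col_ids[5]
  y <- vapply(rows, function(r) as.numeric(target %in% r), 0) +
    stats::rnorm(14, sd = 0.01)
  model <- fit_pls(fm, y, n_factors = 2L)
  vol <- coefficient_volumes(model, quantile_threshold = 0.95)
  ctr <- phore3d:::grid_cube_centers(
    g, (target - 1L) %% prod(g$dims) + 1L)
  expect_true(any(vol$sign == 1 &
                    abs(vol$x - ctr[1]) < 1e-9 &
                    abs(vol$y - ctr[2]) < 1e-9 &
                    abs(vol$z - ctr[3]) < 1e-9))
  mflip <- fit_pls(fm, -y, n_factors = 2L)
  vflip <- coefficient_volumes(mflip, quantile_threshold = 0.95)
  expect_equal(vflip$sign, -vol$sign)
  expect_lte(nrow(coefficient_volumes(model, 1.0)), 1L)
})
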