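test_that("the enrichment metrics reproduce the worked screening example", {
  # hit list of 50 from a 7,361-compound database holding 111 actives,
  # 39 of them retrieved
  expect_equal(enrichment_factor(39, 50, 111, 7361), 51.726,
               tolerance = 1e-4)
  expect_equal(goodness_of_hit(39, 50, 111, 7361), 0.6718,
               tolerance = 1e-4)
  expect_equal(yield_of_actives(39, 50), 78.0)
  expect_equal(ratio_of_actives(39, 111), 35.135, tolerance = 1e-3)
})

test_that("metric limits: ideal, null and no-enrichment cases", {
  expect_equal(enrichment_factor(10, 10, 100, 100), 1.0)
  expect_equal(enrichment_factor(0, 50, 111, 7361), 0.0)
  expect_equal(goodness_of_hit(50, 50, 50, 7361), 1.0)
  expect_equal(goodness_of_hit(0, 50, 111, 7361), 0.0)
  expect_equal(yield_of_actives(0, 50), 0)
  expect_equal(yield_of_actives(50, 50), 100)
  expect_equal(ratio_of_actives(111, 111), 100)
  expect_equal(ratio_of_actives(0, 111), 0)
  expect_error(enrichment_factor(60, 50, 111, 7361), "exceed")
  expect_error(enrichment_factor(39, 50, 111, 100), "exceed")
  expect_error(yield_of_actives(1, 0), "positive")
  expect_error(goodness_of_hit(10, 10, 20, 20), "d > a")
})

test_that("EF obeys its algebraic identity on random valid tuples", {
  set.seed(51)
  for (i in 1:200) {
    d <- sample(2:5000, 1)
    a <- sample(seq_len(d - 1), 1)
    ht <- sample(seq_len(d), 1)
    ha_rng <- max(0, ht - (d - a)):min(a, ht)
    ha <- ha_rng[sample.int(length(ha_rng), 1)]
    expect_equal(enrichment_factor(ha, ht, a, d) * (a / d), ha / ht,
                 tolerance = 1e-12)
  }
})

test_that("GH stays within [0, 1] on valid screening contingencies", {
  set.seed(52)
  for (i in 1:300) {
    d <- sample(3:200, 1); a <- sample(seq_len(d - 1), 1)
    ht <- sample(seq_len(d), 1)
    ha_rng <- max(0, ht - (d - a)):min(a, ht)
    ha <- ha_rng[sample.int(length(ha_rng), 1)]
    gh <- goodness_of_hit(ha, ht, a, d)
    expect_gte(gh, -1e-12); expect_lte(gh, 1 + 1e-12)
  }
  # a hit list holding more inactives than the database is rejected
  expect_error(goodness_of_hit(1, 9, 5, 10), "cannot exceed d - a")
})

test_that("AUC equals the brute-force pair count and handles ties", {
  # 2 actives {0.9, 0.4} vs 2 decoys {0.7, 0.1}: 3 of 4 pairs correct
  r <- roc_curve_auc(c(0.9, 0.4, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_equal(trapezoid_auc(r$roc), 0.75, tolerance = 1e-12)
  # perfect separation and complete ties
  expect_equal(roc_curve_auc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE,
                                              FALSE))$auc, 1.0)
  expect_equal(roc_curve_auc(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE,
                                          FALSE, TRUE))$auc, 0.5)
  expect_error(roc_curve_auc(1:3, c(TRUE, TRUE, TRUE)), "at least one")
  set.seed(53)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    act <- stats::runif(n) < 0.4
    if (!any(act) || all(act)) next
    r <- roc_curve_auc(sc, act)
    expect_equal(r$auc, pairwise_auc(sc, act), tolerance = 1e-12)
    expect_equal(trapezoid_auc(r$roc), r$auc, tolerance = 1e-10)
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
    expect_equal(unlist(r$roc[nrow(r$roc), ]), c(fpr = 1, tpr = 1))
    # invariance under strictly monotone transforms of the scores
    expect_equal(roc_curve_auc(exp(3 * sc), act)$auc, r$auc,
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  sc <- stats::rnorm(80)
  act <- stats::runif(80) < 0.3
  expect_equal(roc_curve_auc(sc, act)$auc,
               as.numeric(pROC::auc(pROC::roc(act, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("enrichment reports echo injected counts and handle extremes", {
  set.seed(55)
  # a ranked table with the worked example's counts: 39 of the top 50 are
  # active, 72 more actives below, database of 7,361
  d <- 7361; a <- 111
  is_active <- c(stats::runif(50) < 2, rep(FALSE, d - 50))  # top-50 seed
  is_active[1:50] <- FALSE; is_active[sample(1:50, 39)] <- TRUE
  is_active[sample(51:d, a - 39)] <- TRUE
  df <- data.frame(id = sprintf("m%05d", 1:d),
                   pred_pKi = seq(9, 2, length.out = d),
                   is_active = is_active)
  rep50 <- enrichment_report(df, cutoff = 50)
  expect_equal(rep50$ha, 39L)
  expect_equal(rep50$ef, 51.726, tolerance = 1e-3)
  expect_equal(rep50$gh, 0.6718, tolerance = 1e-3)
  expect_equal(rep50$pct_ya, 78)
  expect_equal(rep50$pct_ra, 35.135, tolerance = 1e-3)
  # whole-database hit list retrieves everything: EF = 1
  repd <- enrichment_report(df, cutoff = d)
  expect_equal(repd$ha, a)
  expect_equal(repd$ef, 1.0)
  expect_error(enrichment_report(df, cutoff = 0), "cutoff")
  # default cutoff is ~1% of the database
  expect_equal(enrichment_report(df)$ht, ceiling(0.01 * d))
})
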