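test_that("planted hypotheses are AHPRR, Euclidean and seed-sensitive", {
  h1 <- plant_hypothesis(1)
  expect_equal(h1$label, "AHPRR")
  dd <- h1$dist
  expect_true(all(dd[upper.tri(dd)] >= 3 & dd[upper.tri(dd)] <= 12))
  # triangle inequality (Euclidean construction)
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-9)
  }
  h2 <- plant_hypothesis(2)
  expect_gt(max(abs(h1$dist - h2$dist)), 0.1)
  expect_identical(plant_hypothesis(1)$dist, h1$dist)
})

test_that("zero-jitter actives match the planted hypothesis exactly", {
  spec <- synthetic_spec(seed = 3, n_actives = 6, n_decoys = 5,
                         site_jitter_sigma = 0)
  hyp <- plant_hypothesis(spec$seed)
  acts <- generate_actives(spec, hyp)
  for (en in ligand_entries(acts)) {
    m <- match_ligand(hyp, en, min_sites = 5L)
    expect_equal(m$rmsd, 0, tolerance = 1e-8)
  }
})

test_that("jittered actives all match at the working tolerance", {
  spec <- synthetic_spec(seed = 4, n_actives = 50, n_decoys = 5,
                         site_jitter_sigma = 0.3)
  hyp <- plant_hypothesis(spec$seed)
  acts <- generate_actives(spec, hyp)
  hits <- vapply(ligand_entries(acts), function(en) {
    !is.null(match_ligand(hyp, en, min_sites = 5L, tol = 2.0))
  }, TRUE)
  expect_equal(mean(hits), 1.0)
  # distractor sites never coincide with planted ones
  for (mol in acts[1:10]) {
    s <- mol$sites
    planted <- as.matrix(s[1:5, c("x", "y", "z")])
    extra <- as.matrix(s[-(1:5), c("x", "y", "z")])
    if (nrow(extra)) {
      expect_gt(min(as.matrix(stats::dist(rbind(planted, extra)))[
        1:5, 5 + seq_len(nrow(extra))]), 1.0)
    }
  }
})

test_that("decoys are property-matched but lack the full pharmacophore", {
  spec <- synthetic_spec(seed = 5, n_actives = 50, n_decoys = 500)
  hyp <- plant_hypothesis(spec$seed)
  acts <- generate_actives(spec, hyp)
  dec <- generate_decoys(spec, hyp, acts)
  # ids disjoint
  expect_length(intersect(vapply(acts, `[[`, "", "id"),
                          vapply(dec, `[[`, "", "id")), 0L)
  # atom-class histograms agree (total variation distance <= 0.1)
  hist_of <- function(mols) {
    tab <- table(factor(unlist(lapply(mols, `[[`, "atom_class")),
                        levels = c("D", "H", "N", "P", "W", "X")))
    tab / sum(tab)
  }
  tvd <- sum(abs(hist_of(acts) - hist_of(dec))) / 2
  expect_lte(tvd, 0.1)
  # mean atom counts agree within 10%
  na <- mean(vapply(acts, function(m) nrow(m$atoms), 0))
  nd <- mean(vapply(dec, function(m) nrow(m$atoms), 0))
  expect_lte(abs(na - nd) / na, 0.1)
  # complete-pharmacophore match rate at the default tolerance <= 5%
  rate <- mean(vapply(ligand_entries(dec), function(en) {
    !is.null(match_ligand(hyp, en, min_sites = 5L, tol = 2.0))
  }, TRUE))
  expect_lte(rate, 0.05)
})

test_that("planted activities follow the linear model and the Ki window", {
  spec0 <- synthetic_spec(seed = 6, n_actives = 10, n_decoys = 5,
                          noise_sigma = 0,
                          activity_coefficients = c(2))
  hyp <- plant_hypothesis(spec0$seed)
  acts <- generate_actives(spec0, hyp)
  dec <- generate_decoys(spec0, hyp, acts)
  out <- assign_activities(acts, dec, spec0)
  for (mol in out$actives) {
    expect_equal(mol$pki,
                 spec0$activity_intercept + 2 * as.numeric(mol$substituents),
                 tolerance = 1e-9)
  }
  # every decoy is inactive by construction
  expect_true(all(vapply(out$decoys, `[[`, "", "activity_class") ==
                    "inactive"))
  # default spec: active Ki spans >= 3 log units, inside the window
  spec <- synthetic_spec(seed = 7, n_actives = 120, n_decoys = 5)
  outd <- assign_activities(generate_actives(spec), generate_decoys(spec),
                            spec)
  pkis <- vapply(outd$actives, `[[`, 0, "pki")
  expect_gte(max(pkis) - min(pkis), 3)
  kis <- vapply(outd$actives, `[[`, 0, "ki")
  expect_true(all(kis >= spec$ki_range[1] - 1e-15 &
                    kis <= spec$ki_range[2] + 1e-15))
})

test_that("benchmark bundles are deterministic and self-consistent", {
  spec <- synthetic_spec(seed = 8, n_actives = 12, n_decoys = 6)
  d1 <- file.path(tempdir(), "bench_a"); d2 <- file.path(tempdir(), "bench_b")
  unlink(c(d1, d2), recursive = TRUE)
  b1 <- make_benchmark(spec, dir = d1)
  b2 <- make_benchmark(spec, dir = d2)
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
  expect_identical(readLines(file.path(d1, "actives.sdf")),
                   readLines(file.path(d2, "actives.sdf")))
  expect_error(make_benchmark(spec, dir = d1), "not empty")
  # bundle partitions: train + test = actives; labels consistent
  expect_length(b1$train, round(0.6 * 12))
  expect_length(c(b1$train, b1$test), 12L)
  # written bundle reloads with sites and classes intact
  back <- read_molecules(file.path(d1, "actives.sdf"), "sdf")
  expect_false(is.null(back[[1]]$sites))
  expect_false(is.null(back[[1]]$atom_class))
  expect_equal(back[[1]]$sites$kind[1:5], b1$actives[[1]]$sites$kind[1:5])
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a tiny bundle flows through hypothesis, QSAR and screening", {
  spec <- synthetic_spec(seed = 9, n_actives = 40, n_decoys = 60)
  res <- benchmark_pipeline(spec, n_screen_actives = 20)
  expect_equal(res$hypothesis$label, "AHPRR")
  expect_lte(hyp_dist_gap(res$hypothesis, res$bundle$hypothesis),
             res$bin_size)
  expect_equal(nrow(res$stats_table), res$model$n_factors)
  expect_true(all(res$stats_table$r2 >= 0 & res$stats_table$r2 <= 1))
  expect_gte(res$enrichment$auc, 0.8)
  # ranking is deterministic and ordered by the documented policy
  rk <- res$screen$ranking
  matched <- rk[!rk$no_match, ]
  expect_true(all(diff(matched$pred_pKi) <= 1e-12))
  expect_true(all(which(rk$no_match) > nrow(matched)))
})
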