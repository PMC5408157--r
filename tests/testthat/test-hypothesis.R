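make_entry <- function(id, xyz, kinds) {
  mol <- point_set_mol(id, xyz, rep("H", nrow(xyz)), kinds = kinds)
  ligand_entries(list(mol))[[1]]
}

test_that("the hypothesis label is a pure function of the kind multiset", {
  expect_equal(hypothesis_label(c("R", "A", "P", "R", "H")), "AHPRR")
  expect_equal(hypothesis_label(c("H", "A", "R", "P", "R")), "AHPRR")
  xyz <- matrix(stats::rnorm(15, sd = 3), 5, 3)
  h <- ph_hypothesis(data.frame(kind = c("R", "A", "P", "R", "H"),
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                dx = NA_real_, dy = NA_real_,
                                dz = NA_real_, atoms = ""))
  expect_equal(h$label, "AHPRR")
  expect_true(isSymmetric(h$dist))
  expect_equal(diag(h$dist), rep(0, 5))
})

test_that("identical molecules share every k-subset with zero spread", {
  set.seed(31)
  xyz <- matrix(stats::runif(12, 0, 8), 4, 3)
  kinds <- c("A", "H", "P", "R")
  e1 <- make_entry("m1", xyz, kinds)
  e2 <- make_entry("m2", xyz, kinds)
  hyps <- find_common_hypotheses(list(e1, e2), n_features = 3L,
                                 must_match = 1.0, bin_size = 1.0,
                                 score = FALSE)
  expect_length(hyps, choose(4, 3))
  for (h in hyps) {
    m <- match_ligand(h, e1, min_sites = 3L)
    expect_equal(m$rmsd, 0, tolerance = 1e-9)
  }
})

test_that("a molecule with n distinct sites yields choose(n, k) variants", {
  set.seed(32)
  xyz <- matrix(stats::runif(18, 0, 10), 6, 3)
  e <- make_entry("m1", xyz, c("A", "D", "H", "N", "P", "R"))
  vars <- phore3d:::enumerate_variants(list(e), 4L)
  expect_length(vars, choose(6, 4))
})

test_that("tree search equals brute-force enumeration on small instances", {
  set.seed(33)
  for (rep in 1:6) {
    n_mol <- sample(2:4, 1)
    base <- matrix(stats::runif(15, 0, 7), 5, 3)
    kinds5 <- c("A", "H", "P", "R", "R")
    entries <- lapply(seq_len(n_mol), function(i) {
      n_extra <- sample(0:1, 1)
      xyz <- base + matrix(stats::rnorm(15, sd = 0.1), 5, 3)
      kinds <- kinds5
      if (n_extra) {
        xyz <- rbind(xyz, stats::runif(3, 0, 7))
        kinds <- c(kinds, sample(c("A", "D", "H"), 1))
      }
      make_entry(sprintf("m%d", i), xyz, kinds)
    })
    mine <- find_common_hypotheses(entries, n_features = 4L,
                                   must_match = 0.75, bin_size = 1.0,
                                   score = FALSE)
    ref <- brute_force_hypotheses(entries, 4L, 0.75, 1.0)
    expect_length(mine, length(ref))
    if (length(mine)) {
      # every found hypothesis's canonical distance vector must lie in
      # exactly one reference box of the same label
      for (h in mine) {
        ok <- any(vapply(ref, function(r) {
          if (r$label != h$label) return(FALSE)
          k <- nrow(h$sites)
          ut <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
          ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
          dv <- h$dist[ut]
          any(apply(r$dvecs, 1, function(x) max(abs(x - dv)) < 1e-9))
        }, TRUE))
        expect_true(ok)
      }
    }
  }
})

test_that("a planted geometry is recovered from rigid point-set actives", {
  set.seed(34)
  hyp0 <- plant_hypothesis(99)
  xyz0 <- as.matrix(hyp0$sites[, c("x", "y", "z")])
  entries <- lapply(1:5, function(i) {
    extra <- stats::runif(3, -4, 4)
    xyz <- rbind(xyz0, extra)
    rot <- random_rot3()
    xyz <- sweep(xyz %*% rot, 2, stats::runif(3, -10, 10), `+`)
    make_entry(sprintf("m%d", i), xyz,
               c(hyp0$sites$kind, sample(c("D", "N"), 1)))
  })
  hyps <- find_common_hypotheses(entries, n_features = 5L,
                                 must_match = 1.0, bin_size = 1.0)
  expect_gte(length(hyps), 1L)
  top <- hyps[[1]]
  expect_equal(top$label, "AHPRR")
  expect_lt(hyp_dist_gap(top, hyp0), 1e-6)
})

test_that("matching finds the self-correspondence and respects kinds", {
  hyp <- plant_hypothesis(7)
  xyz <- as.matrix(hyp$sites[, c("x", "y", "z")])
  self <- make_entry("self", xyz, hyp$sites$kind)
  m <- match_ligand(hyp, self, min_sites = 5L)
  expect_equal(m$n_matched, 5L)
  expect_equal(m$rmsd, 0, tolerance = 1e-9)
  # remove the positive ionizable site: full match impossible
  nop <- make_entry("nop", xyz[hyp$sites$kind != "P", , drop = FALSE],
                    hyp$sites$kind[hyp$sites$kind != "P"])
  expect_null(match_ligand(hyp, nop, min_sites = 5L))
  # but a 4-of-5 match remains, on the planted correspondence
  m4 <- match_ligand(hyp, nop, min_sites = 4L)
  expect_equal(m4$n_matched, 4L)
  expect_equal(m4$rmsd, 0, tolerance = 1e-9)
  expect_false("P" %in% hyp$sites$kind[m4$hyp_sites])
})

test_that("alignment inverts a known rotation and is rigid-invariant", {
  set.seed(35)
  hyp <- plant_hypothesis(5)
  xyz <- as.matrix(hyp$sites[, c("x", "y", "z")])
  rot <- random_rot3(); shift <- c(3, -7, 2)
  entry <- make_entry("rot", sweep(xyz %*% rot, 2, shift, `+`),
                      hyp$sites$kind)
  m <- match_ligand(hyp, entry, min_sites = 5L)
  expect_equal(m$rmsd, 0, tolerance = 1e-8)
  al <- align_ligand(hyp, m, entry)
  expect_equal(al$sites_aligned[, c("x", "y", "z")],
               hyp$sites[, c("x", "y", "z")],
               tolerance = 1e-6, ignore_attr = TRUE)
  # rmsd invariant under any further rigid pre-transform
  entry2 <- make_entry("rot2",
                       sweep(sweep(xyz %*% rot, 2, shift, `+`) %*%
                               random_rot3(), 2, c(1, 1, 1), `+`),
                       hyp$sites$kind)
  m2 <- match_ligand(hyp, entry2, min_sites = 5L)
  expect_equal(m2$rmsd, m$rmsd, tolerance = 1e-8)
  expect_error(align_ligand(hyp, NULL, entry), "no match")
})

test_that("noisy-site alignment RMSD matches the quaternion oracle", {
  set.seed(36)
  hyp <- plant_hypothesis(3)
  xyz <- as.matrix(hyp$sites[, c("x", "y", "z")])
  for (rep in 1:8) {
    noisy <- xyz + matrix(stats::rnorm(15, sd = 0.3), 5, 3)
    entry <- make_entry("n", noisy, hyp$sites$kind)
    m <- match_ligand(hyp, entry, min_sites = 5L)
    # oracle on the matched correspondence
    ref <- quaternion_superpose_rmsd(noisy[m$lig_sites, , drop = FALSE],
                                     xyz[m$hyp_sites, , drop = FALSE])
    expect_lte(m$rmsd, ref + 1e-9)
  }
})

test_that("scores reward perfect alignment and scale linearly", {
  hyp <- plant_hypothesis(11)
  xyz <- as.matrix(hyp$sites[, c("x", "y", "z")])
  entries <- lapply(1:3, function(i) make_entry(sprintf("m%d", i), xyz,
                                                hyp$sites$kind))
  s <- score_hypothesis(hyp, entries)
  expect_equal(s, 3, tolerance = 1e-9)
  s2 <- score_hypothesis(hyp, entries, w_align = 2)
  expect_equal(s2 - s, 1, tolerance = 1e-9)  # alignment term is 1 here
  expect_error(score_hypothesis(hyp, list(make_entry(
    "x", matrix(stats::rnorm(9), 3, 3), c("D", "D", "D")))), "no ligand")
})

test_that("jittering active geometry lowers the score in expectation", {
  set.seed(37)
  hyp <- plant_hypothesis(13)
  xyz <- as.matrix(hyp$sites[, c("x", "y", "z")])
  clean <- lapply(1:4, function(i) make_entry(sprintf("c%d", i), xyz,
                                              hyp$sites$kind))
  s_clean <- score_hypothesis(hyp, clean)
  s_noisy <- mean(replicate(25, {
    noisy <- lapply(1:4, function(i) {
      make_entry(sprintf("n%d", i),
                 xyz + matrix(stats::rnorm(15, sd = 0.3), 5, 3),
                 hyp$sites$kind)
    })
    score_hypothesis(hyp, noisy)
  }))
  expect_lt(s_noisy, s_clean)
})
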