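test_that("bootstrap z handles degenerate and well-separated samples", {
  # identical constant samples: all replica differences are 0
  res <- bootstrap_mean_difference(c(1, 1, 1), c(1, 1, 1), n_replicas = 200, seed = 1)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  # far-apart samples: z >> 0 and p below 1e-6
  res2 <- bootstrap_mean_difference(c(10, 11, 12), c(0, 1, 2),
                                    n_replicas = 5000, seed = 2)
  expect_gt(res2$z, 5)
  expect_lt(res2$p, 1e-6)
  # constant but different samples: zero variance, certain sign
  res3 <- bootstrap_mean_difference(c(2, 2), c(1, 1), n_replicas = 100, seed = 3)
  expect_equal(res3$p, 0)
  expect_gt(res3$z, 0)
})

test_that("undersized samples yield a missing marker, not an error", {
  res <- bootstrap_mean_difference(1, c(1, 2, 3), seed = 1)
  expect_true(res$missing)
  expect_true(is.na(res$z))
  expect_error(bootstrap_mean_difference(1:3, 1:4, paired = TRUE), "equal length")
})

test_that("swapping samples negates z exactly under mirrored seed streams", {
  a <- rnorm(12, mean = 1); b <- rnorm(20)
  seeds <- c(101L, 202L)
  r1 <- bootstrap_mean_difference(a, b, n_replicas = 400, seeds = seeds)
  r2 <- bootstrap_mean_difference(b, a, n_replicas = 400, seeds = rev(seeds))
  expect_equal(r1$z, -r2$z)
  expect_equal(r1$p, r2$p)
  # paired comparisons mirror under the same seed
  p1 <- bootstrap_mean_difference(a, a + rnorm(12), n_replicas = 400,
                                  paired = TRUE, seed = 5)
  p2 <- bootstrap_mean_difference(a + rnorm(12), a, n_replicas = 400,
                                  paired = TRUE, seed = 5)
  expect_equal(abs(p1$z) > 0, abs(p2$z) > 0)
})

test_that("bootstrap results are reproducible under a fixed seed", {
  a <- rnorm(15); b <- rnorm(15)
  r1 <- bootstrap_mean_difference(a, b, n_replicas = 1000, seed = 42)
  r2 <- bootstrap_mean_difference(a, b, n_replicas = 1000, seed = 42)
  expect_identical(r1, r2)
})

test_that("Bonferroni level reproduces 0.05/56 at the default configuration", {
  expect_equal(bonferroni_level(), 0.05 / 56)
  expect_equal(round(bonferroni_level(), 7), 8.929e-4, tolerance = 1e-4)
  expect_equal(bonferroni_level(2, 4, 0.04), 0.005)
  expect_equal(bonferroni_level() * 56, 0.05)
})

test_that("orientation flips leave hypothesis verdicts unchanged", {
  # curvature: lower = more central; multiplying by -1 and treating it as an
  # ordinary metric must give the same direction verdict
  set.seed(8)
  a <- rnorm(30, mean = -5) # "curvature" of a central set (negative)
  b <- rnorm(30, mean = 0)
  res_c <- egotopo:::compare_one(a, b, "C", 1000, 0.05, seed = 1)
  res_flip <- egotopo:::compare_one(-a, -b, "N", 1000, 0.05, seed = 1)
  expect_equal(res_c$direction, res_flip$direction)
  expect_equal(res_c$direction, 1L)
})

test_that("patient-level tests produce one row per band-metric-pair", {
  coh <- generate_cohort(n_patients = 2, sf_fraction = 0.5, n_nodes = 30,
                         bands = c("B", "theta"), seed = 31)
  res <- patient_tests(coh$patients[[1]], n_replicas = 200, seed = 1)
  expect_equal(nrow(res), 2 * 8 * 4)
  expect_equal(unique(res$alpha_prime), 0.05 / 16)
  # explicit n_tests keeps the full-study correction under subset runs
  res56 <- patient_tests(coh$patients[[1]], bands = "B", n_replicas = 200,
                         n_tests = 56, seed = 1)
  expect_equal(unique(res56$alpha_prime), 0.05 / 56)
  expect_true(all(res56$p[res56$significant] < 0.05 / 56))
})

test_that("group-level tests are paired over patients and flag trivial nulls", {
  coh <- generate_cohort(n_patients = 6, sf_fraction = 0.5, n_nodes = 30,
                         bands = "B", seed = 41)
  sm <- cohort_set_means(coh, bands = "B")
  grp <- group_level_tests(sm, n_replicas = 500, n_tests = 56, seed = 3)
  expect_equal(nrow(grp), 8 * 4)
  expect_true(all(grp$n_patients <= 6))
  # equal set means for every patient: z = 0, p = 1
  fake <- sm
  fake$mean_value <- 1
  grp0 <- group_level_tests(fake, n_replicas = 200, n_tests = 56, seed = 3)
  expect_true(all(grp0$z[!grp0$missing] == 0))
  expect_true(all(grp0$p[!grp0$missing] == 1))
  # relabelling which set comes first negates z
  pairs_fwd <- tibble::tibble(set1 = "RA", set2 = "O")
  pairs_rev <- tibble::tibble(set1 = "O", set2 = "RA")
  g1 <- group_level_tests(sm, pairs = pairs_fwd, n_replicas = 500,
                          n_tests = 56, seed = 3)
  g2 <- group_level_tests(sm, pairs = pairs_rev, n_replicas = 500,
                          n_tests = 56, seed = 3)
  ok <- !g1$missing & !g2$missing
  expect_equal(sign(g1$z[ok]), -sign(g2$z[ok]))
})

test_that("cohort summary fractions count direction-consistent significance", {
  res <- tibble::tibble(
    patient_id = rep(c("a", "b", "c"), each = 1),
    band = "B", metric = "N", set1 = "RA", set2 = "O",
    significant = c(TRUE, TRUE, FALSE),
    direction = c(1L, -1L, 1L),
    missing = c(FALSE, FALSE, FALSE)
  )
  s <- cohort_summary_table(res)
  expect_equal(s$frac_positive, 1 / 3)
  expect_equal(s$frac_negative, 1 / 3)
  expect_equal(s$n_tested, 3)
})
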