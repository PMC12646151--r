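test_that("r scores encode significance and direction", {
  expect_equal(r_score(FALSE, 1L), 0L)
  expect_equal(r_score(TRUE, 1L), 1L)
  expect_equal(r_score(TRUE, -1L), -1L)
  expect_equal(r_score(TRUE, 1L, missing = TRUE), 0L)
  expect_equal(r_score(c(TRUE, TRUE, FALSE), c(1L, -1L, 1L)), c(1L, -1L, 0L))
})

test_that("distinguishability sums r scores per pair and combines three pairs", {
  grid <- tidyr::crossing(
    patient_id = "P1", band = "B", metric = ego_metrics(),
    tibble::tibble(set1 = c("RA", "RA", "RA", "N"),
                   set2 = c("RAbar", "N", "O", "O"))
  )
  res <- dplyr::mutate(grid,
                       significant = TRUE, direction = 1L, missing = FALSE)
  d <- distinguishability_scores(res)
  expect_equal(d$D[d$comparison == "RA>RAbar"], 8)
  expect_equal(d$D[d$comparison == "comb"], 24)
  # hand case: D(RA,N)=2, D(RA,O)=5, D(N,O)=6 -> D_comb = 13
  res2 <- dplyr::mutate(grid,
    significant = dplyr::case_when(
      set1 == "RA" & set2 == "N" ~ metric %in% c("N", "E"),
      set1 == "RA" & set2 == "O" ~ metric %in% c("N", "E", "b0", "b1", "b2"),
      set1 == "N" & set2 == "O" ~ metric %in% c("N", "E", "b0", "b1", "b2", "BC"),
      TRUE ~ FALSE
    ),
    direction = 1L,
    missing = FALSE
  )
  d2 <- distinguishability_scores(res2)
  expect_equal(d2$D[d2$comparison == "RA>N"], 2)
  expect_equal(d2$D[d2$comparison == "RA>O"], 5)
  expect_equal(d2$D[d2$comparison == "N>O"], 6)
  expect_equal(d2$D[d2$comparison == "comb"], 13)
  expect_true(all(abs(d2$D[d2$comparison != "comb"]) <= 8))
  # a significant result marked missing contributes nothing
  res3 <- dplyr::mutate(res2, missing = set1 == "RA" & set2 == "N")
  d3 <- distinguishability_scores(res3)
  expect_equal(d3$D[d3$comparison == "RA>N"], 0)
  expect_equal(d3$D[d3$comparison == "comb"], 11)
})

test_that("Mann-Whitney AUC matches hand cases and the ties rule", {
  expect_equal(roc_auc(c(2, 3, 0, 1), c("SF", "SF", "NSF", "NSF"))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("SF", "NSF"), 3))$auc, 0.5)
  # SF {1, 0}, NSF {0}: one win, one tie -> (1 + 0.5) / 2
  expect_equal(roc_auc(c(1, 0, 0), c("SF", "SF", "NSF"))$auc, 0.75)
  # node-level D' hand case: RA {5, 3} vs RAbar {4, 1, 1} -> 5/6
  expect_equal(egotopo:::mw_auc(c(5, 3, 4, 1, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               5 / 6)
  expect_error(roc_auc(1:3, rep("SF", 3)), "both outcome classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (k in 1:20) {
    scores <- round(rnorm(30), 1) # rounding forces ties
    labels <- sample(c("SF", "NSF"), 30, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    ours <- roc_auc(scores, labels)$auc
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("NSF", "SF"),
                                     direction = "<")))
    )
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("AUC is antisymmetric under label flips and invariant to monotone maps", {
  set.seed(23)
  scores <- rnorm(40)
  labels <- sample(c("SF", "NSF"), 40, replace = TRUE)
  auc <- roc_auc(scores, labels)$auc
  flipped <- roc_auc(scores, labels, positive = "NSF")$auc
  expect_equal(auc, 1 - flipped)
  expect_equal(roc_auc(exp(scores * 3) + 2, labels)$auc, auc)
  expect_equal(roc_auc(rank(scores), labels)$auc, auc)
})

test_that("the ROC curve is monotone from (0,0) to (1,1) and AUC matches it", {
  set.seed(9)
  scores <- sample(0:5, 25, replace = TRUE)
  labels <- sample(c("SF", "NSF"), 25, replace = TRUE)
  r <- roc_auc(scores, labels)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  # trapezoid area under the step curve equals the Mann-Whitney AUC
  area <- sum(diff(r$curve$fpr) * (r$curve$tpr[-1] + r$curve$tpr[-nrow(r$curve)]) / 2)
  expect_equal(area, r$auc)
})

test_that("bootstrap AUC confidence intervals behave at the extremes", {
  # perfect separation at decent n: CI collapses to [1, 1]
  sep <- roc_auc(c(rnorm(40, 10), rnorm(40)), rep(c("SF", "NSF"), each = 40),
                 n_replicas = 500, seed = 4)
  expect_equal(unname(sep$ci), c(1, 1))
  # random scores: CI straddles 0.5
  set.seed(10)
  rnd <- roc_auc(rnorm(91), sample(c("SF", "NSF"), 91, replace = TRUE,
                                   prob = c(0.68, 0.32)),
                 n_replicas = 2000, seed = 5)
  expect_lt(rnd$ci[1], 0.5)
  expect_gt(rnd$ci[2], 0.5)
  # determinism and CI ordering
  r1 <- roc_auc(rnorm(20), rep(c("SF", "NSF"), 10), n_replicas = 300, seed = 6)
  r2 <- roc_auc(rnorm(20), rep(c("SF", "NSF"), 10), n_replicas = 300, seed = 6)
  expect_lte(r1$ci[1], r1$ci[2])
  expect_equal(length(r1$replicates), 300)
})

test_that("tidy and glance summarise ROC objects", {
  r <- roc_auc(c(1, 2, 3, 4), c("NSF", "SF", "NSF", "SF"), n_replicas = 100, seed = 1)
  expect_named(generics::tidy(r), c("threshold", "fpr", "tpr"))
  g <- generics::glance(r)
  expect_equal(g$auc, r$auc)
  expect_equal(g$ci_low, r$ci[1])
})

test_that("pairwise AUC comparison uses overlap fractions and BH correction", {
  mk <- function(auc, reps) {
    structure(list(auc = auc, replicates = reps), class = "ego_roc")
  }
  # identical tests: p = 0.5 by symmetric overlap
  a <- mk(0.7, seq(0.6, 0.8, length.out = 100))
  self_p <- auc_pairwise_comparison(list(x = a, y = a))$p
  expect_equal(self_p, 0.5, tolerance = 0.02)
  # disjoint replicate distributions: p near 0
  lo <- mk(0.3, seq(0.25, 0.35, length.out = 100))
  hi <- mk(0.9, seq(0.85, 0.95, length.out = 100))
  expect_lt(auc_pairwise_comparison(list(lo = lo, hi = hi))$p[1], 0.01)
  # BH hand case: step-up thresholds k/4 * 0.05 = .0125, .025, .0375, .05;
  # 0.04 > 0.0375, so exactly the two smallest p-values are rejected
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.9), method = "BH") < 0.05,
               c(TRUE, TRUE, FALSE, FALSE))
  mixed <- auc_pairwise_comparison(list(lo = lo, hi = hi, lo2 = lo))
  expect_true(all(mixed$p_adj >= mixed$p - 1e-12))
})

test_that("node-level D' and downstream patient classification work end to end", {
  coh <- generate_cohort(n_patients = 6, sf_fraction = 0.5, n_nodes = 90,
                         bands = "B", ra_size = c(3, 5),
                         sf_scenario = effect_scenario("ra_hub", 2), seed = 71)
  dp <- node_auc_scores(coh, bands = "B")
  expect_setequal(unique(dp$metric), c(ego_metrics(), "strength"))
  expect_true(all(dp$d_prime >= 0 & dp$d_prime <= 1, na.rm = TRUE))
  # SF patients carry an RA hub: their RA>O D' for degree-like metrics is high
  man <- cohort_manifest(coh)
  strong <- dp[dp$metric == "N" & dp$comparison == "RA>O", ] |>
    dplyr::inner_join(man[, c("patient_id", "outcome")], by = "patient_id")
  expect_gt(mean(strong$d_prime[strong$outcome == "SF"], na.rm = TRUE),
            mean(strong$d_prime[strong$outcome == "NSF"], na.rm = TRUE))
  cls <- classify_outcomes(dp, man, score = "d_prime", n_replicas = 0)
  expect_true(all(c("band", "comparison", "metric", "auc") %in% names(cls)))
})
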