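#' r score of one comparison
#'
#' Collapses a comparison into +1 (significant after correction, in the
#' direction of the hypothesis that the first set is more central), -1
#' (significant against it) or 0 (not significant, or missing). The
#' orientation flip for the curvature is already encoded in the
#' comparison's `direction`.
#'
#' @param significant Logical vector.
#' @param direction Integer vector in \{-1, 0, 1\}.
#' @param missing Logical vector.
#' @return Integer vector in \{-1, 0, 1\}.
#' @export
r_score <- function(significant, direction, missing = FALSE) {
  n <- length(significant)
  missing <- rep_len(missing, n)
  direction <- rep_len(as.integer(direction), n)
  out <- integer(n)
  scored <- !(is.na(missing) | missing) & !is.na(significant) & significant
  out[scored] <- direction[scored]
  out
}

#' Distinguishability scores per patient
#'
#' Sums the r scores over the centrality metrics to a per-patient, per-band,
#' per-pair distinguishability score D (range -8..8 for the 8 default
#' metrics), and combines the three pairwise comparisons of the three-set
#' partition into `D_comb = D(RA,N) + D(RA,O) + D(N,O)` (range -24..24).
#' Missing comparisons contribute 0.
#'
#' @param results Output of [cohort_individual_tests()].
#' @return Tibble: `patient_id`, `band`, `comparison` (e.g. `"RA>N"` or
#'   `"comb"`), `D`.
#' @export
distinguishability_scores <- function(results) {
  d <- results |>
    dplyr::mutate(r = r_score(.data$significant, .data$direction, .data$missing)) |>
    dplyr::group_by(.data$patient_id, .data$band, .data$set1, .data$set2) |>
    dplyr::summarise(D = sum(.data$r), .groups = "drop") |>
    dplyr::mutate(comparison = paste0(.data$set1, ">", .data$set2)) |>
    dplyr::select("patient_id", "band", "comparison", "D")
  comb <- d |>
    dplyr::filter(.data$comparison %in% c("RA>N", "RA>O", "N>O")) |>
    dplyr::group_by(.data$patient_id, .data$band) |>
    dplyr::summarise(D = sum(.data$D), comparison = "comb", n_parts = dplyr::n(),
                     .groups = "drop")
  comb <- dplyr::select(dplyr::filter(comb, .data$n_parts == 3), -"n_parts")
  dplyr::bind_rows(d, comb) |>
    dplyr::arrange(.data$patient_id, .data$band, .data$comparison)
}

# Mann-Whitney AUC: probability that a positive-class score exceeds a
# negative-class score, ties counting one half (midranks).
mw_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Threshold-sweep ROC curve (for plotting; the AUC itself is Mann-Whitney).
roc_curve_points <- function(scores, positive) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- vapply(thr, function(t) {
    c(fpr = sum(!positive & scores >= t) / sum(!positive),
      tpr = sum(positive & scores >= t) / sum(positive))
  }, numeric(2))
  tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, pts["fpr", ]),
    tpr = c(0, pts["tpr", ])
  )
}

#' ROC classification of patients by a score
#'
#' Classifies patients into outcome classes from a numeric score, with the
#' seizure-free group as the positive class. The AUC is the Mann-Whitney
#' statistic (ties contribute one half), which equals the area under the
#' threshold-sweep ROC curve and is invariant under strictly increasing
#' transformations of the score. Optionally, a bootstrap resamples the
#' (score, label) rows with replacement `n_replicas` times to yield a
#' percentile confidence interval; replicates that lose one of the classes
#' are redrawn (and counted), keeping exactly `n_replicas` usable
#' replicates.
#'
#' @param scores Numeric patient scores.
#' @param labels Outcome labels (`"SF"`/`"NSF"` or any two levels).
#' @param positive The positive class label (default `"SF"`).
#' @param n_replicas Bootstrap replicates; 0 skips the bootstrap.
#' @param level Confidence level of the percentile interval (default 0.90).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `ego_roc`: AUC, curve points, replicate AUCs,
#'   confidence interval.
#' @export
#' @examples
#' roc_auc(c(2, 3, 0, 1), c("SF", "SF", "NSF", "NSF"))$auc # 1
roc_auc <- function(scores, labels, positive = "SF", n_replicas = 0,
                    level = 0.90, seed = 1) {
  stopifnot(length(scores) == length(labels), level > 0, level < 1)
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    stop("both outcome classes must be present for ROC analysis", call. = FALSE)
  }
  auc <- mw_auc(scores, pos)
  out <- list(auc = auc, curve = roc_curve_points(scores, pos),
              n = length(scores), positive = positive,
              replicates = NULL, ci = NULL, level = level,
              n_redrawn = 0L)
  if (n_replicas > 0) {
    n <- length(scores)
    reps <- numeric(n_replicas)
    redrawn <- 0L
    with_seed(derive_seed(seed, "auc-boot"), {
      for (r in seq_len(n_replicas)) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (any(pos[idx]) && !all(pos[idx])) break
          redrawn <- redrawn + 1L
        }
        reps[r] <- mw_auc(scores[idx], pos[idx])
      }
    })
    out$replicates <- reps
    out$ci <- unname(quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
    out$n_redrawn <- redrawn
  }
  class(out) <- "ego_roc"
  out
}

#' @export
print.ego_roc <- function(x, ...) {
  cat(sprintf("<ego_roc> AUC = %.3f (n = %d, positive = %s)", x$auc, x$n, x$positive))
  if (!is.null(x$ci)) {
    cat(sprintf(", %d%% CI [%.3f, %.3f]", round(100 * x$level), x$ci[1], x$ci[2]))
  }
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ROC result into its curve points
#'
#' @param x An `ego_roc`.
#' @param ... Unused.
#' @return Tibble of `threshold`, `fpr`, `tpr`.
#' @exportS3Method generics::tidy
tidy.ego_roc <- function(x, ...) x$curve

#' One-row summary of an ROC result
#'
#' @param x An `ego_roc`.
#' @param ... Unused.
#' @return Tibble with `auc`, `ci_low`, `ci_high`, `level`, `n`.
#' @exportS3Method generics::glance
glance.ego_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc,
                 ci_low = if (is.null(x$ci)) NA_real_ else x$ci[1],
                 ci_high = if (is.null(x$ci)) NA_real_ else x$ci[2],
                 level = x$level, n = x$n)
}

#' Pairwise comparison of AUCs via their bootstrap distributions
#'
#' For every pair of tests, each test's point AUC is compared against the
#' other's bootstrap replicate distribution: the p-value is the average of
#' the two crossing fractions — the share of the lower test's replicates at
#' or above the higher test's AUC, and the share of the higher test's
#' replicates at or below the lower test's AUC. Identical tests give p of
#' about 0.5 (each AUC sits in the middle of the other's distribution);
#' non-overlapping distributions give p near 0. P-values are then
#' FDR-corrected over the full grid with the Benjamini-Hochberg procedure
#' at threshold `q`.
#'
#' @param rocs Named list of `ego_roc` objects with bootstrap replicates.
#' @param q FDR threshold (default 0.05).
#' @return Tibble: `test_a`, `test_b`, `p`, `p_adj`, `significant`.
#' @export
auc_pairwise_comparison <- function(rocs, q = 0.05) {
  stopifnot(length(rocs) >= 2, !is.null(names(rocs)))
  for (r in rocs) {
    if (is.null(r$replicates)) {
      stop("all ROC results need bootstrap replicates", call. = FALSE)
    }
  }
  pairs <- utils::combn(names(rocs), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    lo <- if (rocs[[i]]$auc <= rocs[[j]]$auc) i else j
    hi <- if (identical(lo, i)) j else i
    p <- mean(c(mean(rocs[[lo]]$replicates >= rocs[[hi]]$auc),
                mean(rocs[[hi]]$replicates <= rocs[[lo]]$auc)))
    tibble::tibble(test_a = i, test_b = j, p = p)
  })
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < q
  out
}

#' Node-level AUC distinguishability (D')
#'
#' A continuous alternative to the sign-based r score: for each patient,
#' band, metric and node-set pair, D' is the Mann-Whitney AUC of separating
#' the first set's node-level metric values from the second's (first set
#' positive). The backbone node strength is included among the metrics for
#' this analysis. Patients are subsequently classified by D' with
#' [roc_auc()].
#'
#' @param cohort An `ego_cohort`.
#' @param bands,metrics,pairs,alpha,d As in [cohort_individual_tests()];
#'   `metrics` defaults to the 8 centrality metrics plus `"strength"`.
#' @return Tibble: `patient_id`, `band`, `metric`, `comparison`, `d_prime`
#'   (`NA` where a set is empty).
#' @export
node_auc_scores <- function(cohort, bands = NULL,
                            metrics = c(ego_metrics(), "strength"),
                            pairs = ego_pairs(), alpha = 0.1, d = 2) {
  stopifnot(inherits(cohort, "ego_cohort"))
  purrr::map_dfr(cohort$patients, function(patient) {
    pbands <- bands %||% names(patient$networks)
    purrr::map_dfr(pbands, function(band) {
      a <- disparity_filter(patient$networks[[band]], alpha = alpha)
      cent <- generalized_centrality(patient$networks[[band]], a, d = d)
      part <- partition_nodes(a, patient$ra_rois)
      purrr::map_dfr(metrics, function(metric) {
        mt <- dplyr::filter(cent, .data$metric == !!metric)
        purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
          v1 <- set_values(mt, part, pairs$set1[k])
          v2 <- set_values(mt, part, pairs$set2[k])
          dp <- if (length(v1) == 0 || length(v2) == 0) NA_real_ else {
            mw_auc(c(v1, v2), c(rep(TRUE, length(v1)), rep(FALSE, length(v2))))
          }
          tibble::tibble(patient_id = patient$patient_id, band = band,
                         metric = metric,
                         comparison = paste0(pairs$set1[k], ">", pairs$set2[k]),
                         d_prime = dp)
        })
      })
    })
  })
}

#' Classify surgical outcome from per-patient scores
#'
#' Joins a per-patient score table with outcome labels and runs
#' [roc_auc()] for each band x comparison (and metric, if present).
#'
#' @param score_tbl Tibble with `patient_id`, `band`, `comparison`, and a
#'   score column (`D` or `d_prime`).
#' @param manifest Output of [cohort_manifest()] (or any tibble with
#'   `patient_id` and `outcome`).
#' @param score Name of the score column (default `"D"`).
#' @param n_replicas,level,seed Passed to [roc_auc()].
#' @return Tibble with one row per test: grouping columns, `auc`, `ci_low`,
#'   `ci_high`, and the `ego_roc` objects in a list column `roc`.
#' @export
classify_outcomes <- function(score_tbl, manifest, score = "D",
                              n_replicas = 1e4, level = 0.90, seed = 1) {
  stopifnot(score %in% names(score_tbl))
  joined <- dplyr::inner_join(score_tbl,
                              dplyr::select(manifest, "patient_id", "outcome"),
                              by = "patient_id")
  group_cols <- intersect(c("band", "comparison", "metric"), names(joined))
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::group_modify(function(g, key) {
      r <- roc_auc(g[[score]], g$outcome, n_replicas = n_replicas,
                   level = level,
                   seed = derive_seed(seed, paste(unlist(key), collapse = "/")))
      tibble::tibble(auc = r$auc,
                     ci_low = if (is.null(r$ci)) NA_real_ else r$ci[1],
                     ci_high = if (is.null(r$ci)) NA_real_ else r$ci[2],
                     n = r$n, roc = list(r))
    }) |>
    dplyr::ungroup()
}
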