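#' Bootstrap z-score for a difference in means
#'
#' Draws `n_replicas` bootstrap resamples of each sample (independently for
#' unpaired data, jointly over index pairs for paired data), records the
#' difference of resampled means per replica, and summarizes the resulting
#' distribution by `z = mean(diffs) / sd(diffs)` with a two-tailed p-value
#' from the standard normal, `p = 2 (1 - Phi(|z|))`. If every replica
#' difference equals the same value delta, the normal approximation
#' degenerates and the limit is returned: `p = 1` when delta is 0, else
#' `p = 0`.
#'
#' Samples of fewer than two values cannot be compared; a missing-result
#' row (`missing = TRUE`, `z` and `p` `NA`) is returned rather than an
#' error, since node sets of size < 2 legitimately occur.
#'
#' @param a,b Numeric value samples. Paired comparison requires equal
#'   lengths.
#' @param n_replicas Number of bootstrap replicas (default 10^4).
#' @param paired Resample index pairs jointly instead of independently.
#' @param seed Integer seed; two child streams are derived from it, one per
#'   sample, so results are reproducible.
#' @param seeds Optional pair of explicit child seeds overriding `seed`
#'   (swapping `a`/`b` together with `seeds` negates `z` exactly).
#' @return One-row tibble: `z`, `p`, `mean_diff`, `n1`, `n2`, `missing`.
#' @export
#' @examples
#' bootstrap_mean_difference(c(10, 11, 12), c(0, 1, 2), seed = 1)
bootstrap_mean_difference <- function(a, b, n_replicas = 1e4, paired = FALSE,
                                      seed = 1, seeds = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  miss <- function() tibble::tibble(z = NA_real_, p = NA_real_,
                                    mean_diff = NA_real_, n1 = na, n2 = nb,
                                    missing = TRUE)
  if (na < 2 || nb < 2) return(miss())
  if (paired && na != nb) stop("paired samples must have equal length", call. = FALSE)
  if (is.null(seeds)) seeds <- c(derive_seed(seed, "sample", 1), derive_seed(seed, "sample", 2))
  stopifnot(length(seeds) == 2)
  if (paired) {
    idx <- with_seed(seeds[1], matrix(sample.int(na, na * n_replicas, replace = TRUE),
                                      na, n_replicas))
    diffs <- colMeans(matrix((a - b)[idx], na, n_replicas))
  } else {
    ia <- with_seed(seeds[1], matrix(sample.int(na, na * n_replicas, replace = TRUE),
                                     na, n_replicas))
    ib <- with_seed(seeds[2], matrix(sample.int(nb, nb * n_replicas, replace = TRUE),
                                     nb, n_replicas))
    diffs <- colMeans(matrix(a[ia], na, n_replicas)) -
      colMeans(matrix(b[ib], nb, n_replicas))
  }
  s <- sd(diffs)
  m <- mean(diffs)
  if (s == 0) {
    z <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    z <- m / s
    p <- 2 * (1 - pnorm(abs(z)))
  }
  tibble::tibble(z = z, p = p, mean_diff = mean(a) - mean(b),
                 n1 = na, n2 = nb, missing = FALSE)
}

#' Bonferroni-corrected significance level
#'
#' The per-test level obtained by dividing the base level by the number of
#' comparisons per patient (bands x metrics). At the defaults — 7 bands and
#' 8 metrics, 56 tests — this is 0.05 / 56, approximately 8.9e-4.
#'
#' @param n_bands,n_metrics Numbers of bands and metrics tested.
#' @param base_alpha Uncorrected significance level.
#' @return The corrected level alpha'.
#' @export
#' @examples
#' bonferroni_level() # 0.05 / 56
bonferroni_level <- function(n_bands = length(ego_bands()),
                             n_metrics = length(ego_metrics()),
                             base_alpha = 0.05) {
  stopifnot(n_bands >= 1, n_metrics >= 1, base_alpha > 0, base_alpha < 1)
  base_alpha / (n_bands * n_metrics)
}

# One set-pair comparison from node-level values; orientation flips the
# direction reading for metrics where low values mean central (curvature).
compare_one <- function(vals1, vals2, metric, n_replicas, alpha_prime, seed,
                        paired = FALSE) {
  res <- bootstrap_mean_difference(vals1, vals2, n_replicas = n_replicas,
                                   paired = paired, seed = seed)
  orient <- metric_orientation(metric)
  res$direction <- ifelse(res$missing | res$mean_diff == 0, 0L,
                          as.integer(sign(res$mean_diff) * orient))
  res$significant <- !res$missing & !is.na(res$p) & res$p < alpha_prime
  res$alpha_prime <- alpha_prime
  res
}

#' Individual-level node-set comparisons for one patient
#'
#' For each band, metric and node-set pair, tests whether the first set is
#' more central than the second via an unpaired bootstrap of the node-level
#' metric values, with Bonferroni correction over bands x metrics. For the
#' curvature the hypothesis direction is inverted (lower values = more
#' central). Comparisons where either set holds fewer than two nodes are
#' returned with `missing = TRUE`.
#'
#' @param patient An `ego_patient` (as inside an `ego_cohort`).
#' @param bands Bands to analyse; default all bands of the patient. The
#'   Bonferroni correction always uses `n_tests` (or its default, the full
#'   bands x metrics grid), so analysing a subset of bands does not loosen
#'   the threshold.
#' @param metrics Metrics to test; default [ego_metrics()].
#' @param pairs Node-set pairs; default [ego_pairs()].
#' @param alpha Disparity-filter level.
#' @param d Neighbourhood radius.
#' @param n_replicas Bootstrap replicas per test.
#' @param base_alpha Uncorrected significance level.
#' @param n_tests Number of comparisons for the Bonferroni correction;
#'   default `length(bands) * length(metrics)` computed on the full default
#'   configuration (7 x 8 = 56).
#' @param seed Integer seed.
#' @return Tibble: one row per band x metric x pair with `z`, `p`,
#'   `direction`, `significant`, `alpha_prime`, set sizes and `missing`.
#' @export
patient_tests <- function(patient, bands = NULL, metrics = ego_metrics(),
                          pairs = ego_pairs(), alpha = 0.1, d = 2,
                          n_replicas = 1e4, base_alpha = 0.05, n_tests = NULL,
                          seed = 1) {
  stopifnot(inherits(patient, "ego_patient"))
  if (is.null(bands)) bands <- names(patient$networks)
  if (is.null(n_tests)) n_tests <- length(names(patient$networks)) * length(metrics)
  alpha_prime <- base_alpha / n_tests
  purrr::map_dfr(bands, function(band) {
    w <- patient$networks[[band]]
    if (is.null(w)) stop("patient ", patient$patient_id, " has no band ", band,
                         call. = FALSE)
    a <- disparity_filter(w, alpha = alpha)
    cent <- generalized_centrality(w, a, d = d)
    part <- partition_nodes(a, patient$ra_rois)
    purrr::map_dfr(metrics, function(metric) {
      mt <- dplyr::filter(cent, .data$metric == !!metric)
      purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
        s1 <- pairs$set1[k]; s2 <- pairs$set2[k]
        res <- compare_one(
          set_values(mt, part, s1), set_values(mt, part, s2), metric,
          n_replicas, alpha_prime,
          seed = derive_seed(seed, patient$patient_id, band, metric, s1, s2)
        )
        dplyr::bind_cols(
          tibble::tibble(patient_id = patient$patient_id, band = band,
                         metric = metric, set1 = s1, set2 = s2),
          res
        )
      })
    })
  })
}

#' Individual-level comparisons for a whole cohort
#'
#' Runs [patient_tests()] for every patient.
#'
#' @param cohort An `ego_cohort`.
#' @inheritParams patient_tests
#' @return Tibble of all patients' comparison results.
#' @export
cohort_individual_tests <- function(cohort, bands = NULL, metrics = ego_metrics(),
                                    pairs = ego_pairs(), alpha = 0.1, d = 2,
                                    n_replicas = 1e4, base_alpha = 0.05,
                                    n_tests = NULL, seed = 1) {
  stopifnot(inherits(cohort, "ego_cohort"))
  purrr::map_dfr(cohort$patients, patient_tests, bands = bands,
                 metrics = metrics, pairs = pairs, alpha = alpha, d = d,
                 n_replicas = n_replicas, base_alpha = base_alpha,
                 n_tests = n_tests, seed = seed)
}

#' Per-patient node-set mean centralities
#'
#' For each patient, band, metric and node set, the mean metric value over
#' the set's nodes — the quantities compared at the group level. Empty sets
#' yield `NaN` means and are excluded pairwise downstream.
#'
#' @inheritParams cohort_individual_tests
#' @return Tibble: `patient_id`, `band`, `metric`, `set`, `mean_value`,
#'   `set_size`.
#' @export
cohort_set_means <- function(cohort, bands = NULL, metrics = ego_metrics(),
                             alpha = 0.1, d = 2) {
  stopifnot(inherits(cohort, "ego_cohort"))
  purrr::map_dfr(cohort$patients, function(patient) {
    pbands <- bands %||% names(patient$networks)
    purrr::map_dfr(pbands, function(band) {
      a <- disparity_filter(patient$networks[[band]], alpha = alpha)
      cent <- generalized_centrality(patient$networks[[band]], a, d = d) |>
        dplyr::filter(.data$metric %in% metrics)
      part <- partition_nodes(a, patient$ra_rois)
      sets <- tibble::tibble(set = c("RA", "N", "O", "RAbar"))
      tidyr::crossing(metric = metrics, sets) |>
        dplyr::mutate(
          patient_id = patient$patient_id, band = band,
          values = purrr::map2(.data$metric, .data$set, function(m, s) {
            set_values(dplyr::filter(cent, .data$metric == m), part, s)
          }),
          set_size = lengths(.data$values),
          mean_value = vapply(.data$values, function(v) mean(v), numeric(1)),
          values = NULL
        ) |>
        dplyr::select("patient_id", "band", "metric", "set", "set_size", "mean_value")
    })
  })
}

#' Group-level node-set comparisons
#'
#' Paired bootstrap over patients of the per-patient set means: for each
#' band, metric and node-set pair, patients contribute the difference of
#' their two set means; patients missing either set are excluded pairwise.
#' Bonferroni correction as in [patient_tests()].
#'
#' @param set_means Output of [cohort_set_means()].
#' @inheritParams patient_tests
#' @return Tibble: one row per band x metric x pair, with `n_patients`
#'   used in each test.
#' @export
group_level_tests <- function(set_means, pairs = ego_pairs(), n_replicas = 1e4,
                              base_alpha = 0.05, n_tests = NULL, seed = 1) {
  bands <- unique(set_means$band)
  metrics <- unique(set_means$metric)
  if (is.null(n_tests)) n_tests <- length(bands) * length(metrics)
  alpha_prime <- base_alpha / n_tests
  wide <- tidyr::pivot_wider(set_means, id_cols = c("patient_id", "band", "metric"),
                             names_from = "set", values_from = "mean_value")
  purrr::map_dfr(bands, function(band) {
    purrr::map_dfr(metrics, function(metric) {
      sub <- dplyr::filter(wide, .data$band == !!band, .data$metric == !!metric)
      purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
        s1 <- pairs$set1[k]; s2 <- pairs$set2[k]
        v1 <- sub[[s1]]; v2 <- sub[[s2]]
        ok <- is.finite(v1) & is.finite(v2)
        res <- if (sum(ok) >= 2) {
          # seed keyed on the unordered pair: reversing the hypothesis reuses
          # the same resampling indices, so z is negated exactly
          compare_one(v1[ok], v2[ok], metric, n_replicas, alpha_prime,
                      seed = derive_seed(seed, "group", band, metric,
                                         paste(sort(c(s1, s2)), collapse = "-")),
                      paired = TRUE)
        } else {
          tibble::tibble(z = NA_real_, p = NA_real_, mean_diff = NA_real_,
                         n1 = sum(ok), n2 = sum(ok), missing = TRUE,
                         direction = 0L, significant = FALSE,
                         alpha_prime = alpha_prime)
        }
        dplyr::bind_cols(
          tibble::tibble(scope = "group", band = band, metric = metric,
                         set1 = s1, set2 = s2, n_patients = sum(ok)),
          res
        )
      })
    })
  })
}

#' Cohort summary of individual-level tests
#'
#' For every band, metric and node-set pair: the fraction of patients whose
#' comparison was significant in the direction of the hypothesis and the
#' fraction significant against it, over patients with a non-missing
#' comparison.
#'
#' @param results Output of [cohort_individual_tests()].
#' @return Tibble with `frac_positive`, `frac_negative`, `n_tested`,
#'   `n_missing` per cell.
#' @export
cohort_summary_table <- function(results) {
  results |>
    dplyr::group_by(.data$band, .data$metric, .data$set1, .data$set2) |>
    dplyr::summarise(
      n_tested = sum(!.data$missing),
      n_missing = sum(.data$missing),
      frac_positive = ifelse(n_tested > 0,
                             sum(.data$significant & .data$direction > 0) / n_tested, NA_real_),
      frac_negative = ifelse(n_tested > 0,
                             sum(.data$significant & .data$direction < 0) / n_tested, NA_real_),
      .groups = "drop"
    )
}
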