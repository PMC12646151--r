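#' Pipeline configuration
#'
#' Collects the tunable parameters of the full analysis. The Bonferroni
#' test count is always `length(bands) * length(metrics)`; at the defaults
#' (7 bands, 8 metrics) this is 56 and the corrected level is 0.05/56.
#'
#' @param alpha Disparity-filter significance level.
#' @param d Extended-neighbourhood radius.
#' @param bands Band labels analysed.
#' @param metrics Generalized centrality metrics tested.
#' @param pairs Node-set pairs tested.
#' @param n_replicas Bootstrap replicas for set comparisons and AUC CIs.
#' @param ci_level AUC confidence level.
#' @param base_alpha Uncorrected significance level.
#' @param seed Master seed for all stochastic stages.
#' @return A list of class `ego_config` with derived fields `n_tests` and
#'   `alpha_prime`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$n_tests      # 56
#' cfg$alpha_prime  # 0.05 / 56
pipeline_config <- function(alpha = 0.1, d = 2, bands = ego_bands(),
                            metrics = ego_metrics(), pairs = ego_pairs(),
                            n_replicas = 1e4, ci_level = 0.90,
                            base_alpha = 0.05, seed = 1) {
  cfg <- list(alpha = alpha, d = d, bands = bands, metrics = metrics,
              pairs = pairs, n_replicas = n_replicas, ci_level = ci_level,
              base_alpha = base_alpha, seed = seed)
  cfg$n_tests <- length(bands) * length(metrics)
  cfg$alpha_prime <- bonferroni_level(length(bands), length(metrics), base_alpha)
  class(cfg) <- "ego_config"
  cfg
}

#' @export
print.ego_config <- function(x, ...) {
  cat(sprintf(paste0("<ego_config> alpha=%g d=%d |bands|=%d |metrics|=%d ",
                     "n_tests=%d alpha'=%.3g n_replicas=%g seed=%s\n"),
              x$alpha, x$d, length(x$bands), length(x$metrics),
              x$n_tests, x$alpha_prime, x$n_replicas, format(x$seed)))
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes backbone extraction, centrality metrics, node-set partition,
#' individual and group-level bootstrap comparisons, distinguishability
#' scoring and outcome classification on a cohort, and optionally writes
#' every stage table plus a machine-readable run log. Rerunning with the
#' same cohort and configuration reproduces the results exactly.
#'
#' @param cohort An `ego_cohort`, or a path to a cohort `manifest.json`.
#' @param config An [pipeline_config()].
#' @param out_dir Optional output directory for stage CSVs and the run log.
#' @return A list of class `ego_run`: `config`, `manifest`, `summaries`
#'   (per patient-band network summaries), `individual`, `group_summary`
#'   (fractions), `group`, `scores` (D and D_comb), `classification`.
#' @export
#' @examples
#' coh <- generate_cohort(n_patients = 4, sf_fraction = 0.5, n_nodes = 25,
#'                        bands = c("B", "theta"), seed = 3)
#' cfg <- pipeline_config(bands = c("B", "theta"), n_replicas = 200)
#' run <- run_pipeline(coh, cfg)
#' run$classification
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "ego_cohort"), inherits(config, "ego_config"))
  manifest <- cohort_manifest(cohort)
  summaries <- purrr::map_dfr(cohort$patients, function(p) {
    purrr::map_dfr(config$bands, function(b) {
      dplyr::bind_cols(
        tibble::tibble(patient_id = p$patient_id, band = b),
        network_summary(disparity_filter(p$networks[[b]], alpha = config$alpha))
      )
    })
  })
  individual <- cohort_individual_tests(
    cohort, bands = config$bands, metrics = config$metrics,
    pairs = config$pairs, alpha = config$alpha, d = config$d,
    n_replicas = config$n_replicas, base_alpha = config$base_alpha,
    n_tests = config$n_tests, seed = derive_seed(config$seed, "individual")
  )
  set_means <- cohort_set_means(cohort, bands = config$bands,
                                metrics = config$metrics,
                                alpha = config$alpha, d = config$d)
  group <- group_level_tests(set_means, pairs = config$pairs,
                             n_replicas = config$n_replicas,
                             base_alpha = config$base_alpha,
                             n_tests = config$n_tests,
                             seed = derive_seed(config$seed, "group"))
  scores <- distinguishability_scores(individual)
  classification <- classify_outcomes(scores, manifest, score = "D",
                                      n_replicas = config$n_replicas,
                                      level = config$ci_level,
                                      seed = derive_seed(config$seed, "roc"))
  run <- list(config = config, manifest = manifest, summaries = summaries,
              individual = individual, set_means = set_means, group = group,
              group_summary = cohort_summary_table(individual),
              scores = scores, classification = classification)
  class(run) <- "ego_run"
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.ego_run <- function(x, ...) {
  cat(sprintf("<ego_run> %d patients, %d bands; alpha'=%.3g\n",
              nrow(x$manifest), length(x$config$bands), x$config$alpha_prime))
  cat("classification:\n")
  print(dplyr::select(x$classification, -"roc"))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("summaries", "individual", "set_means", "group",
              "group_summary", "scores")
  for (s in stages) {
    readr::write_csv(run[[s]], file.path(out_dir, paste0(s, ".csv")))
  }
  readr::write_csv(dplyr::select(run$classification, -"roc"),
                   file.path(out_dir, "classification.csv"))
  readr::write_csv(dplyr::mutate(run$manifest,
                                 ra_rois = vapply(.data$ra_rois, paste,
                                                  character(1), collapse = ";")),
                   file.path(out_dir, "manifest.csv"))
  log <- list(
    config = unclass(run$config)[c("alpha", "d", "bands", "metrics",
                                   "n_replicas", "ci_level", "base_alpha",
                                   "seed", "n_tests", "alpha_prime")],
    package_version = as.character(utils::packageVersion("egotopo")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    n_patients = nrow(run$manifest),
    n_missing_individual = sum(run$individual$missing)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
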