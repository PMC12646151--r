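# On-disk cohort format: a JSON manifest plus one square CSV per
# patient-band (first column `roi`, remaining columns the ROI names).

write_matrix_csv <- function(w, path) {
  df <- tibble::as_tibble(w, rownames = "roi")
  readr::write_csv(df, path)
  invisible(path)
}

read_matrix_csv <- function(path, tol = 1e-9) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  w <- as.matrix(df[, -1])
  rownames(w) <- df[[1]]
  if (!identical(rownames(w), colnames(w))) {
    stop("row and column ROI labels differ in ", path, call. = FALSE)
  }
  asym <- abs(w - t(w))
  if (max(asym) > tol) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetric matrix in %s at [%s, %s] (deviation %.3g)",
                 path, rownames(w)[bad[1]], colnames(w)[bad[2]], max(asym)),
         call. = FALSE)
  }
  check_weight_matrix(w, tol = tol)
}

#' Write a cohort to disk
#'
#' Writes `manifest.json` (patient id, outcome, RA ROIs and relative matrix
#' paths per band) and one CSV connectivity matrix per patient-band.
#'
#' @param cohort An `ego_cohort`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ego_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$patients, function(p) {
    paths <- setNames(
      file.path("matrices", sprintf("%s_%s.csv", p$patient_id, names(p$networks))),
      names(p$networks)
    )
    dir.create(file.path(dir, "matrices"), showWarnings = FALSE)
    for (b in names(p$networks)) {
      write_matrix_csv(p$networks[[b]], file.path(dir, paths[[b]]))
    }
    list(patient_id = p$patient_id, outcome = p$outcome,
         ra_rois = as.list(p$ra_rois), bands = as.list(paths))
  })
  manifest <- list(config = cohort$config, seed = cohort$seed, patients = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort from a manifest
#'
#' Reads a `manifest.json` written by [write_cohort()] (or assembled by
#' hand for real data): each patient lists an outcome (`SF`/`NSF`), RA ROI
#' names and one matrix CSV per band. Matrices are validated (square,
#' symmetric within `tol`, zero diagonal, weights in \[0, 1\]) and exactly
#' symmetrized; RA ROIs must appear among the matrix labels.
#'
#' @param manifest Path to the manifest JSON.
#' @param tol Symmetry tolerance.
#' @return An `ego_cohort`.
#' @export
read_cohort <- function(manifest, tol = 1e-9) {
  m <- jsonlite::read_json(manifest)
  base <- dirname(manifest)
  patients <- lapply(m$patients, function(e) {
    if (!e$outcome %in% c("SF", "NSF")) {
      stop("patient ", e$patient_id, ": outcome must be SF or NSF", call. = FALSE)
    }
    networks <- lapply(e$bands, function(rel) read_matrix_csv(file.path(base, rel), tol))
    ra <- unlist(e$ra_rois)
    for (b in names(networks)) {
      missing_rois <- setdiff(ra, rownames(networks[[b]]))
      if (length(missing_rois)) {
        stop("patient ", e$patient_id, ": unknown RA ROI(s) ",
             paste(missing_rois, collapse = ", "), " in band ", b, call. = FALSE)
      }
    }
    structure(list(patient_id = e$patient_id, outcome = e$outcome,
                   ra_rois = ra, networks = networks),
              class = "ego_patient")
  })
  ids <- vapply(patients, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) stop("duplicated patient ids in manifest", call. = FALSE)
  structure(list(patients = patients,
                 config = m$config %||% list(),
                 seed = m$seed %||% NA_integer_),
            class = "ego_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
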