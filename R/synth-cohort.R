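#' Effect scenario for planted ground truth
#'
#' Encodes the competing hypotheses about where pathological hubs sit:
#' `"ra_hub"` makes the resected nodes themselves hubs, `"neighbour_hub"`
#' makes a node strongly connected to the resection area a hub, `"null"`
#' plants nothing.
#'
#' @param kind One of `"null"`, `"ra_hub"`, `"neighbour_hub"`.
#' @param strength Non-negative weight-inflation factor; incident weights
#'   are multiplied by `1 + strength`. Must be 0 iff `kind = "null"`.
#' @return A list of class `effect_scenario`.
#' @export
effect_scenario <- function(kind = c("null", "ra_hub", "neighbour_hub"), strength = 0) {
  kind <- match.arg(kind)
  stopifnot(length(strength) == 1, is.finite(strength), strength >= 0)
  if (kind == "null" && strength != 0) {
    stop("a null scenario has strength 0", call. = FALSE)
  }
  if (kind != "null" && strength == 0) {
    stop("a planted scenario needs positive strength", call. = FALSE)
  }
  structure(list(kind = kind, strength = strength), class = "effect_scenario")
}

#' Phase panel constructor
#'
#' Wraps per-node instantaneous phase series (radians) with their epoch
#' structure. Phases are stored as one matrix, nodes in rows, the
#' `n_epochs * epoch_length` samples in columns.
#'
#' @param phases Numeric matrix, nodes x samples, finite.
#' @param n_epochs,epoch_length Epoch structure; their product must equal
#'   `ncol(phases)`.
#' @return An object of class `phase_panel`.
#' @export
phase_panel <- function(phases, n_epochs, epoch_length) {
  stopifnot(is.matrix(phases), all(is.finite(phases)),
            n_epochs >= 1, epoch_length >= 1,
            n_epochs * epoch_length == ncol(phases))
  structure(list(phases = phases, n_epochs = as.integer(n_epochs),
                 epoch_length = as.integer(epoch_length)),
            class = "phase_panel")
}

#' Simulate coupled phase oscillators
#'
#' Generates instantaneous phases from noisy Kuramoto-style oscillators with
#' pairwise coupling given by a weight matrix, so that stronger coupling
#' yields larger downstream phase-lag index. This is a realism path for
#' exercising the connectivity estimator, not a model of MEG physics.
#'
#' @param n_nodes Number of oscillators.
#' @param coupling Optional symmetric non-negative coupling matrix
#'   (zero diagonal); zero coupling when `NULL`.
#' @param n_epochs,epoch_length Epoch structure. Defaults follow the usual
#'   resting-state epoching (174 epochs of 4096 samples); use far smaller
#'   values for quick simulations.
#' @param seed Integer seed; same seed, same panel.
#' @param gain Coupling gain applied to `coupling`.
#' @param noise_sd Per-step phase-noise standard deviation (radians).
#' @return A [phase_panel()].
#' @export
#' @examples
#' p <- generate_phase_panel(4, n_epochs = 3, epoch_length = 64, seed = 1)
generate_phase_panel <- function(n_nodes, coupling = NULL, n_epochs = 174,
                                 epoch_length = 4096, seed = 1, gain = 0.4,
                                 noise_sd = 0.3) {
  if (n_nodes < 1 || n_epochs < 1 || epoch_length < 1) {
    stop("dimensions must be positive", call. = FALSE)
  }
  if (is.null(coupling)) coupling <- matrix(0, n_nodes, n_nodes)
  stopifnot(nrow(coupling) == n_nodes, ncol(coupling) == n_nodes,
            all(coupling >= 0), all(diag(coupling) == 0),
            isTRUE(all.equal(coupling, t(coupling))))
  total <- n_epochs * epoch_length
  with_seed(seed, {
    # natural frequencies spread apart so that coupled pairs lock at a
    # non-zero lag (detectable by PLI) while uncoupled pairs drift freely
    omega <- seq(0.1, 0.5, length.out = n_nodes) + runif(n_nodes, -0.02, 0.02)
    theta <- matrix(0, n_nodes, total)
    theta[, 1] <- runif(n_nodes, 0, 2 * pi)
    k <- gain * coupling
    for (t in seq_len(total - 1)) {
      ph <- theta[, t]
      drift <- rowSums(k * sin(outer(ph, ph, function(a, b) b - a)))
      theta[, t + 1] <- ph + omega + drift + rnorm(n_nodes, sd = noise_sd)
    }
    phase_panel(theta, n_epochs, epoch_length)
  })
}

#' Phase lag index from a phase panel
#'
#' The PLI of a node pair is the absolute mean sign of the sine of their
#' instantaneous phase difference, computed within each epoch and averaged
#' across epochs. It measures the asymmetry of the phase-difference
#' distribution: consistently lagged pairs score 1, symmetric or zero-lag
#' pairs score 0 (`sign(0)` contributes 0, so identical series give PLI 0).
#'
#' @param panel A [phase_panel()].
#' @return Weighted connectivity matrix with entries in \[0, 1\].
#' @export
#' @examples
#' ph <- rbind(seq(0, 20, length.out = 64), seq(0, 20, length.out = 64) + pi / 4)
#' pli_from_phases(phase_panel(ph, 1, 64)) # constant lag: PLI = 1
pli_from_phases <- function(panel) {
  stopifnot(inherits(panel, "phase_panel"))
  if (panel$epoch_length < 2) {
    stop("epochs must contain at least two samples", call. = FALSE)
  }
  n <- nrow(panel$phases)
  pli <- matrix(0, n, n)
  for (e in seq_len(panel$n_epochs)) {
    idx <- ((e - 1) * panel$epoch_length + 1):(e * panel$epoch_length)
    x <- panel$phases[, idx, drop = FALSE]
    for (i in seq_len(n - 1)) {
      diffs <- x[(i + 1):n, , drop = FALSE] - matrix(x[i, ], n - i, ncol(x), byrow = TRUE)
      v <- abs(rowMeans(sign(sin(diffs))))
      pli[i, (i + 1):n] <- pli[i, (i + 1):n] + v
    }
  }
  pli <- pli / panel$n_epochs
  pli <- pli + t(pli)
  rownames(pli) <- colnames(pli) <- default_roi_labels(n)
  check_weight_matrix(pli)
}

#' Generate a PLI-like weight matrix
#'
#' Draws heavy-tailed pairwise weights (log-normal on the upper triangle,
#' rescaled so the largest weight is `wmax`) that mimic the heterogeneity of
#' empirical phase-lag-index matrices. The defaults are tuned so that the
#' disparity filter at `alpha = 0.1` leaves densities around 5%
#' (approximately 0.046-0.052 across realizations) with giant components
#' spanning nearly all of 90 nodes.
#'
#' @param n_nodes Number of ROIs (>= 2).
#' @param sdlog Log-scale standard deviation of the weight distribution
#'   (must be positive; larger values give more heterogeneous weights).
#' @param wmax Largest weight after rescaling, in (0, 1\].
#' @param seed Integer seed; same seed, same matrix.
#' @return Symmetric weight matrix with zero diagonal, entries in \[0, 1\].
#' @export
#' @examples
#' w <- generate_weight_matrix(90, seed = 42)
#' network_summary(disparity_filter(w))
generate_weight_matrix <- function(n_nodes = 90, sdlog = 0.59, wmax = 0.4, seed = 1) {
  if (n_nodes < 2) stop("`n_nodes` must be at least 2", call. = FALSE)
  if (!is.finite(sdlog) || sdlog <= 0) {
    stop("degenerate weight distribution: `sdlog` must be positive", call. = FALSE)
  }
  if (!is.finite(wmax) || wmax <= 0 || wmax > 1) {
    stop("`wmax` must lie in (0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    v <- rlnorm(n_nodes * (n_nodes - 1) / 2, meanlog = 0, sdlog = sdlog)
    w <- matrix(0, n_nodes, n_nodes)
    w[upper.tri(w)] <- v
    w <- w + t(w)
    w <- w / max(w) * wmax
    rownames(w) <- colnames(w) <- default_roi_labels(n_nodes)
    check_weight_matrix(w)
  })
}

#' Plant a hub effect into a weight matrix
#'
#' Implements a controllable ground truth for the hypothesis that the
#' epileptogenic zone is either a hub or connected to one. `"ra_hub"`
#' multiplies every weight incident to an RA node by `1 + strength`;
#' `"neighbour_hub"` does the same for the non-RA node most strongly
#' connected to the RA (ties broken at random under `seed`), which both
#' turns it into a hub and anchors it in the RA's neighbour set. Results
#' are clipped to \[0, 1\] and stay symmetric with zero diagonal. `"null"`
#' returns the input unchanged.
#'
#' @param w Weighted connectivity matrix.
#' @param ra_nodes RA node labels or indices (non-empty).
#' @param scenario An [effect_scenario()].
#' @param seed Seed used only for tie-breaking in `"neighbour_hub"`.
#' @return Weight matrix of the same shape.
#' @export
plant_effect <- function(w, ra_nodes, scenario, seed = 1) {
  stopifnot(inherits(scenario, "effect_scenario"))
  w <- check_weight_matrix(w)
  if (length(ra_nodes) == 0) stop("`ra_nodes` must be non-empty", call. = FALSE)
  idx <- if (is.character(ra_nodes)) match(ra_nodes, rownames(w)) else as.integer(ra_nodes)
  if (anyNA(idx) || any(idx < 1 | idx > nrow(w))) {
    stop("invalid RA nodes: ",
         paste(ra_nodes[is.na(idx) | idx < 1 | idx > nrow(w)], collapse = ", "),
         call. = FALSE)
  }
  if (scenario$kind == "null") return(w)
  n <- nrow(w)
  in_ra <- seq_len(n) %in% idx
  target <- switch(scenario$kind,
    ra_hub = in_ra,
    neighbour_hub = {
      ra_link <- rowSums(w[, idx, drop = FALSE])
      ra_link[in_ra] <- -Inf
      best <- which(ra_link == max(ra_link))
      pick <- if (length(best) > 1) with_seed(seed, sample(best, 1)) else best
      seq_len(n) == pick
    }
  )
  mask <- outer(target, rep(TRUE, n), "&") | outer(rep(TRUE, n), target, "&")
  diag(mask) <- FALSE
  w[mask] <- pmin(1, w[mask] * (1 + scenario$strength))
  check_weight_matrix(w)
}

#' Generate a synthetic patient cohort
#'
#' Builds a cohort of patients, each with a resection-area ROI set, a
#' surgical-outcome label (SF = seizure free, NSF = not) and one weighted
#' connectivity matrix per frequency band. Per patient, a latent broadband
#' log-weight matrix is drawn, the outcome group's effect scenario is
#' planted into it, and each frequency band is a correlated perturbation of
#' the planted latent (Gaussian mixing on the log scale with coefficient
#' `band_mix`, which preserves the marginal weight distribution — and hence
#' the post-filter density calibration — in every band). The broadband
#' network is the planted latent itself. All randomness flows through
#' deterministic per-patient, per-band child seeds of `seed`.
#'
#' @param n_patients Cohort size (>= 2). Default 91 with `sf_fraction`
#'   62/91, mirroring a typical single-centre surgery cohort.
#' @param sf_fraction Fraction of seizure-free patients, in (0, 1).
#' @param n_nodes Number of ROIs (default 90, an AAL-style parcellation).
#' @param bands Band labels; default [ego_bands()]. `"B"` (broadband) plays
#'   the latent role when present, otherwise the first band does.
#' @param ra_size Integer range (min, max) of resection sizes; each
#'   patient's RA size is uniform on it. Default 2-8 nodes: small focal
#'   resections on a 90-ROI atlas.
#' @param sf_scenario,nsf_scenario [effect_scenario()]s applied to SF and
#'   NSF patients respectively; both default to null (no planted effect).
#' @param band_mix Log-scale correlation of each band with the latent
#'   matrix, in \[0, 1\].
#' @param sdlog,wmax Weight-distribution parameters, as in
#'   [generate_weight_matrix()].
#' @param seed Master seed.
#' @return An object of class `ego_cohort`.
#' @export
#' @examples
#' coh <- generate_cohort(n_patients = 4, sf_fraction = 0.5, n_nodes = 30,
#'                        bands = c("B", "theta"), seed = 7)
#' cohort_manifest(coh)
generate_cohort <- function(n_patients = 91, sf_fraction = 62 / 91, n_nodes = 90,
                            bands = ego_bands(), ra_size = c(2, 8),
                            sf_scenario = effect_scenario("null"),
                            nsf_scenario = effect_scenario("null"),
                            band_mix = 0.7, sdlog = 0.59, wmax = 0.4,
                            seed = 1) {
  stopifnot(n_patients >= 2, sf_fraction > 0, sf_fraction < 1,
            band_mix >= 0, band_mix <= 1,
            length(ra_size) == 2, ra_size[1] >= 1, ra_size[2] >= ra_size[1],
            ra_size[2] < n_nodes)
  bands <- as.character(bands)
  if (length(bands) < 1 || anyDuplicated(bands)) {
    stop("`bands` must be a non-empty set of distinct labels", call. = FALSE)
  }
  n_sf <- round(n_patients * sf_fraction)
  n_sf <- min(max(n_sf, 1), n_patients - 1)
  rois <- default_roi_labels(n_nodes)
  latent_band <- if ("B" %in% bands) "B" else bands[1]
  m <- n_nodes * (n_nodes - 1) / 2
  patients <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    outcome <- if (p <= n_sf) "SF" else "NSF"
    scenario <- if (outcome == "SF") sf_scenario else nsf_scenario
    pseed <- derive_seed(seed, "patient", p)
    ra <- with_seed(derive_seed(pseed, "ra"), {
      size <- sample(ra_size[1]:ra_size[2], 1)
      sort(sample(rois, size))
    })
    latent <- generate_weight_matrix(n_nodes, sdlog = sdlog, wmax = wmax,
                                     seed = derive_seed(pseed, "latent"))
    latent <- plant_effect(latent, ra, scenario, seed = derive_seed(pseed, "plant"))
    lw <- log(latent[upper.tri(latent)])
    networks <- lapply(bands, function(b) {
      if (b == latent_band) return(latent)
      z <- with_seed(derive_seed(pseed, "band", b), rnorm(m))
      v <- exp(band_mix * lw + sqrt(1 - band_mix^2) * sdlog * z)
      wb <- matrix(0, n_nodes, n_nodes)
      wb[upper.tri(wb)] <- v
      wb <- wb + t(wb)
      wb <- wb / max(wb) * wmax
      rownames(wb) <- colnames(wb) <- rois
      check_weight_matrix(wb)
    })
    names(networks) <- bands
    patients[[p]] <- structure(
      list(patient_id = sprintf("P%03d", p), outcome = outcome,
           ra_rois = ra, networks = networks),
      class = "ego_patient"
    )
  }
  structure(
    list(
      patients = patients,
      config = list(n_patients = n_patients, sf_fraction = sf_fraction,
                    n_nodes = n_nodes, bands = bands, ra_size = ra_size,
                    sf_scenario = unclass(sf_scenario),
                    nsf_scenario = unclass(nsf_scenario),
                    band_mix = band_mix, sdlog = sdlog, wmax = wmax),
      seed = seed
    ),
    class = "ego_cohort"
  )
}

#' @export
print.ego_cohort <- function(x, ...) {
  m <- cohort_manifest(x)
  cat(sprintf("<ego_cohort> %d patients (%d SF, %d NSF), %d ROIs, bands: %s\n",
              nrow(m), sum(m$outcome == "SF"), sum(m$outcome == "NSF"),
              x$config$n_nodes, paste(x$config$bands, collapse = ", ")))
  invisible(x)
}

#' @export
print.ego_patient <- function(x, ...) {
  cat(sprintf("<ego_patient> %s (%s), RA: %s\n", x$patient_id, x$outcome,
              paste(x$ra_rois, collapse = ", ")))
  invisible(x)
}

#' Cohort manifest table
#'
#' @param cohort An `ego_cohort`.
#' @return A tibble with `patient_id`, `outcome`, `ra_rois` (list column)
#'   and `n_ra`.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "ego_cohort"))
  tibble::tibble(
    patient_id = vapply(cohort$patients, `[[`, character(1), "patient_id"),
    outcome = vapply(cohort$patients, `[[`, character(1), "outcome"),
    ra_rois = lapply(cohort$patients, `[[`, "ra_rois"),
    n_ra = lengths(ra_rois)
  )
}
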