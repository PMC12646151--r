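#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats pnorm quantile rlnorm rnorm runif sd setNames p.adjust
#' @importFrom utils combn
NULL

#' Frequency bands of the analysis
#'
#' The seven bands a resting-state MEG connectivity study typically derives
#' per patient: broadband plus six canonical frequency bands.
#'
#' @return Character vector of band labels.
#' @export
#' @examples
#' ego_bands()
ego_bands <- function() {
  c("B", "delta", "theta", "alpha1", "alpha2", "beta", "gamma")
}

#' Generalized centrality metrics
#'
#' The eight metrics used throughout: local clustering coefficient (`CC`),
#' clique-count curvature (`C`), betweenness centrality (`BC`), and the five
#' extended-neighbourhood descriptors — size (`N`), edge count (`E`) and the
#' first three Betti numbers (`b0`, `b1`, `b2`).
#'
#' @return Character vector of metric names.
#' @export
ego_metrics <- function() {
  c("CC", "C", "BC", "N", "E", "b0", "b1", "b2")
}

#' Node-set comparisons
#'
#' The four ordered node-set pairs tested per patient and band: resected
#' nodes against all non-resected nodes, and the three pairwise comparisons
#' of the three-set partition. The hypothesis is always that the first set
#' is more central than the second.
#'
#' @return A tibble with columns `set1` and `set2`.
#' @export
ego_pairs <- function() {
  tibble::tibble(
    set1 = c("RA", "RA", "RA", "N"),
    set2 = c("RAbar", "N", "O", "O")
  )
}

#' Metric orientation with respect to centrality
#'
#' Higher values mean higher generalized centrality for every metric except
#' the curvature, for which strongly negative values indicate hubs.
#'
#' @param metric Character vector of metric names.
#' @return Integer vector of +1/-1 orientations.
#' @export
metric_orientation <- function(metric) {
  ifelse(metric == "C", -1L, 1L)
}

# Deterministic child-seed derivation: fold integer/character components into
# a seed below 2^31 so per-patient / per-band streams are reproducible and
# independent of evaluation order.
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- as.numeric(seed) %% 2147483647
  for (part in list(...)) {
    codes <- if (is.character(part)) utf8ToInt(paste(part, collapse = "|")) else as.numeric(part)
    for (x in codes) h <- (h * 69069 + (x %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Run an expression under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is left untouched. With seed = NULL the expression
# uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

default_roi_labels <- function(n) sprintf("ROI_%02d", seq_len(n))

# Validate a weighted connectivity matrix: symmetric, zero diagonal,
# entries in [0, 1], unique labels. Returns the matrix with labels attached.
check_weight_matrix <- function(w, tol = 1e-9) {
  if (!is.matrix(w) || !is.numeric(w) || nrow(w) != ncol(w)) {
    stop("`w` must be a square numeric matrix", call. = FALSE)
  }
  if (anyNA(w)) stop("connectivity matrix contains missing values", call. = FALSE)
  asym <- abs(w - t(w))
  if (max(asym) > tol) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("matrix is not symmetric (max deviation %.3g at [%d, %d])",
                 max(asym), bad[1], bad[2]), call. = FALSE)
  }
  w <- (w + t(w)) / 2
  if (any(diag(w) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (min(w) < 0 || max(w) > 1) stop("weights must lie in [0, 1]", call. = FALSE)
  if (is.null(rownames(w))) {
    rownames(w) <- colnames(w) <- default_roi_labels(nrow(w))
  }
  if (anyDuplicated(rownames(w))) stop("ROI labels must be unique", call. = FALSE)
  colnames(w) <- rownames(w)
  w
}

check_binary_matrix <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (!all(a == 0 | a == 1)) stop("adjacency must be 0/1", call. = FALSE)
  if (any(a != t(a))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  if (is.null(rownames(a))) rownames(a) <- colnames(a) <- default_roi_labels(nrow(a))
  a
}

as_igraph <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected", diag = FALSE)
}
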