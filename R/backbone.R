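#' Disparity-filter edge significance
#'
#' For each ordered pair (i, j), the probability that an edge share as large
#' as `w[i, j] / s_i` would arise if node i's strength were spread uniformly
#' over its k_i edges: `alpha_ij = (1 - p_ij)^(k_i - 1)` with
#' `p_ij = w_ij / sum_l w_il`. Edges are assessed per endpoint, so the
#' returned matrix is generally asymmetric. Endpoints with weighted degree
#' k_i <= 1 cannot assess any of their edges; their rows are `NA`
#' ("unassessable from this endpoint"). Entries with zero weight are `NA`.
#'
#' @param w Weighted connectivity matrix (symmetric, zero diagonal,
#'   entries in \[0, 1\]).
#' @return Matrix of tail probabilities, rows = assessing endpoint.
#' @export
#' @examples
#' w <- matrix(0.2, 5, 5); diag(w) <- 0
#' edge_significance(w)[1, 2] # (1 - 1/4)^3
edge_significance <- function(w) {
  w <- check_weight_matrix(w)
  n <- nrow(w)
  k <- rowSums(w > 0)
  s <- rowSums(w)
  out <- matrix(NA_real_, n, n, dimnames = dimnames(w))
  assess <- k >= 2
  if (any(assess)) {
    p <- w[assess, , drop = FALSE] / s[assess]
    out[assess, ] <- (1 - p)^(k[assess] - 1)
    out[assess, ][w[assess, , drop = FALSE] == 0] <- NA_real_
  }
  diag(out) <- NA_real_
  out
}

#' Disparity-filter backbone
#'
#' Thresholds and binarizes a weighted network by keeping each edge whose
#' weight is statistically significant from at least one of its endpoints:
#' edge (i, j) is retained iff `alpha_ij < alpha` for endpoint i or
#' endpoint j (strict inequality, OR rule). Endpoints of weighted degree 1
#' cannot assess their single edge, so an edge between two degree-1 nodes is
#' dropped. Because significance is computed from weight shares, the filter
#' is invariant under global rescaling of the weights.
#'
#' @param w Weighted connectivity matrix.
#' @param alpha Significance level in (0, 1); default 0.1.
#' @return Symmetric 0/1 adjacency matrix with the same ROI labels; the
#'   band attribute of `w`, if any, is carried over.
#' @export
#' @examples
#' w <- generate_weight_matrix(20, seed = 1)
#' a <- disparity_filter(w, alpha = 0.1)
#' network_summary(a)
disparity_filter <- function(w, alpha = 0.1) {
  stopifnot(length(alpha) == 1, alpha > 0, alpha < 1)
  w <- check_weight_matrix(w)
  if (all(w == 0)) {
    warning("all weights are zero; returning an empty backbone", call. = FALSE)
    a <- matrix(0L, nrow(w), ncol(w), dimnames = dimnames(w))
    return(a)
  }
  sig <- edge_significance(w)
  keep <- !is.na(sig) & sig < alpha
  a <- (keep | t(keep)) * 1L
  storage.mode(a) <- "integer"
  dimnames(a) <- dimnames(w)
  attr(a, "alpha") <- alpha
  a
}

#' Summarize a binary network
#'
#' @param a Binary adjacency matrix.
#' @return A tibble with node count, edge count, density
#'   (`2 E / (N (N - 1))`), size of the largest connected component and the
#'   number of components (isolated nodes count as singleton components).
#' @export
network_summary <- function(a) {
  a <- check_binary_matrix(a)
  g <- as_igraph(a)
  comp <- igraph::components(g)
  n <- nrow(a)
  tibble::tibble(
    n_nodes = n,
    n_edges = sum(a) / 2,
    density = if (n > 1) sum(a) / (n * (n - 1)) else 0,
    giant_component = max(comp$csize),
    n_components = comp$no
  )
}
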