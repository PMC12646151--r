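#' Local clustering coefficient
#'
#' Fraction of closed triads around each node: `2 t_i / (k_i (k_i - 1))`
#' with `t_i` the number of triangles through node i. Nodes of degree < 2
#' cannot close a triad and get 0.
#'
#' @param a Binary adjacency matrix.
#' @return Named numeric vector in \[0, 1\].
#' @export
clustering_coefficient <- function(a) {
  a <- check_binary_matrix(a)
  k <- rowSums(a)
  t_i <- diag(a %*% a %*% a) / 2
  cc <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  setNames(as.numeric(cc), rownames(a))
}

#' Betweenness centrality
#'
#' Fraction of shortest paths passing through each node, computed on the
#' unweighted graph (Brandes' algorithm via igraph) and normalized by
#' `(N - 1)(N - 2) / 2` so values lie in \[0, 1\]. Pairs in different
#' components contribute nothing.
#'
#' @param a Binary adjacency matrix.
#' @return Named numeric vector in \[0, 1\].
#' @export
betweenness_centrality <- function(a) {
  a <- check_binary_matrix(a)
  g <- as_igraph(a)
  bc <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  setNames(as.numeric(bc), rownames(a))
}

#' Per-node clique counts
#'
#' `Cl_im` is the number of m-cliques containing node i: `Cl_i1 = 1` (the
#' node), `Cl_i2 = k_i` (its edges), `Cl_i3` its triangles, `Cl_i4` its
#' tetrahedra.
#'
#' @param a Binary adjacency matrix.
#' @param m_max Largest clique size counted (1..4).
#' @return Matrix of counts, one row per node, columns `m1..m_max`.
#' @export
#' @examples
#' clique_counts(1 - diag(4), m_max = 4) # every K4 node: 1, 3, 3, 1
clique_counts <- function(a, m_max = 3) {
  if (!(length(m_max) == 1 && m_max %in% 1:4)) {
    stop("`m_max` must be an integer between 1 and 4", call. = FALSE)
  }
  a <- check_binary_matrix(a)
  n <- nrow(a)
  out <- matrix(0, n, m_max, dimnames = list(rownames(a), paste0("m", seq_len(m_max))))
  out[, 1] <- 1
  if (m_max >= 2) out[, 2] <- rowSums(a)
  if (m_max >= 3) {
    tri <- enumerate_triangles(a != 0)
    if (ncol(tri)) out[, 3] <- tabulate(as.vector(tri), nbins = n)
    if (m_max >= 4) {
      tet <- enumerate_tetrahedra(a != 0, tri)
      if (ncol(tet)) out[, 4] <- tabulate(as.vector(tet), nbins = n)
    }
  }
  out
}

#' Clique-count curvature
#'
#' Discrete curvature of each node as the alternating sum of its clique
#' counts, `C_i = sum_m (-1)^(m+1) Cl_im`; with the default `m_max = 3` this
#' is `1 - k_i + t_i`. Strongly negative values indicate hubs.
#'
#' @param a Binary adjacency matrix.
#' @param m_max Largest clique size in the sum (default 3).
#' @return Named numeric vector.
#' @export
#' @examples
#' star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
#' curvature(star) # centre: 1 - 3 + 0 = -2
curvature <- function(a, m_max = 3) {
  cl <- clique_counts(a, m_max = m_max)
  signs <- (-1)^(seq_len(m_max) + 1)
  setNames(as.numeric(cl %*% signs), rownames(a))
}

#' Node strength on the backbone
#'
#' Sum of the weights of the edges a node retains after thresholding.
#'
#' @param w Weighted connectivity matrix.
#' @param a Binary adjacency matrix from [disparity_filter()] on `w`.
#' @return Named numeric vector.
#' @export
node_strength <- function(w, a) {
  w <- check_weight_matrix(w)
  a <- check_binary_matrix(a)
  stopifnot(identical(dim(w), dim(a)))
  setNames(rowSums(w * (a != 0)), rownames(w))
}

#' All generalized centrality metrics of one network
#'
#' Computes the three node-based metrics (clustering `CC`, curvature `C`,
#' betweenness `BC`), the five neighbourhood-based metrics (`N`, `E`, `b0`,
#' `b1`, `b2`) at radius `d`, plus `degree` and backbone `strength`, for
#' every node of a weighted network after disparity filtering.
#'
#' @param w Weighted connectivity matrix.
#' @param a Optional pre-computed backbone; computed from `w` at `alpha`
#'   when missing.
#' @param alpha Disparity-filter significance level.
#' @param d Neighbourhood radius.
#' @param m_max Largest clique size for the curvature.
#' @return A long tibble: `roi`, `metric`, `value`.
#' @export
#' @examples
#' w <- generate_weight_matrix(30, seed = 5)
#' generalized_centrality(w, d = 2)
generalized_centrality <- function(w, a = NULL, alpha = 0.1, d = 2, m_max = 3) {
  w <- check_weight_matrix(w)
  if (is.null(a)) a <- disparity_filter(w, alpha = alpha)
  nb <- neighbourhood_metrics(a, d = d)
  wide <- tibble::tibble(
    roi = rownames(a),
    degree = as.numeric(rowSums(a)),
    strength = as.numeric(node_strength(w, a)),
    CC = as.numeric(clustering_coefficient(a)),
    C = as.numeric(curvature(a, m_max = m_max)),
    BC = as.numeric(betweenness_centrality(a))
  ) |>
    dplyr::left_join(nb, by = "roi")
  tidyr::pivot_longer(wide, -"roi", names_to = "metric", values_to = "value")
}
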