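#' Extract the extended neighbourhood of a node
#'
#' The d-extended neighbourhood (ego network of radius d) of node i is the
#' subgraph induced by all nodes at hop distance between 1 and d from i.
#' The centre itself is excluded, and with it every edge incident to it, so
#' the neighbourhood's topology reflects how the node's area of influence is
#' organized without the node.
#'
#' @param a Binary adjacency matrix.
#' @param node Node label or index (the centre).
#' @param d Neighbourhood radius in hops (>= 1).
#' @return An object of class `extended_neighbourhood`: centre, members,
#'   induced `adjacency`, `n_nodes`, `n_edges`.
#' @export
#' @examples
#' star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
#' en <- extract_extended_neighbourhood(star, 1, d = 1)
#' en$n_nodes; en$n_edges # 3 mutually non-adjacent leaves
extract_extended_neighbourhood <- function(a, node, d = 2) {
  stopifnot(length(d) == 1, d >= 1)
  a <- check_binary_matrix(a)
  extract_en_unchecked(a, node, d)
}

# validation-free core, for callers that have already checked `a`
extract_en_unchecked <- function(a, node, d) {
  i <- if (is.character(node)) match(node, rownames(a)) else as.integer(node)
  if (is.na(i) || i < 1 || i > nrow(a)) stop("unknown node: ", node, call. = FALSE)
  # breadth-first ring expansion up to d hops
  dist <- rep(Inf, nrow(a))
  dist[i] <- 0
  frontier <- i
  for (h in seq_len(d)) {
    if (!length(frontier)) break
    nbrs <- which(rowSums(a[, frontier, drop = FALSE]) > 0 & is.infinite(dist))
    dist[nbrs] <- h
    frontier <- nbrs
  }
  members <- which(dist >= 1 & dist <= d)
  sub <- a[members, members, drop = FALSE]
  out <- list(
    centre = rownames(a)[i],
    d = d,
    members = rownames(a)[members],
    adjacency = sub,
    n_nodes = length(members),
    n_edges = sum(sub) / 2
  )
  class(out) <- "extended_neighbourhood"
  out
}

#' @export
print.extended_neighbourhood <- function(x, ...) {
  cat(sprintf("<extended_neighbourhood> centre=%s d=%d nodes=%d edges=%d\n",
              x$centre, x$d, x$n_nodes, x$n_edges))
  invisible(x)
}

#' Neighbourhood metric vector of one node
#'
#' Composes neighbourhood extraction, clique complex and Betti numbers into
#' the five neighbourhood descriptors of a node: size `N`, edge count `E`
#' and Betti numbers `b0`, `b1`, `b2`. An isolated node has the empty
#' neighbourhood and returns all zeros.
#'
#' @inheritParams extract_extended_neighbourhood
#' @param dim_cap Passed to [clique_complex()].
#' @return Named numeric vector `(N, E, b0, b1, b2)`.
#' @export
neighbourhood_metric_vector <- function(a, node, d = 2, dim_cap = 3) {
  en <- extract_extended_neighbourhood(a, node, d)
  b <- betti_numbers(clique_complex(en, dim_cap = dim_cap))
  c(N = en$n_nodes, E = en$n_edges, b)
}

en_vector_unchecked <- function(a, node, d, dim_cap) {
  en <- extract_en_unchecked(a, node, d)
  b <- betti_numbers(clique_complex(en, dim_cap = dim_cap))
  c(N = en$n_nodes, E = en$n_edges, b)
}

#' Neighbourhood metrics for all nodes of a network
#'
#' @param a Binary adjacency matrix.
#' @param d Neighbourhood radius (default 2).
#' @param nodes Optional subset of node labels; default all.
#' @param dim_cap Passed to [clique_complex()].
#' @return A tibble with one row per node: `roi`, `N`, `E`, `b0`, `b1`, `b2`.
#' @export
#' @examples
#' a <- disparity_filter(generate_weight_matrix(30, seed = 2))
#' neighbourhood_metrics(a, d = 2)
neighbourhood_metrics <- function(a, d = 2, nodes = NULL, dim_cap = 3) {
  a <- check_binary_matrix(a)
  if (is.null(nodes)) nodes <- rownames(a)
  vals <- vapply(nodes, function(v) en_vector_unchecked(a, v, d, dim_cap),
                 numeric(5))
  tibble::tibble(
    roi = nodes,
    N = unname(vals["N", ]),
    E = unname(vals["E", ]),
    b0 = unname(vals["b0", ]),
    b1 = unname(vals["b1", ]),
    b2 = unname(vals["b2", ])
  )
}
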