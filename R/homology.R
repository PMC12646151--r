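# Clique enumeration and mod-2 simplicial homology for small graphs
# (extended neighbourhoods of brain-network nodes; tens of nodes).

# Triangles of a logical adjacency matrix as a 3-row matrix of vertex
# indices (each column sorted increasing). Enumerates per edge via common
# neighbourhoods; fine at neighbourhood scale.
enumerate_triangles <- function(adj) {
  n <- nrow(adj)
  if (n < 3) return(matrix(integer(), 3, 0))
  ut <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(ut) == 0) return(matrix(integer(), 3, 0))
  tri <- vector("list", nrow(ut))
  for (e in seq_len(nrow(ut))) {
    u <- ut[e, 1]; v <- ut[e, 2]
    common <- which(adj[, u] & adj[, v])
    common <- common[common > v]
    if (length(common)) tri[[e]] <- rbind(u, v, common, deparse.level = 0)
  }
  tri <- tri[!vapply(tri, is.null, logical(1))]
  if (!length(tri)) return(matrix(integer(), 3, 0))
  do.call(cbind, tri)
}

enumerate_tetrahedra <- function(adj, triangles) {
  if (ncol(triangles) == 0) return(matrix(integer(), 4, 0))
  tet <- vector("list", ncol(triangles))
  for (t in seq_len(ncol(triangles))) {
    v <- triangles[, t]
    common <- which(adj[, v[1]] & adj[, v[2]] & adj[, v[3]])
    common <- common[common > v[3]]
    if (length(common)) tet[[t]] <- rbind(v[1], v[2], v[3], common, deparse.level = 0)
  }
  tet <- tet[!vapply(tet, is.null, logical(1))]
  if (!length(tet)) return(matrix(integer(), 4, 0))
  do.call(cbind, tet)
}

# Rank of a logical matrix over GF(2) by Gaussian elimination.
rank_gf2 <- function(m) {
  if (is.null(m) || length(m) == 0 || nrow(m) == 0 || ncol(m) == 0) return(0L)
  m <- m != 0
  nr <- nrow(m); nc <- ncol(m)
  rank <- 0L
  used <- rep(FALSE, nr)
  for (j in seq_len(nc)) {
    cand <- which(m[, j] & !used)
    if (!length(cand)) next
    p <- cand[1]
    used[p] <- TRUE
    rank <- rank + 1L
    others <- which(m[, j])
    others <- others[others != p]
    if (length(others)) {
      m[others, ] <- m[others, , drop = FALSE] !=
        matrix(m[p, ], length(others), nc, byrow = TRUE)
    }
  }
  rank
}

simplex_keys <- function(simplices) {
  if (ncol(simplices) == 0) return(character())
  apply(simplices, 2, paste, collapse = "-")
}

# Boundary matrix of k-simplices (columns) in the basis of their
# (k-1)-faces (rows), over GF(2).
boundary_matrix <- function(faces, simplices) {
  n_faces <- ncol(faces)
  n_simp <- ncol(simplices)
  if (n_faces == 0 || n_simp == 0) return(matrix(FALSE, n_faces, n_simp))
  keys <- simplex_keys(faces)
  k <- nrow(simplices)
  m <- matrix(FALSE, n_faces, n_simp)
  for (drop in seq_len(k)) {
    face <- simplices[-drop, , drop = FALSE]
    idx <- match(simplex_keys(face), keys)
    m[cbind(idx, seq_len(n_simp))] <- TRUE
  }
  m
}

#' Clique complex of a graph
#'
#' Builds the simplicial complex whose m-simplices are the (m+1)-cliques of
#' the graph: vertices, edges, triangles and (for `dim_cap = 3`) tetrahedra.
#' Downward closure holds by construction, since every sub-clique of a
#' clique is a clique.
#'
#' @param x A binary adjacency matrix or an [extract_extended_neighbourhood()]
#'   result.
#' @param dim_cap Highest simplex dimension enumerated (2 or 3). With
#'   `dim_cap = 2` no tetrahedra are stored and the second Betti number is
#'   computed as if there were none.
#' @return An object of class `clique_complex`: a list of simplex matrices
#'   (`vertices`, `edges`, `triangles`, `tetrahedra`, one column per
#'   simplex) with a `counts` vector.
#' @export
#' @examples
#' a <- 1 - diag(4) # K4
#' clique_complex(a)$counts
clique_complex <- function(x, dim_cap = 3) {
  stopifnot(dim_cap %in% c(2, 3))
  adj <- if (inherits(x, "extended_neighbourhood")) x$adjacency else check_binary_matrix(x)
  adj <- adj != 0
  n <- nrow(adj)
  edges <- if (n) t(which(adj & upper.tri(adj), arr.ind = TRUE)) else matrix(integer(), 2, 0)
  rownames(edges) <- NULL
  triangles <- enumerate_triangles(adj)
  tetrahedra <- if (dim_cap >= 3) enumerate_tetrahedra(adj, triangles) else matrix(integer(), 4, 0)
  out <- list(
    vertices = matrix(seq_len(n), 1),
    edges = edges,
    triangles = triangles,
    tetrahedra = tetrahedra,
    counts = c(n0 = n, n1 = ncol(edges), n2 = ncol(triangles), n3 = ncol(tetrahedra)),
    dim_cap = dim_cap,
    labels = rownames(adj)
  )
  class(out) <- "clique_complex"
  out
}

#' @export
print.clique_complex <- function(x, ...) {
  cat("<clique_complex>", paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Betti numbers of a clique complex
#'
#' Computes the first three Betti numbers over the field with two elements:
#' `b_k = dim ker(boundary_k) - rank(boundary_{k+1})`, with ranks obtained by
#' Gaussian elimination on the mod-2 boundary matrices. `b0` counts connected
#' components, `b1` independent cycles not filled by triangles, `b2`
#' enclosed cavities not filled by tetrahedra. The empty complex returns
#' all zeros.
#'
#' @param complex A [clique_complex()] object.
#' @return Named integer vector `c(b0, b1, b2)`.
#' @export
#' @examples
#' cyc4 <- rbind(c(0,1,0,1), c(1,0,1,0), c(0,1,0,1), c(1,0,1,0))
#' betti_numbers(clique_complex(cyc4)) # one component, one loop
betti_numbers <- function(complex) {
  stopifnot(inherits(complex, "clique_complex"))
  n <- complex$counts
  if (n[["n0"]] == 0) {
    return(c(b0 = 0L, b1 = 0L, b2 = 0L))
  }
  r1 <- rank_gf2(boundary_matrix(complex$vertices, complex$edges))
  r2 <- rank_gf2(boundary_matrix(complex$edges, complex$triangles))
  r3 <- rank_gf2(boundary_matrix(complex$triangles, complex$tetrahedra))
  out <- c(
    b0 = n[["n0"]] - r1,
    b1 = (n[["n1"]] - r1) - r2,
    b2 = (n[["n2"]] - r2) - r3
  )
  if (complex$dim_cap < 3) attr(out, "tetrahedra_truncated") <- TRUE
  out
}
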