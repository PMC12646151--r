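# Fixture graphs and independent brute-force oracles used across tests.

# Erdos-Renyi-style random 0/1 adjacency matrix.
rand_graph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a <- a + t(a)
  rownames(a) <- colnames(a) <- sprintf("V%02d", seq_len(n))
  a
}

graph_star <- function(k) {
  a <- matrix(0L, k + 1, k + 1)
  a[1, -1] <- a[-1, 1] <- 1L
  rownames(a) <- colnames(a) <- c("hub", paste0("leaf", seq_len(k)))
  a
}

graph_cycle <- function(n) {
  a <- matrix(0L, n, n)
  a[cbind(seq_len(n), c(2:n, 1))] <- 1L
  a <- a | t(a)
  storage.mode(a) <- "integer"
  rownames(a) <- colnames(a) <- paste0("c", seq_len(n))
  a
}

graph_complete <- function(n) {
  a <- matrix(1L, n, n) - diag(n)
  storage.mode(a) <- "integer"
  rownames(a) <- colnames(a) <- paste0("k", seq_len(n))
  a
}

# Octahedron = K6 minus a perfect matching: 6 vertices, 12 edges,
# 8 triangles, no tetrahedra; encloses one cavity.
graph_octahedron <- function() {
  a <- graph_complete(6)
  a[1, 2] <- a[2, 1] <- 0L
  a[3, 4] <- a[4, 3] <- 0L
  a[5, 6] <- a[6, 5] <- 0L
  a
}

graph_path <- function(n) {
  a <- matrix(0L, n, n)
  if (n > 1) a[cbind(seq_len(n - 1), 2:n)] <- 1L
  a <- a + t(a)
  rownames(a) <- colnames(a) <- paste0("p", seq_len(n))
  a
}

# Independent clique-complex homology oracle: enumerate cliques by exhaustive
# subset checking, build dense boundary matrices, reduce to row echelon form
# mod 2 with explicit row swaps. Shares no code with the package internals.
oracle_betti <- function(adj) {
  n <- nrow(adj)
  cliques_of_size <- function(k) {
    if (n < k) return(list())
    Filter(function(s) all(adj[s, s][upper.tri(matrix(0, k, k))] == 1),
           utils::combn(n, k, simplify = FALSE))
  }
  edges <- cliques_of_size(2)
  tris <- cliques_of_size(3)
  tets <- cliques_of_size(4)
  bmat <- function(faces, simps) {
    m <- matrix(0, length(faces), length(simps))
    if (!length(faces) || !length(simps)) return(m)
    face_key <- vapply(faces, paste, character(1), collapse = ",")
    for (j in seq_along(simps)) {
      s <- simps[[j]]
      for (drop_i in seq_along(s)) {
        m[match(paste(s[-drop_i], collapse = ","), face_key), j] <- 1
      }
    }
    m
  }
  rank_mod2 <- function(m) {
    if (nrow(m) == 0 || ncol(m) == 0) return(0)
    m <- m %% 2
    r <- 0
    for (col in seq_len(ncol(m))) {
      piv <- which(m[, col] == 1)
      piv <- piv[piv > r]
      if (!length(piv)) next
      r <- r + 1
      if (piv[1] != r) {
        tmp <- m[r, ]; m[r, ] <- m[piv[1], ]; m[piv[1], ] <- tmp
      }
      for (i in seq_len(nrow(m))) {
        if (i != r && m[i, col] == 1) m[i, ] <- (m[i, ] + m[r, ]) %% 2
      }
    }
    r
  }
  r1 <- rank_mod2(bmat(as.list(seq_len(n)), edges))
  r2 <- rank_mod2(bmat(edges, tris))
  r3 <- rank_mod2(bmat(tris, tets))
  c(b0 = n - r1, b1 = length(edges) - r1 - r2, b2 = length(tris) - r2 - r3)
}

# Brute-force betweenness: enumerate every simple path per pair by
# recursion, keep the shortest, and accumulate fractional pass-through
# counts. Normalized like the package ((N-1)(N-2)/2). Only for tiny graphs.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- list()
      recurse <- function(path) {
        v <- path[length(path)]
        if (v == t) {
          paths[[length(paths) + 1]] <<- path
          return(invisible())
        }
        for (w in which(adj[v, ] == 1)) {
          if (!(w %in% path)) recurse(c(path, w))
        }
      }
      recurse(s)
      if (!length(paths)) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (p in shortest) {
        inner <- setdiff(p, c(s, t))
        bc[inner] <- bc[inner] + 1 / sigma
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}
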