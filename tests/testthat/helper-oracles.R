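# Independent oracles and random-case generators shared across tests.

# Brute-force q-connected component count: breadth-first search over the
# simplices of dimension >= q, joining pairs whose vertex-set intersection
# has size >= q + 1. Works on raw label lists, independently of the package's
# connectivity-matrix / igraph path.
oracle_component_count <- function(simplex_list, q) {
  sets <- lapply(simplex_list, function(s) unique(as.character(s)))
  dims <- lengths(sets) - 1L
  elig <- which(dims >= q)
  if (length(elig) == 0L) {
    return(0L)
  }
  near <- function(a, b) length(intersect(sets[[a]], sets[[b]])) >= q + 1L
  seen <- rep(FALSE, length(elig))
  n_comp <- 0L
  for (s in seq_along(elig)) {
    if (seen[s]) next
    n_comp <- n_comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0L) {
      cur <- queue[1]
      queue <- queue[-1]
      for (t in seq_along(elig)) {
        if (!seen[t] && near(elig[cur], elig[t])) {
          seen[t] <- TRUE
          queue <- c(queue, t)
        }
      }
    }
  }
  n_comp
}

# Random simplex list over at most n_max integer-labelled vertices.
random_simplex_list <- function(m_max = 12, n_max = 10) {
  m <- sample(2:m_max, 1)
  lapply(seq_len(m), function(i) {
    sample(n_max, sample(min(5L, n_max), 1))
  })
}

# Random symmetric 0/1 adjacency matrix with edge density p.
random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

triangle_adjacency <- function() {
  matrix(1, 3, 3) - diag(3)
}

# Single edge 1-2 on a 3-vertex node set (same node set as the triangle).
edge_adjacency <- function() {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 1
  a
}
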