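#' Specification for a synthetic network ensemble
#'
#' Bundles the parameters of the scale-free / configurational simulation
#' study: number of nodes, the preferential-attachment parameter (edges added
#' per new node), the ensemble size and the random seed. The default preset
#' (`n_nodes = 100`, `m_parameter = 8`, `n_samples = 100`) matches the study's
#' reference configuration; a smaller preset (`n_nodes = 50`,
#' `m_parameter = 10`) is available via [study_presets()].
#'
#' @param n_nodes Number of vertices per network.
#' @param m_parameter Edges attached by each incoming node; must satisfy
#'   `1 <= m_parameter < n_nodes`.
#' @param n_samples Number of networks in the ensemble.
#' @param seed Integer seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_nodes = 100, m_parameter = 8, n_samples = 100,
                           seed = 1) {
  if (!is.numeric(n_nodes) || n_nodes < 2 || n_nodes != floor(n_nodes)) {
    stop("`n_nodes` must be an integer >= 2")
  }
  if (!is.numeric(m_parameter) || m_parameter < 1 || m_parameter >= n_nodes ||
      m_parameter != floor(m_parameter)) {
    stop("`m_parameter` must satisfy 1 <= m_parameter < n_nodes")
  }
  if (!is.numeric(n_samples) || n_samples < 1 || n_samples != floor(n_samples)) {
    stop("`n_samples` must be a positive integer")
  }
  structure(
    list(n_nodes = as.integer(n_nodes), m_parameter = as.integer(m_parameter),
         n_samples = as.integer(n_samples), seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' Named parameter presets for the simulation study
#'
#' `"code"` is the reference configuration (100 nodes, 8 edges per node, 100
#' samples); `"prose"` is the smaller alternative (50 nodes, 10 edges per
#' node, 100 samples).
#'
#' @param name Preset name.
#' @param seed Seed stored in the returned spec.
#' @return A `generator_spec`.
#' @export
study_presets <- function(name = c("code", "prose"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    code = generator_spec(100, 8, 100, seed),
    prose = generator_spec(50, 10, 100, seed)
  )
}

#' Generate a seeded scale-free network ensemble
#'
#' Preferential-attachment (Barabasi-Albert) graphs: starting from a star on
#' `m_parameter + 1` nodes, each incoming node attaches `m_parameter` edges to
#' existing nodes with probability proportional to degree. Under this seed
#' graph every generated network has exactly
#' `(n_nodes - m_parameter) * m_parameter` edges. Generation is deterministic
#' given the spec's seed.
#'
#' @param spec A `generator_spec`.
#' @return List of `n_samples` binary adjacency matrices.
#' @export
generate_scale_free <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  seed_graph <- igraph::make_star(spec$m_parameter + 1L, mode = "undirected")
  lapply(seq_len(spec$n_samples), function(i) {
    g <- igraph::sample_pa(spec$n_nodes, m = spec$m_parameter,
                           directed = FALSE, start.graph = seed_graph)
    unname(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)))
  })
}

#' Generate configurational networks from degree sequences
#'
#' Realises each degree sequence as a simple graph with the Havel-Hakimi
#' construction: repeatedly connect the vertex with the largest remaining
#' degree to the next-largest ones. The construction is deterministic; with
#' `randomize = TRUE` it is followed by seeded degree-preserving double-edge
#' swaps (10 x edge-count attempts), which randomises the wiring while keeping
#' every degree exactly.
#'
#' @param degree_sequences List of non-negative integer vectors; each must be
#'   graphical (Erdos-Gallai condition), otherwise an error names the
#'   offending sequence.
#' @param randomize Apply degree-preserving edge swaps after construction.
#' @param seed Seed for the swaps (only used when `randomize = TRUE`).
#' @return List of binary adjacency matrices, one per sequence.
#' @examples
#' generate_configurational(list(c(2, 2, 2)))[[1]]  # the triangle
#' @export
generate_configurational <- function(degree_sequences, randomize = FALSE,
                                     seed = 1) {
  if (!is.list(degree_sequences) || length(degree_sequences) == 0L) {
    stop("`degree_sequences` must be a non-empty list of integer vectors")
  }
  if (randomize) set.seed(seed)
  lapply(seq_along(degree_sequences), function(i) {
    deg <- as.integer(degree_sequences[[i]])
    if (any(deg < 0) || !igraph::is_graphical(deg)) {
      stop(sprintf("degree sequence %d is not graphical", i))
    }
    adj <- havel_hakimi(deg)
    if (randomize) {
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      g <- igraph::rewire(g, igraph::keeping_degseq(niter = 10L * igraph::ecount(g)))
      adj <- unname(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)))
    }
    adj
  })
}

# Classical Havel-Hakimi realization of a graphical degree sequence: take the
# vertex with the largest remaining degree d, connect it to the d vertices
# with the next-largest remaining degrees (ties broken by vertex index).
havel_hakimi <- function(deg) {
  n <- length(deg)
  adj <- matrix(0, n, n)
  rem <- as.integer(deg)
  repeat {
    v <- order(-rem, seq_len(n))[1]
    d <- rem[v]
    if (d == 0L) break
    rem[v] <- 0L
    cand <- order(-rem, seq_len(n))
    cand <- cand[cand != v & rem[cand] > 0L]
    if (length(cand) < d) stop("degree sequence is not graphical")
    targets <- cand[seq_len(d)]
    adj[v, targets] <- 1
    adj[targets, v] <- 1
    rem[targets] <- rem[targets] - 1L
  }
  adj
}

#' Paired scale-free and configurational ensembles
#'
#' Generates a scale-free ensemble and, for each of its networks, a
#' configurational network realising exactly the same degree sequence
#' (index-paired). The pairing isolates higher-order structure: both ensembles
#' share their degree distributions, so any difference in q-connectivity
#' reflects wiring organisation, not degrees.
#'
#' @param spec A `generator_spec`.
#' @param randomize Passed to [generate_configurational()].
#' @return List with elements `scale_free` and `configurational`, each a list
#'   of `n_samples` adjacency matrices.
#' @export
paired_study_ensembles <- function(spec, randomize = FALSE) {
  stopifnot(inherits(spec, "generator_spec"))
  sf <- generate_scale_free(spec)
  degs <- lapply(sf, rowSums)
  cf <- generate_configurational(degs, randomize = randomize, seed = spec$seed)
  list(scale_free = sf, configurational = cf)
}

#' The two-triangle worked-example complex
#'
#' The complex of two 2-simplices `<v1,v2,v3>` and `<v2,v3,v4>` sharing the
#' edge `<v2,v3>`. Its structure vectors (descending-q display) are
#' FSV = \[2, 1, 1\], SSV = \[2, 2, 2\], TSV = \[0, 0.5, 0.5\].
#'
#' @return A `simplicial_complex`.
#' @export
worked_example_complex <- function() {
  simplicial_complex(list(c("v1", "v2", "v3"), c("v2", "v3", "v4")))
}

#' A four-simplex illustrative complex over seven vertices
#'
#' A synthetic reconstruction of the classic four-simplex, seven-vertex
#' illustration of q-nearness: two 3-simplices sharing a 2-dimensional face
#' \{V1, V5, V6\}, a 2-simplex meeting the first 3-simplex in the single
#' vertex V6 and the second in the 1-face \{V6, V7\}, and a 1-simplex
#' attached through V2. Its component counts are 2 at q = 3, 2 at q = 2,
#' 2 at q = 1 and 1 at q = 0 (FSV = \[2, 2, 2, 1\] descending), and its
#' connectivity matrix has `Pi[1,1] = 3` and `Pi[1,2] = 2`.
#'
#' @return A `simplicial_complex`.
#' @export
illustrative_complex <- function() {
  simplicial_complex(list(
    c("V1", "V4", "V5", "V6"),
    c("V1", "V5", "V6", "V7"),
    c("V2", "V6", "V7"),
    c("V2", "V3")
  ))
}
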