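#' Consensus adjacency matrix of a network ensemble
#'
#' Binarises every network (nonzero entries become edges) and keeps the edges
#' whose occurrence frequency across the ensemble is at least
#' `edge_inclusion_threshold`. The consensus network summarises the shared
#' topological backbone of a group of same-node-set networks (e.g. the same
#' brain parcellation across subjects).
#'
#' @param networks Non-empty list of square symmetric adjacency matrices of
#'   identical shape.
#' @param edge_inclusion_threshold Required edge frequency, in `(0, 1]`;
#'   1 gives the intersection of all edge sets.
#' @return Binary adjacency matrix of the common shape.
#' @export
consensus_adjacency <- function(networks, edge_inclusion_threshold = 0.95) {
  if (!is.list(networks) || length(networks) == 0L) {
    stop("`networks` must be a non-empty list of adjacency matrices")
  }
  if (!is.numeric(edge_inclusion_threshold) || length(edge_inclusion_threshold) != 1L ||
      edge_inclusion_threshold <= 0 || edge_inclusion_threshold > 1) {
    stop("`edge_inclusion_threshold` must lie in (0, 1]")
  }
  dims <- vapply(networks, function(a) dim(as.matrix(a)), integer(2))
  if (any(dims != dims[1, 1])) stop("all networks must share the same square shape")
  freq <- Reduce(`+`, lapply(networks, function(a) (as.matrix(a) != 0) * 1)) /
    length(networks)
  out <- (freq >= edge_inclusion_threshold) * 1
  diag(out) <- 0
  dimnames(out) <- dimnames(as.matrix(networks[[1]]))
  out
}

#' Zero-pad structure vectors to a common length
#'
#' Aligns q-ascending graded vectors from complexes of differing maximum
#' dimension by appending zeros at high q, so that collections of networks of
#' varying size yield uniformly shaped arrays.
#'
#' @param vectors List of numeric vectors (q-ascending, starting at q = 0).
#' @param max_order Target highest q; must be at least every input length - 1.
#' @return Numeric matrix with one row per vector and `max_order + 1` columns.
#' @export
pad_structure_vectors <- function(vectors, max_order) {
  if (!is.list(vectors)) vectors <- list(vectors)
  lens <- lengths(vectors)
  if (any(lens - 1L > max_order)) {
    stop("`max_order` is smaller than the highest q of some input vector")
  }
  out <- matrix(0, length(vectors), max_order + 1L,
                dimnames = list(NULL, 0:max_order))
  for (i in seq_along(vectors)) out[i, seq_len(lens[i])] <- vectors[[i]]
  out
}

#' Consensus-network test statistic between two groups
#'
#' Builds a consensus network per group, converts each to its clique complex,
#' computes the graded parameter sets, pads both to the common q-domain and
#' returns the element-wise absolute difference per (series, q) cell. The
#' statistic is symmetric under a group swap.
#'
#' @param group_a,group_b Non-empty lists of same-shape adjacency matrices.
#' @param max_order Common highest q for padding; defaults to the clique
#'   dimension of the pooled union graph, which bounds any consensus complex.
#' @param edge_inclusion_threshold Passed to [consensus_adjacency()].
#' @param desired Graded series to include (as in [graded_parameters()]).
#' @return Numeric (series x levels) matrix of absolute differences.
#' @export
consensus_statistic <- function(group_a, group_b, max_order = NULL,
                                edge_inclusion_threshold = 0.95,
                                desired = NULL) {
  if (is.null(max_order)) max_order <- union_clique_order(c(group_a, group_b))
  ma <- bundle_matrix(
    graded_parameters(
      complex_from_adjacency(consensus_adjacency(group_a, edge_inclusion_threshold)),
      desired
    ),
    max_order = max_order
  )
  mb <- bundle_matrix(
    graded_parameters(
      complex_from_adjacency(consensus_adjacency(group_b, edge_inclusion_threshold)),
      desired
    ),
    max_order = max_order
  )
  abs(ma - mb)
}

# Highest clique dimension of the union graph of an ensemble; any consensus
# network's edges are a subset of the union's, so this bounds its d_max.
union_clique_order <- function(networks) {
  u <- Reduce(`+`, lapply(networks, function(a) (as.matrix(a) != 0) * 1))
  g <- igraph::graph_from_adjacency_matrix((u != 0) * 1, mode = "undirected",
                                           diag = FALSE)
  max(igraph::clique_num(g) - 1L, 0L)
}

#' Permutation test on consensus-network graded parameters
#'
#' Tests for systematic structural differences between two groups of networks.
#' The observed statistic (by default [consensus_statistic()]) is compared
#' with a null distribution obtained by permuting the group labels (group
#' sizes preserved) and recomputing consensus networks and their graded
#' parameters for every permutation. P-values use the permutation-inclusive
#' add-one estimator `p = (1 + #\{permuted >= observed\}) / (1 + n_resamples)`
#' element-wise, so they are never 0. With `exact = TRUE` all distinct label
#' assignments are enumerated instead and `p` is the exact fraction of
#' assignments (including the identity) whose statistic reaches the observed
#' one.
#'
#' No multiple-testing correction is applied across the (series, q) cells by
#' default; pass the returned table to [stats::p.adjust()] (e.g. method
#' `"BH"`) if one is wanted.
#'
#' @param group_a,group_b Lists of same-shape adjacency matrices.
#' @param statistic Function of two network lists returning a numeric array;
#'   defaults to [consensus_statistic()] with a fixed `max_order` derived
#'   from the pooled union graph.
#' @param n_resamples Number of label permutations (ignored when
#'   `exact = TRUE`); must be >= 1.
#' @param seed Integer seed for the permutation generator.
#' @param exact Enumerate all label assignments instead of sampling.
#' @param edge_inclusion_threshold,max_order,desired Passed to the default
#'   statistic; ignored when `statistic` is supplied.
#' @return An object of class `permutation_result`: list with `observed`,
#'   `p_values` (same shape), `n_resamples`, `seed`, `exact`.
#' @export
permutation_test <- function(group_a, group_b, statistic = NULL,
                             n_resamples = 999, seed = 1, exact = FALSE,
                             edge_inclusion_threshold = 0.95,
                             max_order = NULL, desired = NULL) {
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a + n_b < 2L || n_a == 0L || n_b == 0L) {
    stop("need at least one network in each group and two in total")
  }
  if (!exact && (!is.numeric(n_resamples) || n_resamples < 1)) {
    stop("`n_resamples` must be at least 1")
  }
  pool <- c(group_a, group_b)
  if (is.null(statistic)) {
    if (is.null(max_order)) max_order <- union_clique_order(pool)
    statistic <- function(a, b) {
      consensus_statistic(a, b, max_order = max_order,
                          edge_inclusion_threshold = edge_inclusion_threshold,
                          desired = desired)
    }
  }
  observed <- statistic(group_a, group_b)
  count <- array(0, dim = dim(observed))
  if (exact) {
    assignments <- utils::combn(n_a + n_b, n_a)
    for (k in seq_len(ncol(assignments))) {
      ia <- assignments[, k]
      s <- statistic(pool[ia], pool[-ia])
      count <- count + (s >= observed)
    }
    p <- count / ncol(assignments)
    n_used <- ncol(assignments)
  } else {
    set.seed(seed)
    for (k in seq_len(n_resamples)) {
      ia <- sample(n_a + n_b, n_a)
      s <- statistic(pool[ia], pool[-ia])
      count <- count + (s >= observed)
    }
    p <- (1 + count) / (1 + n_resamples)
    n_used <- n_resamples
  }
  dimnames(p) <- dimnames(observed)
  structure(
    list(observed = observed, p_values = p, n_resamples = n_used,
         seed = seed, exact = exact),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Consensus permutation test (%s, %d %s)\n",
    if (x$exact) "exact" else "sampled", x$n_resamples,
    if (x$exact) "assignments" else "resamples"
  ))
  cat("minimum p-value:", format(min(x$p_values)), "\n")
  invisible(x)
}

#' @export
as.data.frame.permutation_result <- function(x, ...) {
  dn <- dimnames(x$observed)
  series <- if (!is.null(dn[[1]])) dn[[1]] else as.character(seq_len(nrow(x$observed)))
  qs <- if (!is.null(dn[[2]])) as.integer(dn[[2]]) else seq_len(ncol(x$observed)) - 1L
  data.frame(
    Vector = rep(series, times = length(qs)),
    q = rep(qs, each = length(series)),
    Statistic = as.vector(x$observed),
    p = as.vector(x$p_values),
    stringsAsFactors = FALSE
  )
}
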