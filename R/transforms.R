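#' Project a simplicial complex to a graph
#'
#' Builds the co-occurrence graph of a complex: every simplex of dimension
#' >= q contributes an edge between each pair of its vertices. With
#' `weighted = TRUE` the edge weight is the number of contributing simplices
#' containing the pair; otherwise edges are 0/1 indicators. Simplices below
#' the q cut-off are filtered out before counting.
#'
#' @param K A `simplicial_complex`.
#' @param q Minimum simplex dimension to contribute; `q > d_max` yields an
#'   empty (all-zero) graph, `q < 0` is an error.
#' @param weighted Count co-occurrences instead of 0/1 indicators.
#' @return Symmetric n x n numeric matrix with zero diagonal, labelled by the
#'   complex's vertex labels.
#' @examples
#' K <- simplicial_complex(list(c(1, 2, 3), c(2, 3, 4)))
#' simplex_projection(K, 0, weighted = TRUE)["2", "3"]  # 2
#' @export
simplex_projection <- function(K, q = 0, weighted = FALSE) {
  stopifnot(inherits(K, "simplicial_complex"))
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q != floor(q)) {
    stop("q must be a non-negative integer")
  }
  adj <- matrix(0, K$n, K$n, dimnames = list(K$labels, K$labels))
  for (i in seq_len(K$m)) {
    if (K$dims[i] < q) next
    s <- K$simplices[[i]]
    if (length(s) < 2L) next
    prs <- utils::combn(s, 2L)
    for (k in seq_len(ncol(prs))) {
      u <- prs[1, k]; v <- prs[2, k]
      adj[u, v] <- adj[u, v] + 1
      adj[v, u] <- adj[v, u] + 1
    }
  }
  if (!weighted) adj <- (adj > 0) * 1
  adj
}

#' Filter a graph's edges by clique dimension
#'
#' Keeps only the edges that lie inside a clique of at least q + 1 vertices:
#' the graph's clique complex is built, projected back to a graph at level q,
#' and the result is masked with the original edge set (original weights are
#' preserved on retained edges).
#'
#' @param adj Square symmetric adjacency matrix (as for
#'   [complex_from_adjacency()]).
#' @param q Minimum clique dimension; edges outside any (q+1)-vertex clique
#'   are removed.
#' @return Adjacency matrix of the same shape; output edges are a subset of
#'   input edges and the operation is idempotent at fixed q.
#' @export
clique_filter <- function(adj, q) {
  adj <- validate_adjacency(adj)
  K <- complex_from_adjacency(adj)
  mask <- if (q > K$d_max) {
    matrix(0, nrow(adj), ncol(adj))
  } else {
    simplex_projection(K, q, weighted = FALSE)
  }
  out <- adj * ((adj != 0) & (mask != 0))
  dimnames(out) <- dimnames(adj)
  out
}

#' Batch graded parameters over a collection of networks
#'
#' Converts each adjacency matrix to its clique complex, computes the
#' requested graded series, and aligns all networks to a common q-domain
#' 0..`max_order` by zero-padding (levels a network does not reach, and
#' undefined entropy levels, are reported as 0 in the array). The transform is
#' stateless and permutation-equivariant: permuting the input networks
#' permutes the output rows identically.
#'
#' @param networks Non-empty list of adjacency matrices.
#' @param desired Series names as in [graded_parameters()]; `NULL` means all.
#' @param max_order Common highest q; defaults to the largest d_max over the
#'   collection.
#' @return 3-axis numeric array with dimensions (network, vector, q) and
#'   dimnames on the vector and q axes.
#' @export
batch_graded_parameters <- function(networks, desired = NULL, max_order = NULL) {
  if (!is.list(networks) || length(networks) == 0L) {
    stop("`networks` must be a non-empty list of adjacency matrices")
  }
  bundles <- lapply(networks, function(a) {
    graded_parameters(complex_from_adjacency(a), desired)
  })
  if (is.null(max_order)) {
    max_order <- max(vapply(bundles, function(b) b$d_max, integer(1)))
  }
  mats <- lapply(bundles, bundle_matrix, max_order = max_order)
  series_names <- rownames(mats[[1]])
  out <- array(
    0, dim = c(length(networks), length(series_names), max_order + 1L),
    dimnames = list(names(networks), series_names, 0:max_order)
  )
  for (i in seq_along(mats)) out[i, , ] <- mats[[i]]
  out
}

#' Batch q-connected component labelings
#'
#' Applies [q_connected_components_labeled()] to each simplex list in a
#' collection; per-item failures are reported with the item index.
#'
#' @param complexes Non-empty list of simplex lists (each valid for
#'   [simplicial_complex()]).
#' @param q Dimensional level applied to every complex.
#' @return List of `q_component_labeling` objects.
#' @export
batch_component_labels <- function(complexes, q) {
  if (!is.list(complexes) || length(complexes) == 0L) {
    stop("`complexes` must be a non-empty list of simplex lists")
  }
  lapply(seq_along(complexes), function(i) {
    tryCatch(
      q_connected_components_labeled(simplicial_complex(complexes[[i]]), q),
      error = function(e) stop(sprintf("item %d: %s", i, conditionMessage(e)))
    )
  })
}
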