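#' Construct a simplicial complex from a list of simplices
#'
#' A simplicial complex is represented here by the simplices the user supplies:
#' each record is one multi-node interaction (a group of vertex labels), and
#' all metrics are defined over these stored simplices. Lower-dimensional faces
#' are implicit and never materialised, so a stored simplex may be a subset of
#' another (e.g. a small author team that is also part of a larger one); such
#' records are kept as distinct analysis units.
#'
#' Within a simplex, repeated labels are collapsed (set semantics), so
#' `list(c(1, 1, 2))` yields a single 1-simplex. Duplicate simplices
#' (identical vertex sets) are retained by default because they may encode
#' distinct interactions; set `keep_duplicates = FALSE` to collapse them.
#'
#' @param simplices A non-empty list; each element is a non-empty vector of
#'   vertex labels (character, integer or factor — coerced to character).
#' @param keep_duplicates Keep simplices with identical vertex sets as separate
#'   records (default `TRUE`).
#' @return An object of class `simplicial_complex` with elements
#'   `simplices` (list of sorted integer vertex-index vectors), `labels`
#'   (character vector mapping index to label, first-appearance order),
#'   `dims` (integer vector of simplex dimensions), and scalars `m`, `n`,
#'   `d_max`, `s_max`.
#' @examples
#' K <- simplicial_complex(list(c("v1", "v2", "v3"), c("v2", "v3", "v4")))
#' K$d_max  # 2
#' @export
simplicial_complex <- function(simplices, keep_duplicates = TRUE) {
  if (!is.list(simplices) || length(simplices) == 0L) {
    stop("`simplices` must be a non-empty list of vertex-label vectors")
  }
  recs <- lapply(seq_along(simplices), function(i) {
    s <- simplices[[i]]
    s <- s[!is.na(s)]
    if (length(s) == 0L) {
      stop(sprintf("simplex %d is empty", i))
    }
    unique(as.character(s))
  })
  labels <- unique(unlist(recs, use.names = FALSE))
  idx <- lapply(recs, function(s) sort(match(s, labels)))
  if (!keep_duplicates) {
    keys <- vapply(idx, paste, character(1), collapse = ",")
    idx <- idx[!duplicated(keys)]
  }
  new_simplicial_complex(idx, labels)
}

# Internal constructor: `idx` is a list of sorted integer vectors over 1..n.
new_simplicial_complex <- function(idx, labels) {
  dims <- lengths(idx) - 1L
  obj <- list(
    simplices = idx,
    labels = labels,
    dims = dims,
    m = length(idx),
    n = length(labels),
    d_max = max(dims),
    s_max = max(lengths(idx)),
    .cache = new.env(parent = emptyenv())
  )
  class(obj) <- "simplicial_complex"
  obj
}

#' @export
print.simplicial_complex <- function(x, ...) {
  cat(sprintf(
    "Simplicial complex: %d simplices over %d vertices (d_max = %d)\n",
    x$m, x$n, x$d_max
  ))
  invisible(x)
}

#' Build the clique complex of a graph
#'
#' Converts an undirected graph, given as an adjacency matrix, into a
#' simplicial complex whose simplices are the maximal cliques of the graph.
#' Isolated vertices become 0-simplices. Clique enumeration order is
#' implementation-defined, so the simplices are sorted lexicographically on
#' their sorted vertex indices to make the complex deterministic.
#'
#' @param adj Square numeric matrix; nonzero entries are edges, the diagonal
#'   is ignored. Must be symmetric; asymmetric or negative input is an error
#'   rather than being silently repaired.
#' @param labels Optional character vector of vertex labels; defaults to the
#'   matrix dimnames, else `"1"..."n"`.
#' @param tol Tolerance for the symmetry check.
#' @return A `simplicial_complex`.
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' complex_from_adjacency(tri)  # one 2-simplex
#' @export
complex_from_adjacency <- function(adj, labels = NULL, tol = 1e-8) {
  adj <- validate_adjacency(adj, tol = tol)
  n <- nrow(adj)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(adj))) rownames(adj) else as.character(seq_len(n))
  }
  if (length(labels) != n) stop("`labels` must have one entry per vertex")
  g <- igraph::graph_from_adjacency_matrix(
    (adj != 0) * 1, mode = "undirected", diag = FALSE
  )
  cliques <- lapply(igraph::max_cliques(g, min = 1), function(cl) sort(as.integer(cl)))
  ord <- order_lexicographic(cliques)
  new_simplicial_complex(cliques[ord], labels)
}

validate_adjacency <- function(adj, tol = 1e-8) {
  adj <- as.matrix(adj)
  if (!is.numeric(adj)) stop("adjacency matrix must be numeric")
  if (nrow(adj) != ncol(adj)) stop("adjacency matrix must be square")
  if (any(adj < 0)) stop("adjacency matrix must be non-negative")
  if (max(abs(adj - t(adj))) > tol) stop("adjacency matrix must be symmetric")
  adj
}

# Order a list of integer vectors lexicographically.
order_lexicographic <- function(vs) {
  keys <- vapply(
    vs, function(v) paste(sprintf("%09d", v), collapse = " "), character(1)
  )
  order(keys)
}

#' Incidence matrix of a complex
#'
#' The binary m x n matrix Lambda with `Lambda[i, j] = 1` iff vertex j belongs
#' to simplex i. Row sums equal simplex sizes.
#'
#' @param K A `simplicial_complex`.
#' @return Integer matrix with simplex rows and vertex-label columns.
#' @export
incidence_matrix <- function(K) {
  stopifnot(inherits(K, "simplicial_complex"))
  lam <- matrix(0L, K$m, K$n, dimnames = list(NULL, K$labels))
  for (i in seq_len(K$m)) lam[i, K$simplices[[i]]] <- 1L
  lam
}

#' Connectivity (q-nearness) matrix of a complex
#'
#' The m x m matrix Pi = Lambda Lambda^T - 1: entry (i, j) is the number of
#' shared vertices minus one, i.e. the dimension of the largest shared face
#' (-1 for disjoint simplices). The diagonal holds simplex dimensions.
#'
#' @param K A `simplicial_complex`.
#' @return Integer matrix of shared-face dimensions.
#' @export
connectivity_matrix <- function(K) {
  stopifnot(inherits(K, "simplicial_complex"))
  if (!is.null(K$.cache$pi)) return(K$.cache$pi)
  lam <- incidence_matrix(K)
  pi_mat <- tcrossprod(lam) - 1L
  storage.mode(pi_mat) <- "integer"
  K$.cache$pi <- pi_mat
  pi_mat
}

#' q-nearness of two simplices
#'
#' Returns the dimension of the largest face shared by simplices `i` and `j`
#' (the connectivity-matrix entry): -1 if disjoint, `dim(sigma_i)` when
#' `i == j`. Simplices i and j are q-near whenever this value is at least q.
#'
#' @param K A `simplicial_complex`.
#' @param i,j Simplex positions (1-based).
#' @return Integer shared-face dimension.
#' @export
q_nearness <- function(K, i, j) {
  stopifnot(inherits(K, "simplicial_complex"))
  check_simplex_index(K, i)
  check_simplex_index(K, j)
  length(intersect(K$simplices[[i]], K$simplices[[j]])) - 1L
}

check_simplex_index <- function(K, i) {
  if (!is.numeric(i) || length(i) != 1L || is.na(i) || i < 1 || i > K$m || i != floor(i)) {
    stop(sprintf("simplex index must be an integer in 1..%d", K$m))
  }
}

# Components for every q-level at once, cached on the complex. At level q only
# simplices with dim >= q are eligible; edges join eligible pairs with
# Pi_ij >= q. Returns a list indexed by q + 1 with elements `eligible`
# (simplex positions) and `membership` (component id per eligible simplex,
# numbered by ascending smallest member position).
components_all_levels <- function(K) {
  if (!is.null(K$.cache$components)) return(K$.cache$components)
  pi_mat <- connectivity_matrix(K)
  out <- vector("list", K$d_max + 1L)
  for (q in 0:K$d_max) {
    eligible <- which(K$dims >= q)
    sub <- pi_mat[eligible, eligible, drop = FALSE] >= q
    g <- igraph::graph_from_adjacency_matrix(sub * 1, mode = "undirected", diag = FALSE)
    memb <- igraph::components(g)$membership
    # renumber components by ascending smallest member position
    first <- vapply(split(seq_along(memb), memb), min, integer(1))
    relabel <- match(names(sort(first)), names(first))
    memb <- match(memb, relabel)
    out[[q + 1L]] <- list(eligible = eligible, membership = as.integer(memb))
  }
  K$.cache$components <- out
  out
}

check_q_level <- function(K, q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q != floor(q) ||
      q < 0 || q > K$d_max) {
    stop(sprintf("q must be an integer in 0..%d (d_max)", K$d_max))
  }
  as.integer(q)
}

#' Number of q-connected components
#'
#' Two simplices are q-connected when a chain of pairwise q-near simplices
#' joins them; a q-connected component is a maximal q-connected set of
#' simplices of dimension >= q. A lone eligible simplex forms its own
#' component. The first call computes the components for all levels
#' 0..`d_max` at once and caches them; later calls read the cache.
#'
#' @param K A `simplicial_complex`.
#' @param q Dimensional level, `0 <= q <= d_max`.
#' @return Integer component count.
#' @examples
#' K <- simplicial_complex(list(c(1, 2, 3), c(2, 3, 4)))
#' q_connected_components(K, 2)  # 2
#' q_connected_components(K, 1)  # 1
#' @export
q_connected_components <- function(K, q) {
  stopifnot(inherits(K, "simplicial_complex"))
  q <- check_q_level(K, q)
  comp <- components_all_levels(K)[[q + 1L]]
  if (length(comp$membership) == 0L) 0L else max(comp$membership)
}

#' q-connected components with simplex labels
#'
#' Returns the partition of the eligible simplices (those with dim >= q) into
#' q-connected components. Component ids are assigned by ascending smallest
#' member position, so labelings are deterministic.
#'
#' @inheritParams q_connected_components
#' @return An object of class `q_component_labeling`: list with `q`,
#'   `components` (list of integer vectors of simplex positions) and
#'   `membership` (named integer vector, component id per eligible simplex).
#' @export
q_connected_components_labeled <- function(K, q) {
  stopifnot(inherits(K, "simplicial_complex"))
  q <- check_q_level(K, q)
  comp <- components_all_levels(K)[[q + 1L]]
  groups <- split(comp$eligible, comp$membership)
  names(groups) <- NULL
  membership <- stats::setNames(comp$membership, comp$eligible)
  structure(
    list(q = q, components = lapply(groups, as.integer), membership = membership),
    class = "q_component_labeling"
  )
}

#' @export
print.q_component_labeling <- function(x, ...) {
  cat(sprintf("%d q-connected component(s) at q = %d\n", length(x$components), x$q))
  for (i in seq_along(x$components)) {
    cat(sprintf("  [%d] simplices: %s\n", i, paste(x$components[[i]], collapse = ", ")))
  }
  invisible(x)
}
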