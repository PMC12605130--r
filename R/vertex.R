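#' Topological dimensionality of every vertex
#'
#' The number of stored simplices each vertex belongs to — the diagonal of
#' t(Lambda) %*% Lambda. It generalises vertex degree to multi-node
#' interactions: vertices with high values act as hubs of the higher-order
#' structure.
#'
#' @param K A `simplicial_complex`.
#' @param node_names Optional character vector of display names, one per
#'   vertex (in vertex-index order); defaults to the complex's labels.
#' @return An object of class `node_values`: list with `values` (named numeric
#'   vector) and `metric`.
#' @examples
#' K <- simplicial_complex(list(c("v1", "v2", "v3"), c("v2", "v3", "v4")))
#' topological_dimensionality(K)$values  # v1 1, v2 2, v3 2, v4 1
#' @export
topological_dimensionality <- function(K, node_names = NULL) {
  stopifnot(inherits(K, "simplicial_complex"))
  if (is.null(node_names)) {
    node_names <- K$labels
  } else if (length(node_names) != K$n) {
    stop(sprintf("`node_names` must have length %d (one per vertex)", K$n))
  }
  d <- integer(K$n)
  for (s in K$simplices) d[s] <- d[s] + 1L
  structure(
    list(values = stats::setNames(as.numeric(d), node_names),
         metric = "Topological Dimensionality"),
    class = "node_values"
  )
}

#' @export
print.node_values <- function(x, ...) {
  cat(x$metric, "per vertex:\n")
  print(x$values)
  invisible(x)
}

#' @export
as.data.frame.node_values <- function(x, ...) {
  out <- data.frame(Node = names(x$values), Value = unname(x$values),
                    stringsAsFactors = FALSE)
  names(out)[2] <- x$metric
  out
}

# Resolve a simplex reference: a single position index, or a vertex-label set
# that must match a stored simplex exactly.
resolve_simplex_ref <- function(K, ref) {
  if (is.numeric(ref) && length(ref) == 1L) {
    check_simplex_index(K, ref)
    return(as.integer(ref))
  }
  pos <- match(unique(as.character(ref)), K$labels)
  if (anyNA(pos)) {
    stop(sprintf("unknown vertex label(s): %s",
                 paste(setdiff(as.character(ref), K$labels), collapse = ", ")))
  }
  want <- sort(pos)
  for (i in seq_len(K$m)) {
    if (identical(K$simplices[[i]], want)) return(i)
  }
  stop(sprintf("no stored simplex has vertex set {%s}",
               paste(as.character(ref), collapse = ", ")))
}

#' Eccentricity of one simplex relative to another
#'
#' The fraction of the first simplex's vertices not shared with the second,
#' `|a \ b| / |a|`. It is 0 iff `a` is a face of `b` and 1 iff the two are
#' disjoint; it is asymmetric in general.
#'
#' @param K A `simplicial_complex`.
#' @param a,b Simplex references: a position index or a vertex-label set
#'   matching a stored simplex.
#' @return Numeric in `[0, 1]`.
#' @export
eccentricity <- function(K, a, b) {
  stopifnot(inherits(K, "simplicial_complex"))
  ia <- resolve_simplex_ref(K, a)
  ib <- resolve_simplex_ref(K, b)
  sa <- K$simplices[[ia]]
  sb <- K$simplices[[ib]]
  length(setdiff(sa, sb)) / length(sa)
}

#' Minimum eccentricity of a simplex over a family
#'
#' The smallest eccentricity of `s` relative to any member of `family`. The
#' default family is every stored simplex except `s` itself (including `s`
#' would force the trivial value 0).
#'
#' @param K A `simplicial_complex`.
#' @param s Simplex reference (index or vertex-label set).
#' @param family Optional list of simplex references; defaults to all other
#'   simplices.
#' @return Numeric in `[0, 1]`.
#' @export
family_eccentricity <- function(K, s, family = NULL) {
  stopifnot(inherits(K, "simplicial_complex"))
  is <- resolve_simplex_ref(K, s)
  if (is.null(family)) {
    fam <- setdiff(seq_len(K$m), is)
  } else {
    fam <- vapply(family, function(f) resolve_simplex_ref(K, f), integer(1))
  }
  if (length(fam) == 0L) stop("family of simplices is empty")
  min(vapply(fam, function(f) eccentricity(K, is, f), numeric(1)))
}
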