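#' @title Graded parameter sets
#' @description Q-analysis summarises a complex by values graded by the
#'   dimensional level q, with q running 0..d_max: component counts (FSV),
#'   cumulative simplex counts (SSV), normalised connectedness (TSV),
#'   topological entropy, per-dimension simplex counts and shared-face counts.
#'   Each is a `graded_series`; `graded_parameters()` bundles them.
#' @name graded
NULL

GRADED_SERIES_NAMES <- c("FSV", "SSV", "TSV", "Entropy", "SimplexCount", "SharedFaces")

new_graded_series <- function(name, values) {
  structure(
    list(name = name, q = seq_along(values) - 1L, values = unname(values)),
    class = "graded_series"
  )
}

#' @export
print.graded_series <- function(x, ...) {
  # descending-q display matches the conventional vector notation
  vals <- rev(x$values)
  cat(sprintf(
    "%s (q = %d..0): [%s]\n", x$name, max(x$q),
    paste(formatC(vals, format = "g"), collapse = ", ")
  ))
  invisible(x)
}

#' @export
as.data.frame.graded_series <- function(x, ...) {
  data.frame(Vector = x$name, q = x$q, Value = x$values, stringsAsFactors = FALSE)
}

#' First structure vector (FSV)
#'
#' The number of q-connected components at each level q = 0..d_max. Displayed
#' descending in q (the conventional notation); stored ascending with explicit
#' q values.
#'
#' @param K A `simplicial_complex`.
#' @return A `graded_series` named `"FSV"`.
#' @examples
#' K <- simplicial_complex(list(c(1, 2, 3), c(2, 3, 4)))
#' fsv(K)  # [2, 1, 1] in descending-q display
#' @export
fsv <- function(K) {
  stopifnot(inherits(K, "simplicial_complex"))
  vals <- vapply(0:K$d_max, function(q) q_connected_components(K, q), integer(1))
  new_graded_series("FSV", vals)
}

#' Second structure vector (SSV)
#'
#' The number of simplices of dimension >= q at each level; non-increasing in
#' q, with `SSV[0] = m`.
#'
#' @inheritParams fsv
#' @return A `graded_series` named `"SSV"`.
#' @export
ssv <- function(K) {
  stopifnot(inherits(K, "simplicial_complex"))
  vals <- vapply(0:K$d_max, function(q) sum(K$dims >= q), integer(1))
  new_graded_series("SSV", vals)
}

#' Third structure vector (TSV)
#'
#' Normalised connectedness per level: `1 - Q_q / n_q`, where Q_q is the
#' component count and n_q the eligible-simplex count. Values near 1 indicate
#' highly connected levels; 0 means every eligible simplex is its own
#' component.
#'
#' @inheritParams fsv
#' @return A `graded_series` named `"TSV"` with values in `[0, 1)`.
#' @export
tsv <- function(K) {
  stopifnot(inherits(K, "simplicial_complex"))
  q_vals <- fsv(K)$values
  n_vals <- ssv(K)$values
  new_graded_series("TSV", 1 - q_vals / n_vals)
}

# Vertex participation counts Q_v^q: number of stored simplices of dimension
# exactly q (or >= q, cumulative mode) containing each vertex. Returns an
# n x (d_max + 1) integer matrix.
vertex_participation <- function(K, participation = c("exact", "cumulative")) {
  participation <- match.arg(participation)
  counts <- matrix(0L, K$n, K$d_max + 1L, dimnames = list(K$labels, 0:K$d_max))
  for (i in seq_len(K$m)) {
    d <- K$dims[i]
    cols <- if (participation == "exact") d + 1L else seq_len(d + 1L)
    counts[K$simplices[[i]], cols] <- counts[K$simplices[[i]], cols] + 1L
  }
  counts
}

#' Topological entropy per level
#'
#' An information-theoretic measure of how evenly vertices participate in the
#' q-dimensional simplices. With `Q_v^q` the number of dimension-q simplices
#' containing vertex v, `p_v^q = Q_v^q / sum_v Q_v^q` over participating
#' vertices and `M_q` their count, the entropy is
#' `-sum_v p_v^q log p_v^q / log M_q`. Values near 1 indicate decentralised,
#' evenly spread participation; values near 0 indicate hub-dominated levels.
#'
#' Degenerate levels: when no stored simplex has dimension exactly q the value
#' is `NaN` (the level is undefined); when a single vertex participates
#' (`M_q <= 1`) the value is 0. The logarithm base cancels in the ratio.
#'
#' @inheritParams fsv
#' @param participation Count simplices of dimension exactly q (`"exact"`,
#'   default) or at least q (`"cumulative"`).
#' @return A `graded_series` named `"Entropy"` with values in `[0, 1]` where
#'   defined.
#' @export
topological_entropy <- function(K, participation = c("exact", "cumulative")) {
  stopifnot(inherits(K, "simplicial_complex"))
  participation <- match.arg(participation)
  counts <- vertex_participation(K, participation)
  vals <- vapply(0:K$d_max, function(q) {
    cnt <- counts[, q + 1L]
    cnt <- cnt[cnt > 0]
    if (length(cnt) == 0L) return(NaN)
    if (length(cnt) <= 1L) return(0)
    p <- cnt / sum(cnt)
    -sum(p * log(p)) / log(length(cnt))
  }, numeric(1))
  new_graded_series("Entropy", vals)
}

#' Number of simplices at each exact dimension
#'
#' Counts stored simplices with dimension exactly q. Relates to the SSV by
#' `SSV[q] = sum over q' >= q of SimplexCount[q']`.
#'
#' @inheritParams fsv
#' @return A `graded_series` named `"SimplexCount"`.
#' @export
simplex_count_per_dim <- function(K) {
  stopifnot(inherits(K, "simplicial_complex"))
  vals <- vapply(0:K$d_max, function(q) sum(K$dims == q), integer(1))
  new_graded_series("SimplexCount", vals)
}

#' Number of shared faces at each level
#'
#' Counts unordered simplex pairs whose shared face has dimension at least q
#' (`count = "cumulative"`, default, mirroring the q-nearness convention) or
#' exactly q (`count = "exact"`).
#'
#' @inheritParams fsv
#' @param count `"cumulative"` (pairs with shared-face dimension >= q) or
#'   `"exact"`.
#' @return A `graded_series` named `"SharedFaces"`.
#' @export
shared_face_count <- function(K, count = c("cumulative", "exact")) {
  stopifnot(inherits(K, "simplicial_complex"))
  count <- match.arg(count)
  pi_mat <- connectivity_matrix(K)
  upper <- pi_mat[upper.tri(pi_mat)]
  vals <- vapply(0:K$d_max, function(q) {
    if (count == "cumulative") sum(upper >= q) else sum(upper == q)
  }, integer(1))
  new_graded_series("SharedFaces", vals)
}

#' Compute a bundle of graded parameter sets
#'
#' Computes the requested graded series over the shared q-domain 0..d_max and
#' returns them in a single container exportable as a tidy table.
#'
#' @param K A `simplicial_complex`.
#' @param desired Character vector of series names among `"FSV"`, `"SSV"`,
#'   `"TSV"`, `"Entropy"`, `"SimplexCount"`, `"SharedFaces"`
#'   (case-insensitive). `NULL` or empty means all six.
#' @param participation Passed to [topological_entropy()].
#' @param shared_face_mode Passed to [shared_face_count()] as `count`.
#' @return An object of class `graded_bundle`: list with `series` (named list
#'   of `graded_series`) and `d_max`.
#' @examples
#' K <- simplicial_complex(list(c(1, 2, 3), c(2, 3, 4)))
#' graded_parameters(K, c("FSV", "SSV", "TSV"))
#' @export
graded_parameters <- function(K, desired = NULL,
                              participation = c("exact", "cumulative"),
                              shared_face_mode = c("cumulative", "exact")) {
  stopifnot(inherits(K, "simplicial_complex"))
  participation <- match.arg(participation)
  shared_face_mode <- match.arg(shared_face_mode)
  if (is.null(desired) || length(desired) == 0L) {
    desired <- GRADED_SERIES_NAMES
  } else {
    pos <- match(tolower(desired), tolower(GRADED_SERIES_NAMES))
    if (anyNA(pos)) {
      stop(sprintf(
        "unknown series name(s): %s; supported: %s",
        paste(desired[is.na(pos)], collapse = ", "),
        paste(GRADED_SERIES_NAMES, collapse = ", ")
      ))
    }
    desired <- GRADED_SERIES_NAMES[pos]
  }
  series <- lapply(desired, function(nm) {
    switch(nm,
      FSV = fsv(K),
      SSV = ssv(K),
      TSV = tsv(K),
      Entropy = topological_entropy(K, participation),
      SimplexCount = simplex_count_per_dim(K),
      SharedFaces = shared_face_count(K, shared_face_mode)
    )
  })
  names(series) <- desired
  structure(list(series = series, d_max = K$d_max), class = "graded_bundle")
}

#' @export
print.graded_bundle <- function(x, ...) {
  cat(sprintf("Graded parameters (q = 0..%d):\n", x$d_max))
  for (s in x$series) print(s)
  invisible(x)
}

#' Export a graded bundle as a tidy long-format table
#'
#' One row per (series, q) with fixed columns `Vector`, `q`, `Value`, plus any
#' caller-supplied constant columns (e.g. `c(Network = "toy")`). Undefined
#' entropy levels appear as `NA` unless `drop_undefined = TRUE`.
#'
#' @param bundle A `graded_bundle`.
#' @param extra_columns Named character/numeric vector of constant columns
#'   appended after `Value`. Names may not collide with the reserved columns.
#' @param drop_undefined Drop rows whose value is undefined (`NaN`/`NA`).
#' @return A `data.frame`.
#' @export
to_tidy_table <- function(bundle, extra_columns = NULL, drop_undefined = FALSE) {
  stopifnot(inherits(bundle, "graded_bundle"))
  tab <- do.call(rbind, lapply(bundle$series, as.data.frame))
  rownames(tab) <- NULL
  tab$Value[is.nan(tab$Value)] <- NA_real_
  if (!is.null(extra_columns)) {
    nms <- names(extra_columns)
    if (is.null(nms) || any(nms == "")) stop("`extra_columns` must be named")
    if (any(nms %in% c("Vector", "q", "Value"))) {
      stop("`extra_columns` may not use the reserved names Vector, q, Value")
    }
    for (nm in nms) tab[[nm]] <- extra_columns[[nm]]
  }
  if (drop_undefined) tab <- tab[!is.na(tab$Value), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# Values of a bundle as a (series x q) numeric matrix, optionally zero-padded
# to columns 0..max_order; NaN (undefined entropy levels) become 0 in arrays.
bundle_matrix <- function(bundle, max_order = NULL) {
  len <- bundle$d_max + 1L
  if (is.null(max_order)) max_order <- bundle$d_max
  if (max_order < bundle$d_max) stop("max_order smaller than the bundle's d_max")
  out <- matrix(0, length(bundle$series), max_order + 1L,
                dimnames = list(names(bundle$series), 0:max_order))
  for (i in seq_along(bundle$series)) {
    v <- bundle$series[[i]]$values
    v[is.nan(v)] <- 0
    out[i, seq_len(len)] <- v
  }
  out
}
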