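#' Read a simplex list from a plain-text file
#'
#' One simplex per line, whitespace-separated vertex labels. Lines starting
#' with `#` and blank lines are skipped; order is preserved.
#'
#' @param path Path to a readable text file.
#' @return List of character vectors of vertex labels.
#' @export
read_simplex_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  recs <- lapply(strsplit(lines, "[[:space:]]+"), function(x) x[nzchar(x)])
  recs <- recs[lengths(recs) > 0]
  if (length(recs) == 0L) stop(sprintf("no simplices found in '%s'", path))
  recs
}

#' Read an adjacency matrix from CSV or whitespace-delimited text
#'
#' Accepts a numeric square matrix, optionally with a header row and/or a
#' leading label column; labels, when present, are attached as dimnames.
#' Ragged rows and asymmetric matrices are errors reporting the location.
#'
#' @param path Path to the matrix file.
#' @return Square symmetric numeric matrix (possibly with label dimnames).
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop(sprintf("'%s' is empty", path))
  sep <- if (any(grepl(",", lines))) "," else "[[:space:]]+"
  rows <- lapply(lines, function(l) {
    x <- strsplit(l, sep)[[1]]
    trimws(x[nzchar(trimws(x))])
  })
  is_num <- function(x) !anyNA(suppressWarnings(as.numeric(x)))
  labels <- NULL
  # header row: first line not fully numeric
  if (!is_num(rows[[1]])) {
    labels <- rows[[1]]
    rows <- rows[-1]
  }
  # leading label column: first token of each remaining row non-numeric
  if (length(rows) > 0 && all(vapply(rows, function(r) !is_num(r[1]), logical(1)))) {
    row_labels <- vapply(rows, `[`, character(1), 1)
    rows <- lapply(rows, function(r) r[-1])
    if (is.null(labels)) labels <- row_labels
  }
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged row %d in '%s'", bad, path))
  }
  mat <- do.call(rbind, lapply(seq_along(rows), function(i) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v)) stop(sprintf("non-numeric entry in row %d of '%s'", i, path))
    v
  }))
  if (nrow(mat) != ncol(mat)) {
    stop(sprintf("matrix in '%s' is %dx%d, not square", path, nrow(mat), ncol(mat)))
  }
  if (!is.null(labels)) {
    if (length(labels) == nrow(mat)) dimnames(mat) <- list(labels, labels)
  }
  validate_adjacency(mat)
}

#' Read an undirected edge list (TSV) as an adjacency matrix
#'
#' Two or three tab- or whitespace-separated columns: source, target and an
#' optional weight. Vertices are indexed in first-appearance order.
#'
#' @param path Path to the edge-list file.
#' @return Square symmetric numeric matrix with label dimnames.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop(sprintf("no edges found in '%s'", path))
  rows <- strsplit(lines, "[[:space:]]+")
  if (any(!lengths(rows) %in% c(2L, 3L))) {
    bad <- which(!lengths(rows) %in% c(2L, 3L))[1]
    stop(sprintf("line %d of '%s' does not have 2 or 3 columns", bad, path))
  }
  labels <- unique(unlist(lapply(rows, `[`, 1:2)))
  n <- length(labels)
  adj <- matrix(0, n, n, dimnames = list(labels, labels))
  for (r in rows) {
    w <- if (length(r) == 3L) as.numeric(r[3]) else 1
    i <- match(r[1], labels)
    j <- match(r[2], labels)
    adj[i, j] <- w
    adj[j, i] <- w
  }
  diag(adj) <- 0
  adj
}

#' Write a network ensemble to a directory
#'
#' One adjacency CSV per network (`network_001.csv`, ...) plus a
#' `manifest.json` recording the generator parameters and seed, so an
#' ensemble directory is self-describing and reloadable.
#'
#' @param networks List of adjacency matrices.
#' @param dir Output directory (created if needed).
#' @param spec Optional `generator_spec` recorded in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_ensemble <- function(networks, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(networks)) {
    utils::write.table(
      as.matrix(networks[[i]]),
      file.path(dir, sprintf("network_%03d.csv", i)),
      sep = ",", row.names = FALSE, col.names = FALSE
    )
  }
  manifest <- list(n_networks = length(networks))
  if (!is.null(spec)) manifest$spec <- unclass(spec)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a network ensemble directory
#'
#' Loads every `*.csv` adjacency matrix in the directory, in sorted filename
#' order.
#'
#' @param dir Ensemble directory as written by [write_ensemble()].
#' @return List of adjacency matrices.
#' @export
read_ensemble <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no CSV networks found in '%s'", dir))
  lapply(files, read_adjacency)
}
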