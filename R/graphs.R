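#' Construct a time-series matrix object
#'
#' Wraps a node-by-time numeric matrix (one recording site per row) with
#' subject and node identifiers. Node order is assumed to be the cohort-wide
#' canonical order: all subjects in an analysis must present the same nodes
#' in the same order.
#'
#' @param values numeric matrix, `n_nodes x n_timepoints`; no missing values,
#'   at least 3 timepoints.
#' @param node_ids character or integer node identifiers (default `1:N`).
#' @param subject_id subject label.
#' @return an object of class `ts_matrix`.
#' @export
ts_matrix <- function(values, node_ids = NULL, subject_id = "subject") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix (nodes x timepoints)")
  }
  if (anyNA(values)) stopf("time-series matrix contains missing values")
  if (ncol(values) < 3) stopf("need at least 3 timepoints, got %d", ncol(values))
  if (is.null(node_ids)) node_ids <- seq_len(nrow(values))
  if (length(node_ids) != nrow(values)) {
    stopf("node_ids length (%d) != number of rows (%d)",
          length(node_ids), nrow(values))
  }
  structure(list(values = unname(values),
                 node_ids = as.character(node_ids),
                 subject_id = as.character(subject_id)),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("<ts_matrix> subject '%s': %d nodes x %d timepoints\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Pearson correlation matrix of a subject's node time series
#'
#' @param ts a [ts_matrix()] (or a bare numeric node-by-time matrix).
#' @return an `N x N` symmetric matrix of class `corr_matrix`, unit diagonal.
#'   Zero-variance node series are an error (their correlation is undefined).
#' @export
correlation_matrix <- function(ts) {
  if (inherits(ts, "ts_matrix")) {
    x <- ts$values
    ids <- ts$node_ids
  } else if (is.matrix(ts) && is.numeric(ts)) {
    x <- ts
    ids <- as.character(seq_len(nrow(x)))
  } else {
    stopf("`ts` must be a ts_matrix or numeric matrix")
  }
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    stopf("zero-variance node series: %s",
          paste(ids[v == 0], collapse = ", "))
  }
  r <- stats::cor(t(x))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  class(r) <- c("corr_matrix", class(r))
  r
}

#' Number of edges realized at a target link density
#'
#' Link density is the fraction of retained edges out of the
#' `N * (N - 1) / 2` possible node pairs. The edge count is floored so the
#' realized density never exceeds the nominal one.
#'
#' @param N node count (>= 2).
#' @param density target density in `(0, 1]`.
#' @return integer `M = floor(density * N * (N - 1) / 2)`; an error if that
#'   would be zero.
#' @export
target_edge_count <- function(N, density) {
  if (!is_count(N) || N < 2) stopf("N must be an integer >= 2")
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density > 1) {
    stopf("density must be a single value in (0, 1]")
  }
  M <- floor(density * N * (N - 1) / 2)
  if (M < 1) {
    stopf("density %.4g at N = %d yields zero edges", density, N)
  }
  as.integer(M)
}

new_binary_graph <- function(N, edges, density, threshold_used = NA_real_) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(N = as.integer(N), edges = edges, M = nrow(edges),
                 density = density, threshold_used = threshold_used),
            class = "binary_graph")
}

#' Build a binary graph from an explicit edge list
#'
#' @param N node count.
#' @param edges two-column matrix of node index pairs (1-based, no
#'   self-loops, duplicates collapsed).
#' @return a `binary_graph`: undirected simple graph with fields `N`,
#'   `edges`, `M`, `density`, `threshold_used`.
#' @export
binary_graph <- function(N, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (any(edges < 1) || any(edges > N)) stopf("edge endpoint out of range")
  if (any(edges[, 1] == edges[, 2])) stopf("self-loops are not allowed")
  key <- pmin(edges[, 1], edges[, 2]) * (N + 1) + pmax(edges[, 1], edges[, 2])
  edges <- edges[!duplicated(key), , drop = FALSE]
  g <- new_binary_graph(N, edges, density = nrow(edges) / (N * (N - 1) / 2))
  g
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> N = %d, M = %d (density %.3g)\n",
              x$N, x$M, x$density))
  invisible(x)
}

#' Convert a binary graph to an igraph object
#'
#' @param graph a `binary_graph`.
#' @return an undirected [igraph::graph] with `N` vertices.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  g <- igraph::make_empty_graph(n = graph$N, directed = FALSE)
  igraph::add_edges(g, t(graph$edges))
}

to_igraph <- as_igraph

#' Threshold a correlation matrix to an exact link density
#'
#' Ranks all off-diagonal pairs by absolute correlation (sign is ignored:
#' strong negative correlations also form edges) and keeps exactly
#' [target_edge_count()] pairs. Ties at the cut are broken by lexicographic
#' node-pair order so reruns are bit-identical. The realized threshold (the
#' weakest retained `|r|`) is recorded.
#'
#' @param corr correlation matrix (from [correlation_matrix()] or any
#'   symmetric numeric matrix with unit diagonal).
#' @param density target link density in `(0, 1]`.
#' @return a `binary_graph` with exactly `M` edges.
#' @export
threshold_to_density <- function(corr, density) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stopf("`corr` must be a square matrix")
  }
  N <- nrow(corr)
  M <- target_edge_count(N, density)
  ut <- which(upper.tri(corr), arr.ind = TRUE) # already lexicographic (i, j)
  a <- abs(corr[upper.tri(corr)])
  if (sum(a > 0) < M) {
    stopf("only %d nonzero |r| values but %d edges requested", sum(a > 0), M)
  }
  # order by |r| descending; ties by (row, col) ascending
  ord <- order(-a, ut[, 1], ut[, 2])
  keep <- ord[seq_len(M)]
  g <- new_binary_graph(N, ut[keep, , drop = FALSE], density = density,
                        threshold_used = min(a[keep]))
  g
}

#' Graphs at a sweep of link densities
#'
#' Same `|r|` ranking, growing cut: the edge set at a lower density is a
#' subset of the edge set at any higher density.
#'
#' @param corr correlation matrix.
#' @param densities ascending densities in `(0, 1]`.
#' @return a list of `binary_graph`, one per density.
#' @export
density_sweep <- function(corr, densities = seq(0.1, 0.5, by = 0.1)) {
  if (length(densities) == 0) stopf("empty density list")
  if (is.unsorted(densities, strictly = TRUE)) {
    stopf("densities must be strictly ascending")
  }
  lapply(densities, function(d) threshold_to_density(corr, d))
}

#' Connected components of a binary graph
#'
#' @param graph a `binary_graph`.
#' @return list of integer node-index vectors, largest first, with attribute
#'   `is_fully_connected` (TRUE iff a single component).
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  comp <- igraph::components(to_igraph(graph))
  out <- split(seq_len(graph$N), comp$membership)
  out <- out[order(-vapply(out, length, 1L))]
  names(out) <- NULL
  attr(out, "is_fully_connected") <- comp$no == 1
  out
}

#' Read a node-by-time matrix from delimited text
#'
#' Auto-detects the delimiter (tab or comma), an optional header line and an
#' optional leading node-id column (first field non-numeric).
#'
#' @param path file path.
#' @param subject_id subject label (defaults to the file stem).
#' @return a [ts_matrix()].
#' @export
read_ts_matrix <- function(path,
                           subject_id = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  num1 <- suppressWarnings(as.numeric(fields))
  # header iff more than one non-numeric field on line 1 (a lone leading
  # non-numeric field is a node-id column, not a header)
  header <- sum(is.na(num1)) > 1
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  node_ids <- NULL
  if (!is.numeric(df[[1]])) {
    node_ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stopf("non-numeric values in %s", path)
  ts_matrix(m, node_ids = node_ids %||% seq_len(nrow(m)),
            subject_id = subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a time-series matrix as TSV
#'
#' @param ts a [ts_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ts_matrix <- function(ts, path) {
  stopifnot(inherits(ts, "ts_matrix"))
  utils::write.table(ts$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a graph as an edge-list TSV plus a JSON sidecar
#'
#' The sidecar records `N`, `M`, `density`, `threshold_used` and whether the
#' graph is fully connected.
#'
#' @param graph a `binary_graph`.
#' @param path edge-list path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "binary_graph"))
  utils::write.table(data.frame(node_i = graph$edges[, 1],
                                node_j = graph$edges[, 2]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(N = graph$N, M = graph$M, density = graph$density,
               threshold_used = graph$threshold_used,
               connected =
                 isTRUE(attr(connected_components(graph),
                             "is_fully_connected")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
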