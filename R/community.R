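#' Construct a partition object
#'
#' @param labels per-node module labels (any integer coding).
#' @param provenance optional list (density, gamma, seed, ...) recorded with
#'   the partition.
#' @return a `partition` with canonicalized labels: module ids renumbered
#'   1..K in order of first appearance, so label-permuted inputs collapse to
#'   the same object.
#' @export
partition <- function(labels, provenance = list()) {
  if (anyNA(labels)) stopf("every node must be labeled")
  labels <- as.integer(factor(labels, levels = unique(labels)))
  structure(list(labels = labels, n_modules = max(labels),
                 provenance = provenance),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d modules\n",
              length(x$labels), x$n_modules))
  invisible(x)
}

#' Louvain community detection with a resolution parameter
#'
#' Greedy multi-level modularity optimization of Q(gamma) (local node moves
#' followed by graph aggregation, iterated to convergence), with the sweep
#' order randomized by `seed`. Larger `gamma` yields more, smaller modules.
#'
#' @param graph a `binary_graph` with at least one edge.
#' @param gamma structural resolution (default 1).
#' @param seed integer seed.
#' @param keep_levels if TRUE, attach the per-level membership matrix as
#'   attribute `levels` (useful for auditing that Q never decreases across
#'   aggregation levels).
#' @return a [partition()] with provenance `(gamma, seed)`.
#' @export
louvain_partition <- function(graph, gamma = 1, seed = 1,
                              keep_levels = FALSE) {
  stopifnot(inherits(graph, "binary_graph"))
  if (graph$M < 1) stopf("community detection needs at least one edge")
  cl <- with_seed_(seed,
                   igraph::cluster_louvain(to_igraph(graph),
                                           resolution = gamma))
  p <- partition(igraph::membership(cl),
                 provenance = list(gamma = gamma, seed = seed))
  if (keep_levels) attr(p, "levels") <- cl$memberships
  p
}

#' Consensus partition over repeated Louvain runs
#'
#' Runs [louvain_partition()] `n_reps` times with derived seeds, forms the
#' co-assignment matrix (fraction of repetitions in which each node pair
#' shares a module), keeps pairs whose co-assignment exceeds `threshold`,
#' and takes the connected components of the kept-pair graph as the final
#' modules (singletons allowed). Defaults: 100 repetitions, threshold 0.9.
#'
#' @param graph a `binary_graph`.
#' @param gamma structural resolution.
#' @param n_reps number of Louvain repetitions.
#' @param threshold co-assignment frequency in `(0, 1]` a pair must exceed.
#' @param seed integer seed.
#' @return list of class `consensus_result`: `partition`, `coassignment`
#'   (N x N, unit diagonal), `n_reps`, `threshold`.
#' @export
consensus_partition <- function(graph, gamma = 1, n_reps = 100,
                                threshold = 0.9, seed = 1) {
  stopifnot(inherits(graph, "binary_graph"))
  if (!is_count(n_reps) || n_reps < 1) stopf("n_reps must be >= 1")
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  N <- graph$N
  co <- matrix(0, N, N)
  for (k in seq_len(n_reps)) {
    lab <- louvain_partition(graph, gamma = gamma,
                             seed = derive_seed(seed, 401, k))$labels
    co <- co + outer(lab, lab, "==")
  }
  co <- co / n_reps
  diag(co) <- 1
  keep <- co > threshold
  diag(keep) <- TRUE
  memb <- igraph::components(
    igraph::graph_from_adjacency_matrix(keep, mode = "undirected",
                                        diag = FALSE))$membership
  structure(list(partition = partition(memb,
                                       provenance = list(gamma = gamma,
                                                         seed = seed,
                                                         mode = "consensus")),
                 coassignment = co, n_reps = n_reps, threshold = threshold),
            class = "consensus_result")
}

#' Normalized mutual information between two partitions
#'
#' `NMI = 2 I(P1; P2) / (H(P1) + H(P2))` from the label co-occurrence
#' confusion matrix; 1 means identical community structure, 0 independent.
#' Entropy-zero edge cases: two single-module partitions are identical
#' (NMI 1); a single-module vs a multi-module partition gives 0.
#'
#' @param p1,p2 [partition()] objects or label vectors over the same nodes.
#' @return scalar in `[0, 1]`.
#' @export
nmi <- function(p1, p2) {
  l1 <- if (inherits(p1, "partition")) p1$labels else as.integer(p1)
  l2 <- if (inherits(p2, "partition")) p2$labels else as.integer(p2)
  if (length(l1) != length(l2)) {
    stopf("partitions cover different node sets (%d vs %d nodes)",
          length(l1), length(l2))
  }
  n <- length(l1)
  tab <- table(l1, l2) / n
  px <- rowSums(tab)
  py <- colSums(tab)
  h1 <- -sum(px * log(px))
  h2 <- -sum(py * log(py))
  if (h1 == 0 && h2 == 0) return(1)
  if (h1 == 0 || h2 == 0) return(0)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
  2 * mi / (h1 + h2)
}

#' Consensus partitions over a (density, gamma) grid with peak selection
#'
#' Computes a consensus partition for every cell of the two-parameter grid,
#' scores each cell by the mean NMI of its partition with its 4-neighbors
#' (up/down in density, left/right in gamma), and selects the cell with the
#' highest neighborhood similarity — a peak of partition stability in
#' parameter space. Ties go to the lowest density, then the lowest gamma.
#' The grid defaults mirror the standard operating sweep: densities 10-50%
#' in steps of 10%, gamma 1-2 in steps of 0.25.
#'
#' @param corr correlation matrix.
#' @param densities ascending link densities.
#' @param gammas resolution values.
#' @param n_reps,threshold consensus parameters per cell.
#' @param seed integer seed.
#' @return list: `grid` (density x gamma list-matrix of `consensus_result`),
#'   `score` (neighborhood-NMI matrix), `selected` (list with `density`,
#'   `gamma`, `result`).
#' @export
parameter_sweep <- function(corr, densities = seq(0.1, 0.5, by = 0.1),
                            gammas = seq(1, 2, by = 0.25),
                            n_reps = 100, threshold = 0.9, seed = 1) {
  if (!length(densities) || !length(gammas)) stopf("empty parameter grid")
  nd <- length(densities)
  ng <- length(gammas)
  graphs <- lapply(densities, function(d) threshold_to_density(corr, d))
  grid <- vector("list", nd * ng)
  dim(grid) <- c(nd, ng)
  for (i in seq_len(nd)) {
    for (j in seq_len(ng)) {
      grid[[i, j]] <- consensus_partition(graphs[[i]], gamma = gammas[j],
                                          n_reps = n_reps,
                                          threshold = threshold,
                                          seed = derive_seed(seed, 601, i, j))
    }
  }
  score <- matrix(NA_real_, nd, ng)
  for (i in seq_len(nd)) {
    for (j in seq_len(ng)) {
      nb <- list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
      vals <- vapply(Filter(function(x) x[1] >= 1 && x[1] <= nd &&
                              x[2] >= 1 && x[2] <= ng, nb),
                     function(x) nmi(grid[[i, j]]$partition,
                                     grid[[x[1], x[2]]]$partition), 1)
      score[i, j] <- if (length(vals)) mean(vals) else 1
    }
  }
  best <- which(score == max(score), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(grid = grid, score = score, densities = densities, gammas = gammas,
       selected = list(density = densities[best[1]], gamma = gammas[best[2]],
                       result = grid[[best[1], best[2]]]))
}

# matched baseline label for each subject module (NA = unmatched),
# via maximum-overlap one-to-one assignment on the confusion matrix
match_modules <- function(subject, baseline) {
  ls <- if (inherits(subject, "partition")) subject$labels else
    partition(subject)$labels
  lb <- if (inherits(baseline, "partition")) baseline$labels else
    partition(baseline)$labels
  if (length(ls) != length(lb)) stopf("partitions cover different node sets")
  conf <- unclass(table(factor(ls, 1:max(ls)), factor(lb, 1:max(lb))))
  assignment_max(conf)
}

#' Module-allegiance map of a subject partition against a baseline
#'
#' Subject modules are matched one-to-one to baseline modules by
#' maximum-overlap assignment; a node's allegiance is 1 iff its subject
#' module's matched baseline label equals the node's baseline label, 0
#' otherwise (including nodes in unmatched subject modules). A partition
#' compared with itself — under any relabeling — gives all ones.
#'
#' @param subject,baseline [partition()] objects (or label vectors) over
#'   the same nodes.
#' @return integer 0/1 vector of length N, with attribute `matching` (the
#'   subject-module to baseline-module map).
#' @export
allegiance_map <- function(subject, baseline) {
  ls <- if (inherits(subject, "partition")) subject$labels else
    partition(subject)$labels
  lb <- if (inherits(baseline, "partition")) baseline$labels else
    partition(baseline)$labels
  matching <- match_modules(ls, lb)
  mapped <- matching[ls]
  out <- as.integer(!is.na(mapped) & mapped == lb)
  attr(out, "matching") <- matching
  out
}

#' Group-average allegiance map
#'
#' @param maps non-empty list of equal-length [allegiance_map()] vectors.
#' @return per-node mean allegiance in `[0, 1]`.
#' @export
group_allegiance <- function(maps) {
  if (!length(maps)) stopf("empty list of allegiance maps")
  n <- unique(vapply(maps, length, 1L))
  if (length(n) != 1) stopf("allegiance maps differ in length")
  rowMeans(matrix(unlist(maps), nrow = n))
}

#' ROI allegiance profile over baseline modules
#'
#' For each subject and each baseline module m: the fraction of ROI nodes
#' whose matched subject-module label is m. Rows sum to at most 1 (ROI
#' nodes falling in unmatched subject modules contribute to no column).
#'
#' @param subjects list of subject [partition()]s.
#' @param baseline baseline [partition()].
#' @param roi non-empty integer vector of node indices.
#' @return numeric matrix, subjects x baseline modules.
#' @export
roi_allegiance_profile <- function(subjects, baseline, roi) {
  lb <- if (inherits(baseline, "partition")) baseline$labels else
    partition(baseline)$labels
  if (!length(roi)) stopf("empty ROI")
  roi <- as.integer(roi)
  if (any(roi < 1 | roi > length(lb))) stopf("ROI node index out of range")
  k <- max(lb)
  out <- t(vapply(subjects, function(p) {
    ls <- if (inherits(p, "partition")) p$labels else partition(p)$labels
    mapped <- match_modules(ls, lb)[ls][roi]
    vapply(seq_len(k), function(m) mean(!is.na(mapped) & mapped == m), 1)
  }, numeric(k)))
  colnames(out) <- paste0("module", seq_len(k))
  out
}

#' Write / read a partition as a two-column TSV
#'
#' @param p a [partition()].
#' @param path file path (`node_id`, `module` columns).
#' @return `path` invisibly; `read_partition_tsv()` returns a [partition()].
#' @export
write_partition_tsv <- function(p, path) {
  stopifnot(inherits(p, "partition"))
  utils::write.table(data.frame(node_id = seq_along(p$labels),
                                module = p$labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  partition(df$module[order(df$node_id)])
}
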