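#' Nodal degree profile
#'
#' @param graph a `binary_graph`.
#' @return integer vector of length `N` with attributes `density` and `M`;
#'   sums to `2 * M`.
#' @export
node_degree <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  d <- tabulate(graph$edges, nbins = graph$N)
  attr(d, "density") <- graph$density
  attr(d, "M") <- graph$M
  d
}

#' Local clustering coefficients
#'
#' Watts-Strogatz local clustering: triangles through a node divided by
#' `k * (k - 1) / 2`. Nodes with degree below 2 are assigned 0.
#'
#' @param graph a `binary_graph`.
#' @return list with `per_node` (length-`N` vector in `[0, 1]`) and `mean`.
#' @export
clustering_coefficient <- function(graph) {
  g <- to_igraph(graph)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(per_node = cc, mean = mean(cc))
}

#' Global efficiency of a binary graph
#'
#' Mean over distinct node pairs of the inverse shortest-path length;
#' disconnected pairs contribute 0. Equals 1 for a complete graph.
#'
#' @param graph a `binary_graph`.
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(graph) {
  if (graph$M == 0) return(0)
  igraph::global_efficiency(to_igraph(graph))
}

#' Modularity quality Q(gamma) of a partition
#'
#' `Q(gamma) = (1 / 2M) * sum_ij [A_ij - gamma * k_i k_j / 2M] delta(c_i, c_j)`.
#' `gamma = 1` recovers standard Newman-Girvan modularity; larger `gamma`
#' favors smaller modules.
#'
#' @param graph a `binary_graph` with at least one edge.
#' @param partition a [partition()] or an integer label vector of length `N`.
#' @param gamma structural resolution (default 1).
#' @return scalar quality.
#' @export
modularity_quality <- function(graph, partition, gamma = 1) {
  stopifnot(inherits(graph, "binary_graph"))
  labels <- partition_labels(partition, graph$N)
  M <- graph$M
  if (M == 0) stopf("modularity is undefined for an empty graph")
  deg <- node_degree(graph)
  within <- labels[graph$edges[, 1]] == labels[graph$edges[, 2]]
  k_c <- tapply(deg, labels, sum)
  sum(within) / M - gamma * sum((k_c / (2 * M))^2)
}

# accept a partition object or bare label vector
partition_labels <- function(partition, N) {
  labels <- if (inherits(partition, "partition")) partition$labels else partition
  if (length(labels) != N || anyNA(labels)) {
    stopf("partition must label all %d nodes", N)
  }
  as.integer(labels)
}

#' Random-graph reference metrics
#'
#' Generates `n_real` random graphs matched to the input — Erdos-Renyi
#' G(N, M) (`model = "erdos-renyi"`, the default) or degree-preserving
#' Maslov-Sneppen rewiring (`model = "degree-preserving"`) — and returns
#' their mean clustering and mean global efficiency.
#'
#' @param graph a `binary_graph`.
#' @param model `"erdos-renyi"` or `"degree-preserving"`.
#' @param n_real number of realizations (default 25).
#' @param seed integer seed.
#' @param return_graphs if TRUE, attach the realizations (as `binary_graph`
#'   objects) as attribute `graphs` for auditing.
#' @return list with `clustering`, `efficiency`, `n_real`, `model`.
#' @export
random_reference <- function(graph, model = c("erdos-renyi",
                                              "degree-preserving"),
                             n_real = 25, seed = 1, return_graphs = FALSE) {
  stopifnot(inherits(graph, "binary_graph"))
  model <- match.arg(model)
  if (!is_count(n_real) || n_real < 1) stopf("n_real must be >= 1")
  if (model == "degree-preserving" && graph$M < 2) {
    stopf("degree-preserving rewiring impossible with M < 2")
  }
  cc <- eff <- numeric(n_real)
  kept <- if (return_graphs) vector("list", n_real)
  for (k in seq_len(n_real)) {
    gk <- with_seed_(derive_seed(seed, 7001, k), {
      if (model == "erdos-renyi") {
        igraph::sample_gnm(graph$N, graph$M)
      } else {
        igraph::rewire(to_igraph(graph),
                       igraph::keeping_degseq(niter = 10 * graph$M))
      }
    })
    cc[k] <- mean(igraph::transitivity(gk, type = "local", isolates = "zero"))
    eff[k] <- igraph::global_efficiency(gk)
    if (return_graphs) {
      kept[[k]] <- binary_graph(graph$N, igraph::as_edgelist(gk))
    }
  }
  out <- list(clustering = mean(cc), efficiency = mean(eff),
              n_real = n_real, model = model)
  if (return_graphs) attr(out, "graphs") <- kept
  out
}

#' Small-worldness ratio against a random reference
#'
#' `(C_G / C_rand) / (E_rand / E_G)`: clustering normalized by the random
#' reference, divided by the reference's efficiency advantage. A graph with
#' ratio above 2 is flagged as small-world.
#'
#' @param graph a `binary_graph`.
#' @param n_random realizations for the reference (default 25).
#' @param seed integer seed.
#' @param model null model passed to [random_reference()].
#' @return list with `ratio`, `is_small_world` (`ratio > 2`), and the
#'   reference means.
#' @export
small_worldness <- function(graph, n_random = 25, seed = 1,
                            model = "erdos-renyi") {
  ref <- random_reference(graph, model = model, n_real = n_random,
                          seed = seed)
  if (ref$clustering == 0) stopf("reference clustering is zero (degenerate)")
  if (ref$efficiency == 0) stopf("reference efficiency is zero (degenerate)")
  cg <- clustering_coefficient(graph)$mean
  eg <- global_efficiency(graph)
  ratio <- (cg / ref$clustering) / (ref$efficiency / eg)
  list(ratio = ratio, is_small_world = ratio > 2,
       clustering_random = ref$clustering, efficiency_random = ref$efficiency)
}

#' All global metrics for one graph
#'
#' Convenience wrapper: mean clustering, global efficiency, modularity Q of
#' a single Louvain partition, and small-worldness against the chosen null.
#'
#' @inheritParams small_worldness
#' @param gamma resolution for the modularity partition.
#' @return one-row data.frame.
#' @export
graph_metrics <- function(graph, n_random = 25, seed = 1,
                          model = "erdos-renyi", gamma = 1) {
  part <- louvain_partition(graph, gamma = gamma, seed = derive_seed(seed, 3))
  sw <- small_worldness(graph, n_random = n_random, seed = seed, model = model)
  data.frame(
    N = graph$N, M = graph$M, density = graph$density,
    mean_clustering = clustering_coefficient(graph)$mean,
    global_efficiency = global_efficiency(graph),
    modularity_Q = modularity_quality(graph, part, gamma = gamma),
    small_worldness = sw$ratio,
    is_small_world = sw$is_small_world,
    n_random = n_random, random_model = model
  )
}
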