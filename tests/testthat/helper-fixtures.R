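# Shared fixtures: all synthetic, built in code at test time.

# small unequal-module spec: gives degree heterogeneity at 10% density
small_spec <- function(n_timepoints = 200, subject_noise_sd = 0.02) {
  modular_cov_spec(n_nodes = 40, module_sizes = c(12, 10, 8, 6, 4),
                   r_within = 0.6, r_between = 0.1,
                   n_timepoints = n_timepoints,
                   subject_noise_sd = subject_noise_sd)
}

# random Erdos-Renyi binary_graph through the package's own constructor
random_graph <- function(N, M, seed) {
  pairs <- t(utils::combn(N, 2))
  idx <- withr::with_seed(seed, sample.int(nrow(pairs), M))
  binary_graph(N, pairs[idx, , drop = FALSE])
}

# symmetric matrix of random "correlations" with unit diagonal
random_corr <- function(N, seed) {
  withr::with_seed(seed, {
    r <- matrix(stats::runif(N * N, -1, 1), N)
    r[lower.tri(r)] <- t(r)[lower.tri(r)]
    diag(r) <- 1
    r
  })
}

# two disjoint cliques of size k each, as a binary_graph
two_cliques <- function(k = 5) {
  e1 <- t(utils::combn(k, 2))
  e2 <- t(utils::combn(k, 2)) + k
  binary_graph(2 * k, rbind(e1, e2))
}

# planted-partition SBM via igraph, returned with its planted labels
sbm_graph <- function(block_sizes, p_in, p_out, seed) {
  k <- length(block_sizes)
  pm <- matrix(p_out, k, k)
  diag(pm) <- p_in
  g <- withr::with_seed(seed,
    igraph::sample_sbm(sum(block_sizes), pref.matrix = pm,
                       block.sizes = block_sizes))
  el <- igraph::as_edgelist(g)
  list(graph = binary_graph(sum(block_sizes), el),
       labels = rep(seq_len(k), block_sizes))
}

# degree profiles for a cohort of modular subjects at one density
cohort_degrees <- function(spec, n_subjects, density, seed) {
  lapply(gen_cohort(spec, n_subjects, seed), function(s) {
    node_degree(threshold_to_density(correlation_matrix(s), density))
  })
}
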