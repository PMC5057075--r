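#' Specification of a block-modular correlation structure
#'
#' Defines the latent correlation matrix a synthetic cohort is drawn from:
#' nodes are partitioned into modules, with correlation `r_within` inside a
#' module and `r_between` across modules. Per-subject heterogeneity is
#' modeled as symmetric jitter on this latent matrix (projected back to the
#' nearest valid correlation matrix), not as changes in module membership.
#'
#' @param n_nodes total node count.
#' @param module_sizes positive integers summing to `n_nodes`. Unequal sizes
#'   give the degree heterogeneity that hub-disruption analyses need.
#' @param r_within within-module correlation in `(0, 1)`.
#' @param r_between between-module correlation in `[0, r_within)`.
#' @param n_timepoints series length per node.
#' @param subject_noise_sd sd of the per-subject jitter added to latent
#'   correlations (0 = identical structure for every subject).
#' @return a `modular_cov_spec`; construction fails if the implied block
#'   matrix is not positive semi-definite.
#' @export
modular_cov_spec <- function(n_nodes, module_sizes, r_within, r_between,
                             n_timepoints, subject_noise_sd = 0) {
  if (!is_count(n_nodes) || n_nodes < 2) stopf("n_nodes must be >= 2")
  if (any(module_sizes < 1) || sum(module_sizes) != n_nodes) {
    stopf("module_sizes must be positive and sum to n_nodes (%d), got %d",
          n_nodes, sum(module_sizes))
  }
  if (!(r_within > 0 && r_within < 1)) stopf("r_within must be in (0, 1)")
  if (!(r_between >= 0 && r_between < r_within)) {
    stopf("r_between must be in [0, r_within)")
  }
  if (!is_count(n_timepoints) || n_timepoints < 3) {
    stopf("n_timepoints must be >= 3")
  }
  if (subject_noise_sd < 0) stopf("subject_noise_sd must be >= 0")
  spec <- structure(list(n_nodes = as.integer(n_nodes),
                         module_sizes = as.integer(module_sizes),
                         r_within = r_within, r_between = r_between,
                         n_timepoints = as.integer(n_timepoints),
                         subject_noise_sd = subject_noise_sd),
                    class = "modular_cov_spec")
  sigma <- block_correlation(spec)
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    stopf(paste0("block correlation matrix is not positive semi-definite ",
                 "(min eigenvalue %.3g) for r_within = %g, r_between = %g, ",
                 "module_sizes = %s"), ev, r_within, r_between,
          paste(module_sizes, collapse = ","))
  }
  spec
}

#' Latent block correlation matrix of a spec
#'
#' @param spec a [modular_cov_spec()].
#' @return the `n_nodes x n_nodes` correlation matrix.
#' @export
block_correlation <- function(spec) {
  stopifnot(inherits(spec, "modular_cov_spec"))
  mod <- rep(seq_along(spec$module_sizes), spec$module_sizes)
  same <- outer(mod, mod, "==")
  sigma <- ifelse(same, spec$r_within, spec$r_between)
  diag(sigma) <- 1
  sigma
}

#' Module membership implied by a spec
#'
#' @param spec a [modular_cov_spec()].
#' @return integer label vector of length `n_nodes`.
#' @export
planted_modules <- function(spec) {
  stopifnot(inherits(spec, "modular_cov_spec"))
  rep(seq_along(spec$module_sizes), spec$module_sizes)
}

# project a symmetric matrix to the nearest PSD correlation matrix
# (eigenvalue clipping, then rescale to unit diagonal)
nearest_psd_corr <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 1e-8)
  m2 <- e$vectors %*% (vals * t(e$vectors))
  stats::cov2cor(m2)
}

zscore_rows <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  s[s == 0] <- 1
  (x - mu) / s
}

#' Draw one subject's modular time series
#'
#' Samples a zero-mean multivariate Gaussian whose correlation matrix is the
#' spec's block matrix, optionally jittered per subject by
#' `subject_noise_sd` (with nearest-PSD projection). Rows are z-scored.
#'
#' @param spec a [modular_cov_spec()].
#' @param seed integer seed; equal seeds give bit-identical output.
#' @param subject_id label for the returned matrix.
#' @return a [ts_matrix()], `n_nodes x n_timepoints`.
#' @export
gen_modular_timeseries <- function(spec, seed, subject_id = "sim") {
  stopifnot(inherits(spec, "modular_cov_spec"))
  sigma <- block_correlation(spec)
  x <- with_seed_(seed, {
    if (spec$subject_noise_sd > 0) {
      jit <- matrix(stats::rnorm(spec$n_nodes^2, sd = spec$subject_noise_sd),
                    spec$n_nodes)
      jit <- (jit + t(jit)) / 2
      diag(jit) <- 0
      sigma <- nearest_psd_corr(sigma + jit)
    }
    L <- chol(sigma + diag(1e-10, spec$n_nodes))
    z <- matrix(stats::rnorm(spec$n_nodes * spec$n_timepoints),
                nrow = spec$n_timepoints)
    t(z %*% L)
  })
  ts_matrix(zscore_rows(x), subject_id = subject_id)
}

#' Draw a cohort of modular time series
#'
#' `n_subjects` independent draws via [gen_modular_timeseries()], each with
#' a sub-seed derived from `seed` and the subject index.
#'
#' @param spec a [modular_cov_spec()].
#' @param n_subjects cohort size (>= 1).
#' @param seed integer seed.
#' @param prefix subject-id prefix.
#' @return list of [ts_matrix()] named by subject id.
#' @export
gen_cohort <- function(spec, n_subjects, seed, prefix = "sub") {
  if (!is_count(n_subjects) || n_subjects < 1) stopf("n_subjects must be >= 1")
  out <- lapply(seq_len(n_subjects), function(i) {
    gen_modular_timeseries(spec, seed = derive_seed(seed, 101, i),
                           subject_id = sprintf("%s%03d", prefix, i))
  })
  names(out) <- vapply(out, function(x) x$subject_id, "")
  out
}

#' Plant a degree rank-order disruption in a degree profile
#'
#' Degree-mix construction: `d' = (1 - lam) * d + lam * pi(d)` where `pi` is
#' a uniformly random permutation of `d`. Because the permuted vector is
#' uncorrelated with `d` in expectation, the regression of `d' - d` on `d`
#' has expected slope `-lam` — i.e. `lam` is the planted k_D magnitude.
#'
#' @param degrees nonnegative numeric vector (a degree profile, possibly a
#'   cohort mean).
#' @param lam disruption magnitude in `[0, 1]`; 0 leaves the input
#'   untouched, 1 fully randomizes the rank order.
#' @param seed integer seed for the permutation.
#' @return disrupted profile, same length and mean as the input.
#' @export
plant_disruption <- function(degrees, lam, seed) {
  if (!is.numeric(degrees) || any(degrees < 0)) {
    stopf("degrees must be nonnegative")
  }
  if (!is.numeric(lam) || length(lam) != 1 || lam < 0 || lam > 1) {
    stopf("lam must be a single value in [0, 1]")
  }
  if (lam == 0) return(degrees)
  perm <- with_seed_(seed, sample.int(length(degrees)))
  (1 - lam) * degrees + lam * degrees[perm]
}

#' Plant disruption by preferential edge rewiring
#'
#' Edge-level analog of [plant_disruption()] for end-to-end pipeline tests:
#' a fraction `lam` of edges is detached, sampled with probability
#' proportional to the summed endpoint degrees (so hubs preferentially lose
#' edges), and the same number of edges is reattached uniformly at random
#' among current non-edges. `N` and `M` are conserved and the graph stays
#' simple. The resulting k_D against the original graph decreases with
#' `lam`.
#'
#' @param graph a `binary_graph` with at least one edge.
#' @param lam fraction of edges to rewire, in `[0, 1]`.
#' @param seed integer seed.
#' @return a `binary_graph` with identical `N` and `M`.
#' @export
rewire_disruption <- function(graph, lam, seed) {
  stopifnot(inherits(graph, "binary_graph"))
  if (graph$M == 0) stopf("cannot rewire a graph with no edges")
  if (!is.numeric(lam) || length(lam) != 1 || lam < 0 || lam > 1) {
    stopf("lam must be a single value in [0, 1]")
  }
  n_rw <- round(lam * graph$M)
  if (n_rw == 0) return(graph)
  N <- graph$N
  with_seed_(seed, {
    deg <- node_degree(graph)
    w <- deg[graph$edges[, 1]] + deg[graph$edges[, 2]]
    drop_idx <- sample.int(graph$M, n_rw, prob = w)
    kept <- graph$edges[-drop_idx, , drop = FALSE]
    key <- function(e) (pmin(e[, 1], e[, 2]) - 1) * N + pmax(e[, 1], e[, 2])
    occupied <- new.env(hash = TRUE, size = graph$M * 2L)
    for (k in key(kept)) assign(as.character(k), TRUE, envir = occupied)
    added <- matrix(0L, n_rw, 2)
    n_added <- 0
    while (n_added < n_rw) {
      i <- sample.int(N, 1)
      j <- sample.int(N, 1)
      if (i == j) next
      k <- as.character((min(i, j) - 1) * N + max(i, j))
      if (!is.null(occupied[[k]])) next
      assign(k, TRUE, envir = occupied)
      n_added <- n_added + 1
      added[n_added, ] <- c(i, j)
    }
    new_binary_graph(N, rbind(kept, added), density = graph$density,
                     threshold_used = NA_real_)
  })
}

#' Mix white Gaussian noise into a subject's time series
#'
#' Each node's series is replaced by the convex combination
#' `(1 - p) * z(signal) + p * z(noise)` of the z-scored signal and an
#' independent unit-variance white Gaussian series, then re-z-scored so
#' correlation magnitudes stay comparable across noise levels. `p = 0`
#' returns the z-scored input; `p = 1` destroys all inter-node correlation.
#'
#' @param ts a [ts_matrix()].
#' @param p noise proportion in `[0, 1]`.
#' @param seed integer seed for the noise draw.
#' @return a [ts_matrix()] of identical shape.
#' @export
add_white_noise <- function(ts, p, seed) {
  stopifnot(inherits(ts, "ts_matrix"))
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
    stopf("p must be a single value in [0, 1]")
  }
  x <- zscore_rows(ts$values)
  if (p > 0) {
    wgn <- with_seed_(seed, matrix(stats::rnorm(length(x)), nrow = nrow(x)))
    x <- zscore_rows((1 - p) * x + p * zscore_rows(wgn))
  }
  ts_matrix(x, node_ids = ts$node_ids, subject_id = ts$subject_id)
}
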