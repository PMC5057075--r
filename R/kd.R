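#' Reference degree map of a control cohort
#'
#' Element-wise mean nodal degree across the subjects of a designated
#' reference cohort (e.g. off-site controls), all at one common link
#' density. Every disruption index is measured against such a map.
#'
#' @param cohort_degrees list of degree profiles (from [node_degree()]), all
#'   of the same length and density.
#' @param cohort_id label stored with the map.
#' @return numeric vector of per-node mean degrees with attributes
#'   `density`, `cohort_size`, `cohort_id`; class `reference_degree_map`.
#' @export
reference_degree_map <- function(cohort_degrees, cohort_id = "reference") {
  if (!length(cohort_degrees)) stopf("empty cohort")
  n <- unique(vapply(cohort_degrees, length, 1L))
  if (length(n) != 1) {
    stopf("degree profiles differ in length: %s", paste(n, collapse = ", "))
  }
  dens <- unique(vapply(cohort_degrees,
                        function(d) attr(d, "density") %||% NA_real_, 1))
  if (length(dens) != 1) {
    stopf("degree profiles come from mixed densities: %s",
          paste(signif(dens, 3), collapse = ", "))
  }
  m <- rowMeans(matrix(unlist(cohort_degrees), nrow = n))
  structure(m, density = dens, cohort_size = length(cohort_degrees),
            cohort_id = cohort_id, class = "reference_degree_map")
}

# strip class/attrs for arithmetic
ref_values <- function(reference) as.numeric(reference)

kd_fit <- function(x, y, density = NA_real_) {
  n <- length(x)
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) {
    stopf("reference degrees are constant; the disruption slope is undefined")
  }
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  vy <- stats::var(y)
  r <- if (vy == 0) 0 else stats::cor(x, y)
  structure(list(kd = slope, b = intercept, r_fit = r,
                 n_nodes_used = n, density = density),
            class = "kd_result")
}

#' @export
print.kd_result <- function(x, ...) {
  cat(sprintf("<kd_result> kd = %.4f, b = %.4f, r_fit = %.3f (n = %d nodes)\n",
              x$kd, x$b, x$r_fit, x$n_nodes_used))
  invisible(x)
}

#' Degree rank-order disruption index k_D
#'
#' Ordinary least squares of `y = d_subject - d_reference` on
#' `x = d_reference` over all nodes. The slope k_D is 0 when the subject
#' preserves the reference degree rank order, and negative when hubs lose
#' and peripheral nodes gain connections (full randomization approaches
#' -1). All nodes enter the regression, unweighted.
#'
#' @param subject a degree profile ([node_degree()]) or numeric vector.
#' @param reference a [reference_degree_map()] (or numeric vector) of the
#'   same length and density.
#' @return a `kd_result`: `kd` (slope), `b` (intercept), `r_fit` (Pearson
#'   correlation of the fit), `n_nodes_used`, `density`.
#' @export
kd_index <- function(subject, reference) {
  check_kd_pair(subject, reference)
  x <- ref_values(reference)
  y <- as.numeric(subject) - x
  kd_fit(x, y, density = attr(reference, "density") %||% NA_real_)
}

check_kd_pair <- function(subject, reference) {
  if (length(subject) != length(reference)) {
    stopf("subject (%d nodes) and reference (%d nodes) differ",
          length(subject), length(reference))
  }
  ds <- attr(subject, "density")
  dr <- attr(reference, "density")
  if (!is.null(ds) && !is.null(dr) && !is.na(ds) && !is.na(dr) &&
      abs(ds - dr) > 1e-12) {
    stopf("subject density (%g) does not match reference density (%g)",
          ds, dr)
  }
  invisible(TRUE)
}

#' Group-level k_D
#'
#' k_D of a cohort's mean degree profile against the reference map (the
#' group scatter of mean degree differences, not the mean of per-subject
#' slopes; use `vapply(cohort, kd_index, ...)` for the latter).
#'
#' @param cohort non-empty list of degree profiles.
#' @param reference a [reference_degree_map()].
#' @return a `kd_result`.
#' @export
group_kd <- function(cohort, reference) {
  if (!length(cohort)) stopf("empty cohort")
  n <- length(reference)
  if (any(vapply(cohort, length, 1L) != n)) {
    stopf("cohort degree profiles do not match the reference length")
  }
  mean_profile <- rowMeans(matrix(unlist(cohort), nrow = n))
  attr(mean_profile, "density") <- attr(cohort[[1]], "density")
  kd_index(mean_profile, reference)
}

#' k_D after node deletion (k_D')
#'
#' Re-fits the disruption regression with a designated node set removed.
#' Degrees are NOT recomputed on a pruned graph — nodes are simply dropped
#' from the regression — so k_D' isolates whether the index is driven by
#' those nodes.
#'
#' @param subject degree profile.
#' @param reference a [reference_degree_map()].
#' @param deleted_nodes integer node indices to drop (may be empty).
#' @return a `kd_result` with `n_nodes_used` reflecting the survivors.
#' @export
kd_after_deletion <- function(subject, reference, deleted_nodes = integer()) {
  check_kd_pair(subject, reference)
  n <- length(subject)
  deleted_nodes <- unique(as.integer(deleted_nodes))
  if (any(deleted_nodes < 1 | deleted_nodes > n)) {
    stopf("deleted node index out of range 1..%d", n)
  }
  keep <- setdiff(seq_len(n), deleted_nodes)
  if (length(keep) < 2) stopf("fewer than 2 nodes left after deletion")
  x <- ref_values(reference)[keep]
  y <- as.numeric(subject)[keep] - x
  kd_fit(x, y, density = attr(reference, "density") %||% NA_real_)
}

#' k_D from random node subsets (k_D'')
#'
#' Recomputes k_D on `n_perm` independent uniform random subsets containing
#' a `fraction` of the nodes. If the disruption is global, the subset
#' estimates track the full-network k_D; conventional settings are 10%
#' or 1% subsets over 5000 permutations.
#'
#' @param subject degree profile.
#' @param reference a [reference_degree_map()].
#' @param fraction subset fraction; `fraction * N` must be at least 3.
#' @param n_perm number of random subsets.
#' @param seed integer seed.
#' @return list with `kd` (vector of length `n_perm`), `median`, `iqr`,
#'   `fraction`, `subset_size`.
#' @export
kd_random_subset <- function(subject, reference, fraction = 0.1,
                             n_perm = 5000, seed = 1) {
  check_kd_pair(subject, reference)
  n <- length(subject)
  size <- round(fraction * n)
  if (size < 3) {
    stopf("subset of %d nodes (fraction %g of %d) is too small", size,
          fraction, n)
  }
  if (!is_count(n_perm) || n_perm < 1) stopf("n_perm must be >= 1")
  x_all <- ref_values(reference)
  y_all <- as.numeric(subject) - x_all
  kds <- with_seed_(seed, vapply(seq_len(n_perm), function(k) {
    idx <- if (size == n) seq_len(n) else sample.int(n, size)
    kd_fit(x_all[idx], y_all[idx])$kd
  }, 1))
  list(kd = kds, median = stats::median(kds),
       iqr = stats::IQR(kds), fraction = fraction, subset_size = size)
}

#' k_D as a function of injected noise level
#'
#' For each noise proportion `p` the subject's series is mixed with white
#' Gaussian noise ([add_white_noise()]), the graph is rebuilt at the given
#' density, and k_D against the (noise-free) reference is recomputed. Level
#' 0 is prepended as the baseline.
#'
#' @param ts a [ts_matrix()].
#' @param reference a [reference_degree_map()] at `density`.
#' @param density link density for graph construction.
#' @param levels noise proportions in `[0, 1]` (default the 20%-step ladder
#'   0.2, 0.4, 0.6, 0.8, 1).
#' @param seed integer seed.
#' @return data.frame with columns `level`, `kd`, `b`, `r_fit`.
#' @export
kd_noise_curve <- function(ts, reference, density,
                           levels = seq(0.2, 1, by = 0.2), seed = 1) {
  if (any(levels < 0 | levels > 1)) stopf("noise levels must be in [0, 1]")
  levels <- c(0, levels[levels > 0])
  rows <- lapply(seq_along(levels), function(i) {
    p <- levels[i]
    noisy <- add_white_noise(ts, p, seed = derive_seed(seed, 211, i))
    g <- threshold_to_density(correlation_matrix(noisy), density)
    res <- kd_index(node_degree(g), reference)
    data.frame(level = p, kd = res$kd, b = res$b, r_fit = res$r_fit)
  })
  do.call(rbind, rows)
}
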