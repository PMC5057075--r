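#' kdconn: degree rank-order disruption and consensus modularity
#'
#' Tools for correlation-network analysis of node-by-time recordings:
#' fixed-density graph construction, graph metrics against random-graph
#' nulls, the degree rank-order disruption index k_D and its variants,
#' consensus community detection with module-allegiance maps, a cohort
#' pipeline, and a synthetic-cohort generator with planted disruption.
#'
#' @keywords internal
"_PACKAGE"

MODULUS <- 2147483647

#' Derive a reproducible sub-seed
#'
#' All randomness in the package flows from a single top-level seed; nested
#' operations (per subject, per repetition, per noise level) draw sub-seeds
#' through this deterministic mixing function so partial reruns reproduce.
#'
#' @param seed integer top-level seed.
#' @param ... integer stream identifiers (e.g. subject index, repetition).
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(...)
  x <- as.double(abs(as.integer(seed)) %% MODULUS)
  # 48271 is the MINSTD multiplier; all arithmetic stays below 2^53
  for (i in ids) x <- (x * 48271 + as.double(i) + 1) %% MODULUS
  as.integer(x)
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == round(x)

#' Solve the linear assignment problem (maximum total overlap)
#'
#' Hungarian algorithm on a rectangular score matrix: picks a one-to-one
#' assignment of rows to columns maximizing the summed score. Used to match
#' module labels between independently labeled partitions.
#'
#' @param score numeric matrix (rows = source labels, cols = target labels).
#' @return integer vector of length `nrow(score)`; entry i is the column
#'   assigned to row i, or `NA` if the row is unmatched (more rows than
#'   columns).
#' @export
assignment_max <- function(score) {
  if (!is.matrix(score) || !is.numeric(score)) {
    stopf("assignment_max() needs a numeric matrix")
  }
  nr <- nrow(score)
  nc <- ncol(score)
  transposed <- nr > nc
  cost <- -score # minimize cost == maximize score
  if (transposed) cost <- t(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  # Hungarian algorithm with potentials; rows 1..n assigned to columns 1..m
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1) # p[j+1] = row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j + 1] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign_row <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign_row[p[j + 1]] <- j
  if (transposed) {
    out <- rep(NA_integer_, nr)
    for (i in seq_len(n)) if (!is.na(assign_row[i])) out[assign_row[i]] <- i
    out
  } else {
    assign_row
  }
}
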