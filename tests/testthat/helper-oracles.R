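# Brute-force graph-metric oracles, independent of the implementations
# they check (exhaustive triangle counts, Floyd-Warshall, direct double sum).

adjacency_of <- function(g) {
  A <- matrix(0L, g$N, g$N)
  A[g$edges] <- 1L
  A[g$edges[, 2:1, drop = FALSE]] <- 1L
  A
}

brute_clustering <- function(g) {
  A <- adjacency_of(g)
  n <- g$N
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in nb) for (b in nb) if (a < b && A[a, b] == 1) links <- links + 1
    cc[v] <- links / (k * (k - 1) / 2)
  }
  cc
}

brute_efficiency <- function(g) {
  A <- adjacency_of(g)
  n <- g$N
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) { # Floyd-Warshall
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

brute_modularity <- function(g, labels, gamma) {
  A <- adjacency_of(g)
  k <- rowSums(A)
  m2 <- sum(k)
  total <- 0
  for (i in seq_len(g$N)) {
    for (j in seq_len(g$N)) {
      if (labels[i] == labels[j]) {
        total <- total + A[i, j] - gamma * k[i] * k[j] / m2
      }
    }
  }
  total / m2
}

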