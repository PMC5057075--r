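test_that("correlation_matrix matches the definition", {
  x <- withr::with_seed(1, rnorm(100))
  y <- withr::with_seed(2, rnorm(100))
  m <- rbind(x, x + 0, -x, y)
  cm <- correlation_matrix(m)
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], -1)
  expect_equal(diag(cm), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(cm)))

  # 3-node toy against a brute-force covariance / sd computation
  e <- withr::with_seed(3, rnorm(100, sd = 0.3))
  toy <- rbind(x, x + e, y)
  got <- correlation_matrix(toy)
  for (i in 1:3) {
    for (j in 1:3) {
      a <- toy[i, ]
      b <- toy[j, ]
      oracle <- sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
      expect_equal(got[i, j], oracle, tolerance = 1e-12)
    }
  }

  flat <- rbind(x, rep(2, 100), rep(0, 100))
  expect_error(correlation_matrix(flat), "zero-variance node series: 2, 3")
})

test_that("target_edge_count applies the floor rule", {
  expect_identical(target_edge_count(5828, 0.10), 1697987L)
  expect_identical(target_edge_count(10, 1.0), 45L)
  expect_identical(target_edge_count(10, 0.1), 4L)
  expect_error(target_edge_count(5, 0.01), "zero edges")
  expect_error(target_edge_count(10, 0), "density")
})

test_that("thresholding keeps exactly the top-|r| pairs", {
  # 4 nodes, |r| ladder 0.9 > 0.8 > ... > 0.4; M = floor(0.5 * 6) = 3
  r <- diag(4)
  vals <- c(0.9, -0.8, 0.7, 0.6, 0.5, 0.4)
  r[upper.tri(r)] <- vals
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  g <- threshold_to_density(r, 0.5)
  expect_equal(g$M, 3L)
  # upper.tri order for N=4: (1,2) (1,3) (2,3) (1,4) (2,4) (3,4)
  expect_equal(g$edges, rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_equal(g$threshold_used, 0.7)

  # all-equal |r|: the lexicographic tie rule is deterministic
  req <- matrix(0.5, 6, 6)
  diag(req) <- 1
  g1 <- threshold_to_density(req, 0.3)
  g2 <- threshold_to_density(req, 0.3)
  expect_equal(g1$M, 4L)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$edges, rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                                   c(1L, 5L)))
})

test_that("thresholding agrees with an independent sort-and-slice oracle", {
  r <- random_corr(30, seed = 8)
  g <- threshold_to_density(r, 0.2)
  # oracle: data.frame of all pairs, ordered by |r| then pair
  idx <- which(upper.tri(r), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], a = abs(r[idx]))
  df <- df[order(-df$a, df$i, df$j), ]
  M <- floor(0.2 * 30 * 29 / 2)
  oracle <- as.matrix(df[seq_len(M), c("i", "j")])
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), ]
  expect_equal(unname(g$edges), unname(oracle), ignore_attr = TRUE)
})

test_that("thresholding is sign-invariant", {
  ts <- gen_modular_timeseries(small_spec(), seed = 13)
  flipped <- ts$values
  flip <- withr::with_seed(14, sample(nrow(flipped), 15))
  flipped[flip, ] <- -flipped[flip, ]
  g1 <- threshold_to_density(correlation_matrix(ts), 0.15)
  g2 <- threshold_to_density(correlation_matrix(flipped), 0.15)
  expect_identical(g1$edges, g2$edges)
})

test_that("density sweeps are nested with increasing edge counts", {
  edge_key <- function(g) paste(g$edges[, 1], g$edges[, 2])
  r <- correlation_matrix(gen_modular_timeseries(small_spec(), seed = 3))
  gs <- density_sweep(r, seq(0.1, 0.5, by = 0.1))
  expect_length(gs, 5)
  ms <- vapply(gs, function(g) g$M, 1L)
  expect_true(all(diff(ms) > 0))
  for (i in 1:4) expect_true(all(edge_key(gs[[i]]) %in% edge_key(gs[[i + 1]])))

  # property check over random instances
  for (seed in 1:100) {
    r <- random_corr(12, seed = seed)
    gs <- density_sweep(r, c(0.15, 0.4))
    expect_true(all(edge_key(gs[[1]]) %in% edge_key(gs[[2]])))
    expect_equal(vapply(gs, function(g) g$M, 1L),
                 c(target_edge_count(12, 0.15), target_edge_count(12, 0.4)))
  }

  expect_error(density_sweep(r, c(0.4, 0.2)), "ascending")
  single <- density_sweep(r, 0.3)
  expect_identical(single[[1]]$edges, threshold_to_density(r, 0.3)$edges)
})

test_that("connected components are reported, not enforced", {
  path <- binary_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  cc <- connected_components(path)
  expect_length(cc, 1)
  expect_true(attr(cc, "is_fully_connected"))

  tri2 <- two_cliques(3)
  cc2 <- connected_components(tri2)
  expect_length(cc2, 2)
  expect_equal(sort(lengths(cc2)), c(3L, 3L))
  expect_false(attr(cc2, "is_fully_connected"))

  # dense E-R graphs are almost surely connected
  n_conn <- sum(vapply(1:100, function(s) {
    length(connected_components(random_graph(100, 800, seed = s))) == 1
  }, TRUE))
  expect_gte(n_conn, 99)
})

test_that("time-series files round-trip with format auto-detection", {
  ts <- gen_modular_timeseries(small_spec(n_timepoints = 20), seed = 21)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ts_matrix(ts, f)
  back <- read_ts_matrix(f)
  expect_equal(back$values, ts$values, tolerance = 1e-12)

  # comma-separated with node-id column and header
  f2 <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(node = paste0("n", 1:5),
                   matrix(round(rnorm(50), 4), 5, 10))
  utils::write.table(df, f2, sep = ",", quote = FALSE, row.names = FALSE)
  back2 <- read_ts_matrix(f2)
  expect_equal(back2$node_ids, paste0("n", 1:5))
  expect_equal(dim(back2$values), c(5L, 10L))
})

test_that("graph export writes an edge list plus JSON sidecar", {
  g <- random_graph(20, 30, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, f)
  el <- utils::read.table(f, header = TRUE)
  expect_equal(nrow(el), 30)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$N, 20)
  expect_equal(meta$M, 30)
})
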