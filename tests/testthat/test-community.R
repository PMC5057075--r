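test_that("partitions canonicalize to first-appearance labeling", {
  p <- partition(c(7, 7, 2, 2, 9))
  expect_equal(p$labels, c(1L, 1L, 2L, 2L, 3L))
  expect_equal(p$n_modules, 3L)
  expect_equal(partition(c(1, 1, 3, 3, 2))$labels, p$labels)
  expect_error(partition(c(1, NA, 2)), "labeled")
})

test_that("louvain recovers unambiguous structure at any seed", {
  g <- two_cliques(5)
  for (seed in 1:5) {
    p <- louvain_partition(g, gamma = 1, seed = seed)
    expect_equal(p$labels, rep(1:2, each = 5))
  }
})

test_that("louvain recovers a strongly assortative planted partition", {
  hits <- vapply(1:10, function(s) {
    sbm <- sbm_graph(rep(25, 4), p_in = 0.5, p_out = 0.02, seed = s)
    nmi(louvain_partition(sbm$graph, seed = s), sbm$labels) >= 0.9
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("higher resolution yields more modules", {
  n1 <- n20 <- numeric(20)
  for (s in 1:20) {
    g <- random_graph(60, 150, seed = s)
    n1[s] <- louvain_partition(g, gamma = 1, seed = s)$n_modules
    n20[s] <- louvain_partition(g, gamma = 20, seed = s)$n_modules
  }
  expect_true(mean(n20) > mean(n1))
  expect_true(all(n20 >= n1))
})

test_that("quality never decreases across aggregation levels", {
  for (s in 1:5) {
    g <- random_graph(50, 120, seed = s)
    for (gamma in c(1, 1.5)) {
      p <- louvain_partition(g, gamma = gamma, seed = s, keep_levels = TRUE)
      lv <- attr(p, "levels")
      qs <- apply(lv, 1, function(lab) modularity_quality(g, lab, gamma))
      if (length(qs) > 1) expect_true(all(diff(qs) >= -1e-12))
      expect_gte(modularity_quality(g, p, gamma),
                 modularity_quality(g, rep(1L, g$N), gamma) - 1e-12)
    }
  }
})

test_that("consensus reduces to the single run and stabilizes the SBM", {
  g <- two_cliques(5)
  cons <- consensus_partition(g, n_reps = 1, seed = 5)
  expect_equal(cons$partition$labels,
               louvain_partition(g, seed = derive_seed(5, 401, 1))$labels)

  # unambiguous optimum: all repetitions identical, coassignment is 0/1
  cons2 <- consensus_partition(g, n_reps = 25, seed = 6)
  expect_true(all(cons2$coassignment %in% c(0, 1)))
  expect_equal(cons2$partition$labels, rep(1:2, each = 5))
  expect_true(isSymmetric(cons2$coassignment))
  expect_equal(diag(cons2$coassignment), rep(1, 10))

  # consensus NMI at least matches the median single-run NMI
  sbm <- sbm_graph(rep(25, 4), p_in = 0.35, p_out = 0.05, seed = 3)
  singles <- vapply(1:20, function(s) {
    nmi(louvain_partition(sbm$graph, seed = derive_seed(30, 401, s)),
        sbm$labels)
  }, 1)
  cons3 <- consensus_partition(sbm$graph, n_reps = 20, seed = 30)
  expect_gte(nmi(cons3$partition, sbm$labels), median(singles) - 1e-12)
})

test_that("nmi obeys its identities and edge cases", {
  expect_equal(nmi(c(1, 1, 2, 2, 3), c(5, 5, 9, 9, 1)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(nmi(rep(1, 6), rep(2, 6)), 1)    # two trivial partitions
  expect_equal(nmi(rep(1, 6), c(1, 1, 1, 2, 2, 2)), 0)
  expect_error(nmi(c(1, 2), c(1, 2, 3)), "different node sets")

  a <- withr::with_seed(1, sample(1:4, 200, replace = TRUE))
  b <- withr::with_seed(2, sample(1:4, 200, replace = TRUE))
  expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)

  # independent random partitions on 1000 nodes are near-orthogonal
  vals <- vapply(1:20, function(s) {
    p1 <- withr::with_seed(s, sample(1:6, 1000, replace = TRUE))
    p2 <- withr::with_seed(s + 500, sample(1:6, 1000, replace = TRUE))
    nmi(p1, p2)
  }, 1)
  expect_lt(mean(vals), 0.05)
})

test_that("nmi matches an independent confusion-matrix computation", {
  for (s in 1:10) {
    p1 <- withr::with_seed(s, sample(1:3, 60, replace = TRUE))
    p2 <- withr::with_seed(s + 99, sample(1:4, 60, replace = TRUE))
    n <- 60
    mi <- 0
    h1 <- 0
    h2 <- 0
    for (a in unique(p1)) {
      pa <- mean(p1 == a)
      h1 <- h1 - pa * log(pa)
      for (b in unique(p2)) {
        pab <- mean(p1 == a & p2 == b)
        if (pab > 0) mi <- mi + pab * log(pab / (pa * mean(p2 == b)))
      }
    }
    for (b in unique(p2)) {
      pb <- mean(p2 == b)
      h2 <- h2 - pb * log(pb)
    }
    expect_equal(nmi(p1, p2), 2 * mi / (h1 + h2), tolerance = 1e-12)
  }
})

test_that("allegiance maps are label-correspondence aware", {
  base <- c(rep(1, 5), rep(2, 5), rep(3, 5))
  relabeled <- c(rep(9, 5), rep(4, 5), rep(7, 5))
  expect_equal(allegiance_map(relabeled, base), rep(1L, 15),
               ignore_attr = TRUE)

  moved <- relabeled
  moved[1] <- 4 # one node defects to another module
  am <- allegiance_map(moved, base)
  expect_equal(sum(am == 0), 1)
  expect_equal(which(am == 0), 1)

  # allegiance of a partition with itself is all ones for any labeling
  for (s in 1:5) {
    lab <- withr::with_seed(s, sample(1:4, 30, replace = TRUE))
    shuf <- c(3, 1, 4, 2)[lab]
    expect_equal(allegiance_map(shuf, lab), rep(1L, 30), ignore_attr = TRUE)
  }
})

test_that("group allegiance averages element-wise into [0, 1]", {
  maps <- list(c(1L, 1L, 0L), c(1L, 0L, 0L))
  expect_equal(group_allegiance(maps), c(1, 0.5, 0))
  expect_equal(group_allegiance(maps[1]), c(1, 1, 0))
  expect_error(group_allegiance(list()), "empty")
  for (s in 1:5) {
    rmaps <- lapply(1:4, function(i) {
      withr::with_seed(s * 10 + i, sample(0:1, 20, replace = TRUE))
    })
    ga <- group_allegiance(rmaps)
    expect_true(all(ga >= 0 & ga <= 1))
  }
})

test_that("roi allegiance profile recovers a planted reassignment rate", {
  base <- rep(1:6, each = 20)
  roi <- 1:20 # all of baseline module 1
  expect_equal(roi_allegiance_profile(list(base), base, roi)[1, ],
               c(module1 = 1, module2 = 0, module3 = 0, module4 = 0,
                 module5 = 0, module6 = 0))

  q <- 0.3 # each ROI node defects from module 1 to module 2 w.p. q
  subs <- lapply(1:50, function(s) {
    lab <- base
    flip <- withr::with_seed(s, runif(20) < q)
    lab[roi][flip] <- 2L
    lab
  })
  prof <- roi_allegiance_profile(subs, base, roi)
  expect_true(all(prof >= 0 & prof <= 1))
  expect_true(all(rowSums(prof) <= 1 + 1e-12))
  expect_lt(abs(mean(prof[, "module2"]) - q), 0.05)
  expect_lt(abs(mean(prof[, "module1"]) - (1 - q)), 0.05)
  expect_error(roi_allegiance_profile(subs, base, integer()), "empty ROI")
})

test_that("parameter sweep selects a stability peak deterministically", {
  spec <- small_spec(n_timepoints = 300, subject_noise_sd = 0)
  cm <- correlation_matrix(gen_modular_timeseries(spec, seed = 31))

  one <- parameter_sweep(cm, densities = 0.2, gammas = 1, n_reps = 10,
                         seed = 1)
  expect_equal(one$selected$density, 0.2)
  expect_equal(one$selected$gamma, 1)

  sw <- parameter_sweep(cm, densities = c(0.1, 0.2), gammas = c(1, 1.5),
                        n_reps = 20, seed = 2)
  expect_equal(dim(sw$score), c(2, 2))
  expect_true(all(sw$score >= 0 & sw$score <= 1))
  # the planted 5-module structure is recovered at the selected cell
  expect_gte(nmi(sw$selected$result$partition, planted_modules(spec)), 0.9)

  # the default grid is the standard 10-50% x 1-2 sweep and contains the
  # default operating point (10% density, gamma 1.5)
  fmls <- formals(parameter_sweep)
  expect_equal(eval(fmls$densities), seq(0.1, 0.5, by = 0.1))
  expect_equal(eval(fmls$gammas), seq(1, 2, by = 0.25))
  cfg <- pipeline_config()
  expect_equal(cfg$kd_density, 0.1)
  expect_equal(cfg$gamma, 1.5)
})

test_that("partitions round-trip through TSV", {
  p <- partition(withr::with_seed(40, sample(1:4, 30, replace = TRUE)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition_tsv(p, f)
  expect_equal(read_partition_tsv(f)$labels, p$labels)
})
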