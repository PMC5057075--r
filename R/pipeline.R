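#' Read a cohort manifest
#'
#' A manifest is a TSV with required columns `subject_id`, `group`, `file`
#' and any number of additional numeric covariate columns (e.g. a pain
#' score). Paths are resolved relative to the manifest's directory. Parsing
#' is strict: duplicate subject ids, missing files and malformed rows are
#' errors naming the offending line.
#'
#' @param path manifest path.
#' @param check_files verify that every referenced matrix file exists.
#' @return data.frame of class `cohort_manifest` with resolved `file` paths.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stopf("no such manifest: %s", path)
  lines <- readLines(path)
  if (!length(lines)) stopf("empty manifest: %s", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("subject_id", "group", "file")
  if (!all(need %in% header)) {
    stopf("manifest header must contain %s; got: %s",
          paste(need, collapse = ", "), lines[1])
  }
  nfield <- length(header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(rows) != nfield)
  if (length(bad)) {
    stopf("manifest line %d has %d fields, expected %d",
          bad[1] + 1, lengths(rows)[bad[1]], nfield)
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  dup <- duplicated(df$subject_id)
  if (any(dup)) {
    stopf("duplicate subject_id '%s' (manifest line %d)",
          df$subject_id[dup][1], which(dup)[1] + 1)
  }
  covs <- setdiff(header, need)
  for (cv in covs) {
    v <- suppressWarnings(as.numeric(df[[cv]]))
    if (anyNA(v) && !all(is.na(v))) {
      stopf("covariate '%s' has non-numeric entries (e.g. manifest line %d)",
            cv, which(is.na(v))[1] + 1)
    }
    df[[cv]] <- v
  }
  df$file <- ifelse(grepl("^/", df$file), df$file,
                    file.path(dirname(path), df$file))
  if (check_files) {
    miss <- !file.exists(df$file)
    if (any(miss)) {
      stopf("matrix file not found for subject '%s': %s",
            df$subject_id[miss][1], df$file[miss][1])
    }
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest
#'
#' @param manifest a data.frame with at least `subject_id`, `group`, `file`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pearson correlation of a score with a covariate
#'
#' Two-sided p-value from the t transform; used for k_D-versus-clinical
#' covariate tables.
#'
#' @param scores,covariate equal-length numeric vectors, n >= 3, both with
#'   nonzero variance.
#' @return list `(R, p, n)`.
#' @export
covariate_correlation <- function(scores, covariate) {
  if (length(scores) != length(covariate)) stopf("length mismatch")
  ok <- is.finite(scores) & is.finite(covariate)
  scores <- scores[ok]
  covariate <- covariate[ok]
  if (length(scores) < 3) stopf("need at least 3 complete pairs")
  if (stats::var(scores) == 0 || stats::var(covariate) == 0) {
    stopf("zero variance in scores or covariate")
  }
  ct <- stats::cor.test(scores, covariate, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(scores))
}

#' Per-node permutation test of group degree differences
#'
#' For each node: difference of group mean degrees (A minus B), a two-sided
#' permutation p-value from `n_perm` random relabelings of subjects, and a
#' Benjamini-Hochberg q-value across nodes. The smallest attainable p is
#' `1 / (n_perm + 1)`.
#'
#' @param cohortA,cohortB lists of degree profiles (same N, each cohort of
#'   at least 2 subjects).
#' @param n_perm number of label permutations (values below 100 trigger a
#'   warning).
#' @param seed integer seed.
#' @return data.frame with columns `node`, `diff`, `p`, `q`.
#' @export
nodal_group_difference <- function(cohortA, cohortB, n_perm = 1000,
                                   seed = 1) {
  if (length(cohortA) < 2 || length(cohortB) < 2) {
    stopf("each cohort needs at least 2 subjects")
  }
  n <- unique(c(vapply(cohortA, length, 1L), vapply(cohortB, length, 1L)))
  if (length(n) != 1) stopf("degree profiles differ in length across cohorts")
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-values")
  A <- matrix(unlist(cohortA), nrow = n)
  B <- matrix(unlist(cohortB), nrow = n)
  X <- cbind(A, B) # nodes x subjects
  na <- ncol(A)
  ns <- ncol(X)
  obs <- rowMeans(A) - rowMeans(B)
  exceed <- integer(n)
  with_seed_(seed, {
    for (k in seq_len(n_perm)) {
      idx <- sample.int(ns, na)
      d <- rowMeans(X[, idx, drop = FALSE]) -
        rowMeans(X[, -idx, drop = FALSE])
      exceed <- exceed + (abs(d) >= abs(obs) - 1e-12)
    }
  })
  p <- (exceed + 1) / (n_perm + 1)
  data.frame(node = seq_len(n), diff = obs, p = p,
             q = stats::p.adjust(p, method = "BH"))
}

#' Default pipeline configuration
#'
#' Operating point used throughout: k_D and community analysis at 10% link
#' density (with a 10-50% metric sweep), consensus Louvain at gamma = 1.5
#' with 100 repetitions thresholded at 0.9, and 25 Erdos-Renyi null graphs
#' for metric normalization.
#'
#' @param densities densities for the metric sweep.
#' @param kd_density density at which k_D and communities are computed.
#' @param gamma structural resolution for Louvain.
#' @param n_reps,consensus_threshold consensus parameters.
#' @param n_random random-reference realizations (0 skips graph metrics).
#' @param n_perm permutations for the nodal group contrast.
#' @param reference_group group label of the reference cohort.
#' @param seed top-level seed; all sub-seeds derive from it.
#' @return named list.
#' @export
pipeline_config <- function(densities = seq(0.1, 0.5, by = 0.1),
                            kd_density = 0.1, gamma = 1.5, n_reps = 100,
                            consensus_threshold = 0.9, n_random = 25,
                            n_perm = 1000, reference_group = "control",
                            seed = 1) {
  list(densities = densities, kd_density = kd_density, gamma = gamma,
       n_reps = n_reps, consensus_threshold = consensus_threshold,
       n_random = n_random, n_perm = n_perm,
       reference_group = reference_group, seed = seed)
}

#' Run the full cohort analysis
#'
#' End-to-end orchestration over a manifest: per-subject graphs at the
#' configured densities; the reference degree map from the reference group;
#' k_D per subject and per group; consensus partitions, NMI against the
#' reference group's consensus baseline, and allegiance maps; optional
#' graph metrics; per-node group contrasts against the reference group; and
#' covariate correlations with k_D for every numeric manifest column.
#' Deterministic given the manifest, config and seed.
#'
#' @param manifest a `cohort_manifest` (from [read_manifest()]) or a list of
#'   [ts_matrix()] plus a `groups` vector via `subjects=`/`groups=`.
#' @param config a [pipeline_config()].
#' @param subjects,groups alternative in-memory input: named list of
#'   [ts_matrix()] and parallel group labels.
#' @param covariates optional data.frame of per-subject numeric covariates
#'   (row order matching `subjects`).
#' @return list of class `cohort_report`: `subjects` (per-subject table),
#'   `groups` (mean +/- sem summaries), `covariates` (correlation table or
#'   NULL), `nodal` (group-contrast tables vs the reference group),
#'   `baseline_partition`, `group_allegiance`, `config`.
#' @export
run_cohort <- function(manifest = NULL, config = pipeline_config(),
                       subjects = NULL, groups = NULL, covariates = NULL) {
  if (!is.null(manifest)) {
    stopifnot(inherits(manifest, "cohort_manifest"))
    subjects <- lapply(seq_len(nrow(manifest)), function(i) {
      read_ts_matrix(manifest$file[i], subject_id = manifest$subject_id[i])
    })
    names(subjects) <- manifest$subject_id
    groups <- manifest$group
    covs <- setdiff(names(manifest), c("subject_id", "group", "file"))
    if (length(covs)) covariates <- manifest[, covs, drop = FALSE]
  }
  if (is.null(subjects) || is.null(groups)) {
    stopf("provide either a manifest or subjects + groups")
  }
  if (length(subjects) != length(groups)) {
    stopf("groups must match subjects in length")
  }
  if (!(config$reference_group %in% groups)) {
    stopf("reference group '%s' has no subjects", config$reference_group)
  }
  ns <- vapply(subjects, function(s) nrow(s$values), 1L)
  if (length(unique(ns)) != 1) {
    bad <- names(subjects)[ns != stats::median(ns)]
    stopf("subjects differ in node count: %s", paste(bad, collapse = ", "))
  }

  ids <- names(subjects) %||% paste0("sub", seq_along(subjects))
  kd_d <- config$kd_density
  corrs <- lapply(subjects, correlation_matrix)
  graphs_kd <- lapply(corrs, threshold_to_density, density = kd_d)
  degrees <- lapply(graphs_kd, node_degree)

  is_ref <- groups == config$reference_group
  refmap <- reference_degree_map(degrees[is_ref],
                                 cohort_id = config$reference_group)

  # consensus baseline: reference group's mean correlation matrix
  ref_corr <- Reduce(`+`, corrs[is_ref]) / sum(is_ref)
  diag(ref_corr) <- 1
  baseline <- consensus_partition(threshold_to_density(ref_corr, kd_d),
                                  gamma = config$gamma,
                                  n_reps = config$n_reps,
                                  threshold = config$consensus_threshold,
                                  seed = derive_seed(config$seed, 11))

  per_subject <- vector("list", length(subjects))
  alleg <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    res <- kd_index(degrees[[i]], refmap)
    cons <- consensus_partition(graphs_kd[[i]], gamma = config$gamma,
                                n_reps = config$n_reps,
                                threshold = config$consensus_threshold,
                                seed = derive_seed(config$seed, 13, i))
    alleg[[i]] <- allegiance_map(cons$partition, baseline$partition)
    row <- data.frame(subject_id = ids[i], group = groups[i],
                      kd = res$kd, b = res$b, r_fit = res$r_fit,
                      n_nodes_used = res$n_nodes_used,
                      nmi = nmi(cons$partition, baseline$partition),
                      mean_allegiance = mean(alleg[[i]]),
                      stringsAsFactors = FALSE)
    if (config$n_random > 0) {
      sweep_g <- density_sweep(corrs[[i]], config$densities)
      for (g in sweep_g) {
        d_lab <- sprintf("d%02.0f", 100 * g$density)
        met <- graph_metrics(g, n_random = config$n_random,
                             seed = derive_seed(config$seed, 17, i),
                             gamma = 1)
        row[[paste0("clustering_", d_lab)]] <- met$mean_clustering
        row[[paste0("efficiency_", d_lab)]] <- met$global_efficiency
        row[[paste0("smallworld_", d_lab)]] <- met$small_worldness
      }
    }
    per_subject[[i]] <- row
  }
  subj_tab <- do.call(rbind, per_subject)

  sem <- function(x) stats::sd(x) / sqrt(length(x))
  groups_tab <- do.call(rbind, lapply(split(subj_tab, subj_tab$group),
    function(d) data.frame(group = d$group[1], n = nrow(d),
                           kd_mean = mean(d$kd), kd_sem = sem(d$kd),
                           nmi_mean = mean(d$nmi), nmi_sem = sem(d$nmi),
                           allegiance_mean = mean(d$mean_allegiance))))
  rownames(groups_tab) <- NULL

  cov_tab <- NULL
  if (!is.null(covariates) && ncol(covariates) > 0) {
    cov_rows <- lapply(names(covariates), function(cv) {
      v <- covariates[[cv]]
      ok <- is.finite(v) & !is_ref # covariates relate to patients
      if (sum(ok) >= 3 && stats::var(subj_tab$kd[ok]) > 0 &&
          stats::var(v[ok]) > 0) {
        cc <- covariate_correlation(subj_tab$kd[ok], v[ok])
        data.frame(covariate = cv, R = cc$R, p = cc$p, n = cc$n)
      }
    })
    cov_tab <- do.call(rbind, cov_rows)
  }

  nodal <- list()
  for (gl in setdiff(unique(groups), config$reference_group)) {
    sel <- groups == gl
    if (sum(sel) >= 2 && sum(is_ref) >= 2) {
      nodal[[gl]] <- nodal_group_difference(degrees[sel], degrees[is_ref],
                                            n_perm = config$n_perm,
                                            seed = derive_seed(config$seed,
                                                               19))
    }
  }

  g_alleg <- lapply(split(alleg, groups), group_allegiance)

  structure(list(subjects = subj_tab, groups = groups_tab,
                 covariates = cov_tab, nodal = nodal,
                 baseline_partition = baseline$partition,
                 group_allegiance = g_alleg, config = config),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects, %d groups (reference '%s')\n",
              nrow(x$subjects), nrow(x$groups), x$config$reference_group))
  print(x$groups)
  invisible(x)
}

#' Write a cohort report to a directory
#'
#' Emits `subjects.tsv`, `groups.tsv`, `covariates.tsv` (if any),
#' `nodal_<group>.tsv` per contrast, `baseline_partition.tsv`,
#' `group_allegiance.tsv` and a `config.json` echo (including the seed) for
#' reproducibility.
#'
#' @param report a `cohort_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.table(d, file.path(out_dir, f),
                                         sep = "\t", quote = FALSE,
                                         row.names = FALSE)
  w(report$subjects, "subjects.tsv")
  w(report$groups, "groups.tsv")
  if (!is.null(report$covariates)) w(report$covariates, "covariates.tsv")
  for (gl in names(report$nodal)) {
    w(report$nodal[[gl]], sprintf("nodal_%s.tsv", gl))
  }
  write_partition_tsv(report$baseline_partition,
                      file.path(out_dir, "baseline_partition.tsv"))
  ga <- data.frame(node = seq_along(report$group_allegiance[[1]]),
                   report$group_allegiance, check.names = FALSE)
  w(ga, "group_allegiance.tsv")
  jsonlite::write_json(report$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
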