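#' Material-wise ratio-of-means statistic
#'
#' For each material, the mean of the metric among dried samples is divided by
#' the mean among frozen samples; the overall statistic is the unweighted
#' arithmetic mean of these per-material ratios. A ratio above 1 means drying
#' increased the metric relative to freezing in that material. Samples with a
#' missing value for the metric are excluded.
#'
#' @param table a [metric_table()].
#' @param metric metric (column) name.
#' @return A list with `per_material` (named vector of per-material ratios),
#'   `overall` (their mean) and `n` (number of samples used).
#' @export
#' @examples
#' d <- sample_design(paste0("s", 1:4), rep("A", 4),
#'                    c("dried", "dried", "frozen", "frozen"))
#' mt <- metric_table(d, matrix(c(2, 4, 1, 3), ncol = 1,
#'                    dimnames = list(d$sample_id, "yield")))
#' ratio_statistic(mt, "yield")
ratio_statistic <- function(table, metric) {
  stopifnot(inherits(table, "metric_table"))
  if (!metric %in% colnames(table$metrics)) {
    stop("unknown metric: ", metric, call. = FALSE)
  }
  values <- table$metrics[, metric]
  design <- table$design
  keep <- !is.na(values)
  values <- values[keep]
  design <- design[keep, , drop = FALSE]
  materials <- sort(unique(design$material))
  rho <- vapply(materials, function(m) {
    idx <- design$material == m
    d_mean <- mean(values[idx & design$treatment == "dried"])
    f_mean <- mean(values[idx & design$treatment == "frozen"])
    if (is.nan(d_mean) || is.nan(f_mean)) {
      stop("material '", m, "' lacks one of the treatments for metric '",
           metric, "'", call. = FALSE)
    }
    if (f_mean == 0) {
      stop("frozen-group mean of '", metric, "' is zero for material '", m,
           "'", call. = FALSE)
    }
    d_mean / f_mean
  }, numeric(1))
  list(per_material = rho, overall = mean(rho), n = length(values))
}

# Ratio recomputation given a fixed (design, material index) layout; used
# inside the permutation loop where inputs are already validated.
ratio_from_values <- function(values, dried_idx, frozen_idx) {
  n_mat <- length(dried_idx)
  rho <- numeric(n_mat)
  for (m in seq_len(n_mat)) {
    rho[m] <- mean(values[dried_idx[[m]]]) / mean(values[frozen_idx[[m]]])
  }
  mean(rho)
}

#' Material-controlled permutation location test on a scalar metric
#'
#' Tests whether the dried/frozen ratio-of-means statistic differs from 1,
#' under a null model in which metric values are randomly shuffled within each
#' material's samples (treatment labels fixed). This breaks any association
#' between value and treatment while preserving the association between value
#' and material, and makes no distributional assumptions. Significance is
#' two-sided around 1: the fraction of permuted statistics whose absolute
#' distance from 1 is at least the observed distance.
#'
#' @param table a [metric_table()].
#' @param metric metric name.
#' @param n_permutations number of random permutations (default 10,000).
#' @param seed integer seed; the test is deterministic given it.
#' @param estimator `"fraction"` (default) counts permutations at least as
#'   extreme as observed, exactly; `"add_one"` uses the (b + 1)/(N + 1)
#'   estimator, which can never return 0 and is guaranteed valid.
#' @param keep_null if `TRUE`, the permuted statistics are stored in the
#'   result (`null_ratios`).
#' @return A `location_test_result` with the per-material ratios, the overall
#'   ratio, the p-value, permutation count, sample count, seed and any
#'   warnings.
#' @export
location_test <- function(table, metric, n_permutations = 10000, seed = 1,
                          estimator = c("fraction", "add_one"),
                          keep_null = FALSE) {
  estimator <- match.arg(estimator)
  n_permutations <- check_count(n_permutations, "n_permutations")
  obs <- ratio_statistic(table, metric)
  warnings <- character()
  if (n_permutations < 100) {
    warnings <- c(warnings, "fewer than 100 permutations; p-value is coarse")
  }
  values <- table$metrics[, metric]
  keep <- !is.na(values)
  values <- values[keep]
  design <- table$design[keep, , drop = FALSE]
  materials <- sort(unique(design$material))
  mat_idx <- lapply(materials, function(m) which(design$material == m))
  dried_idx <- lapply(materials, function(m)
    which(design$material == m & design$treatment == "dried"))
  frozen_idx <- lapply(materials, function(m)
    which(design$material == m & design$treatment == "frozen"))
  obs_extreme <- abs(obs$overall - 1)
  null_ratios <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      perm <- values
      for (idx in mat_idx) {
        perm[idx] <- perm[idx][sample.int(length(idx))]
      }
      ratio_from_values(perm, dried_idx, frozen_idx)
    }, numeric(1))
  })
  hits <- sum(abs(null_ratios - 1) >= obs_extreme)
  p <- switch(estimator,
              fraction = hits / n_permutations,
              add_one = (hits + 1) / (n_permutations + 1))
  structure(
    list(metric_name = metric,
         per_material_ratio = obs$per_material,
         overall_ratio = obs$overall,
         p_value = p,
         n_permutations = n_permutations,
         n_samples = obs$n,
         seed = as.integer(seed),
         estimator = estimator,
         warnings = warnings,
         null_ratios = if (keep_null) null_ratios else NULL),
    class = "location_test_result"
  )
}

#' @export
print.location_test_result <- function(x, ...) {
  cat(sprintf("Ratio-of-means location test: %s\n", x$metric_name))
  cat("  per-material dried/frozen ratios:\n")
  print(round(x$per_material_ratio, 4))
  cat(sprintf("  overall ratio = %.4g, p = %.4g (%d permutations, n = %d)\n",
              x$overall_ratio, x$p_value, x$n_permutations, x$n_samples))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Run the location test over every metric of a table
#'
#' Convenience wrapper mirroring a full success-metric screen: one
#' [location_test()] per metric column, with per-metric child seeds derived
#' from the master seed via [derive_seed()].
#'
#' @param table a [metric_table()].
#' @param n_permutations permutations per metric.
#' @param seed master seed.
#' @return A data frame with one row per metric: the per-material ratios, the
#'   overall ratio, p-value, n and seed.
#' @export
location_test_all <- function(table, n_permutations = 10000, seed = 1) {
  metrics <- colnames(table$metrics)
  rows <- lapply(metrics, function(g) {
    res <- location_test(table, g, n_permutations = n_permutations,
                         seed = derive_seed(seed, "location_test", g))
    c(list(metric = g),
      as.list(stats::setNames(res$per_material_ratio,
                              paste0("ratio_", names(res$per_material_ratio)))),
      list(overall_ratio = res$overall_ratio, p_value = res$p_value,
           n = res$n_samples, seed = res$seed))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# Welch t statistic with unbiased variances; the degenerate zero-variance
# cases follow the documented convention (0/0 -> 0, x/0 -> +-Inf).
welch_statistic <- function(x, y) {
  num <- mean(x) - mean(y)
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  if (se2 == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / sqrt(se2)
}

# Column-wise Welch statistics for one dried/frozen split, from precomputed
# column sums (S, Q = sums of values and squares). Vectorised for the
# permutation loop; tiny negative variances from roundoff are clamped to 0.
welch_statistics_cols <- function(V, V2, S, Q, is_dried) {
  n1 <- sum(is_dried)
  n2 <- length(is_dried) - n1
  s1 <- colSums(V[is_dried, , drop = FALSE])
  q1 <- colSums(V2[is_dried, , drop = FALSE])
  m1 <- s1 / n1
  m2 <- (S - s1) / n2
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v2 <- ((Q - q1) - n2 * m2^2) / (n2 - 1)
  # constant groups must yield exactly zero variance despite cancellation error
  v1[v1 <= 1e-10 * q1 / (n1 - 1)] <- 0
  v2[v2 <= 1e-10 * (Q - q1) / (n2 - 1)] <- 0
  num <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  t <- num / sqrt(se2)
  zero_se <- se2 == 0
  t[zero_se] <- sign(num[zero_se]) * Inf
  t[zero_se & num == 0] <- 0
  t
}

#' Per-group Welch-statistic permutation tests within one material
#'
#' For each feature group (column) of the table restricted to one material,
#' compares dried and frozen proportions via the Welch t statistic, with
#' significance from a null model that permutes the treatment labels across
#' that material's samples (group sizes preserved). Two-sided on |t|.
#' Raw p-values are Bonferroni-adjusted across all groups tested in the
#' material. Groups with zero variance in both treatments and zero mean
#' difference get t = 0, p = 1; zero variance with a nonzero difference is
#' flagged infinite and gets the minimum attainable p.
#'
#' @param table a proportions-mode [feature_table()] (typically KEGG level-C
#'   or other grouped kind).
#' @param material material label; the material must have >= 2 samples per
#'   treatment.
#' @param n_permutations permutations (default 10,000).
#' @param seed integer seed.
#' @return A `group_location_result`: data frame `groups` with columns
#'   `group`, `statistic`, `p_value`, `p_adjusted`, plus metadata fields.
#' @export
welch_group_test <- function(table, material, n_permutations = 10000, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (table$mode != "proportions") {
    stop("welch_group_test requires a proportions-mode table", call. = FALSE)
  }
  n_permutations <- check_count(n_permutations, "n_permutations")
  sub <- subset_material(table, material)
  treat <- sub$design$treatment
  if (sum(treat == "dried") < 2 || sum(treat == "frozen") < 2) {
    stop("material '", material, "' needs >= 2 samples per treatment",
         call. = FALSE)
  }
  vals <- sub$values
  n <- nrow(vals)
  n_dried <- sum(treat == "dried")
  V2 <- vals^2
  S <- colSums(vals)
  Q <- colSums(V2)
  obs <- welch_statistics_cols(vals, V2, S, Q, treat == "dried")
  names(obs) <- colnames(vals)
  exceed <- integer(length(obs))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      is_dried <- seq_len(n) %in% sample.int(n, n_dried)
      t_star <- welch_statistics_cols(vals, V2, S, Q, is_dried)
      exceed <- exceed + (abs(t_star) >= abs(obs))
    }
  })
  raw_p <- exceed / n_permutations
  raw_p[obs == 0] <- 1  # degenerate all-equal groups: never evidence
  n_groups <- length(obs)
  adj_p <- pmin(1, raw_p * n_groups)
  structure(
    list(groups = data.frame(group = colnames(vals),
                             statistic = unname(obs),
                             p_value = unname(raw_p),
                             p_adjusted = unname(adj_p),
                             stringsAsFactors = FALSE),
         material = material,
         n_permutations = n_permutations,
         n_groups = n_groups,
         seed = as.integer(seed)),
    class = "group_location_result"
  )
}

#' @export
print.group_location_result <- function(x, ...) {
  cat(sprintf(
    "Welch-statistic permutation tests, material %s: %d groups, %d permutations\n",
    x$material, x$n_groups, x$n_permutations))
  sig <- x$groups[x$groups$p_adjusted < 0.05, , drop = FALSE]
  cat(sprintf("  %d group(s) significant after Bonferroni (alpha = 0.05)\n",
              nrow(sig)))
  invisible(x)
}
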