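#' Configuration for the synthetic paired-design generator
#'
#' The generator emulates the study design this package targets: several
#' source materials, each split into a dried and a frozen arm with an equal
#' number of replicates. Defaults follow that design (6 materials, 5
#' replicates per treatment, sequencing depths around 70,000 reads); where the
#' design itself fixes no value (feature count, heterogeneity), defaults are
#' plausible field-survey magnitudes, not fitted estimates.
#'
#' @param n_materials number of source materials (default 6).
#' @param n_replicates_per_treatment replicates per (material, treatment)
#'   stratum (default 5; must be >= 2).
#' @param n_features number of features in simulated community tables.
#' @param base_concentration total Dirichlet concentration for material base
#'   compositions; each feature gets `base_concentration / n_features`, so
#'   small values give sparse, uneven communities.
#' @param within_material_overdispersion Dirichlet concentration scaling for
#'   replicate-level compositional variation around the condition composition;
#'   larger values mean tighter replicates.
#' @param treatment_effect_sd standard deviation of per-feature Gaussian
#'   log-fold perturbations applied to the dried condition; 0 is the null.
#' @param depth_mean,depth_dispersion log-normal sequencing-depth model:
#'   depths are `round(exp(rnorm(log(depth_mean), depth_dispersion)))`,
#'   floored at 1,000 reads.
#' @param metric_effect_ratios named numeric vector: true multiplicative
#'   dried/frozen effect per scalar metric.
#' @param metric_cv coefficient of variation of the log-normal replicate
#'   noise on scalar metrics.
#' @param seed integer seed; all generation is deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_materials = 6,
                             n_replicates_per_treatment = 5,
                             n_features = 1000,
                             base_concentration = 50,
                             within_material_overdispersion = 200,
                             treatment_effect_sd = 0.3,
                             depth_mean = 70000,
                             depth_dispersion = 0.3,
                             metric_effect_ratios = c(yield = 1),
                             metric_cv = 0.2,
                             seed = 1) {
  cfg <- list(
    n_materials = check_count(n_materials, "n_materials"),
    n_replicates_per_treatment =
      check_count(n_replicates_per_treatment, "n_replicates_per_treatment", min = 2L),
    n_features = check_count(n_features, "n_features"),
    base_concentration = check_positive(base_concentration, "base_concentration"),
    within_material_overdispersion =
      check_positive(within_material_overdispersion, "within_material_overdispersion"),
    treatment_effect_sd = as.numeric(treatment_effect_sd),
    depth_mean = check_positive(depth_mean, "depth_mean"),
    depth_dispersion = check_positive(depth_dispersion, "depth_dispersion"),
    metric_effect_ratios = metric_effect_ratios,
    metric_cv = as.numeric(metric_cv),
    seed = as.integer(seed)
  )
  if (cfg$treatment_effect_sd < 0) stop("treatment_effect_sd must be >= 0", call. = FALSE)
  if (cfg$metric_cv < 0) stop("metric_cv must be >= 0", call. = FALSE)
  if (is.null(names(cfg$metric_effect_ratios)) ||
      any(!nzchar(names(cfg$metric_effect_ratios)))) {
    stop("metric_effect_ratios must be a named vector", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

synthetic_design <- function(cfg) {
  materials <- sprintf("material%d", seq_len(cfg$n_materials))
  reps <- cfg$n_replicates_per_treatment
  grid <- expand.grid(
    replicate = seq_len(reps),
    treatment = c("dried", "frozen"),
    material = materials,
    stringsAsFactors = FALSE
  )
  sample_design(
    sample_id = sprintf("%s_%s_r%d", grid$material, grid$treatment, grid$replicate),
    material = grid$material,
    treatment = grid$treatment,
    replicate = grid$replicate
  )
}

#' Simulate a scalar success-metric table with known treatment effects
#'
#' For material m and metric g, frozen replicate values are
#' `B[m,g] * exp(eps)` and dried values are `B[m,g] * r[g] * exp(eps)`, where
#' `B[m,g]` is a per-material log-normal baseline, `r[g]` the configured true
#' dried/frozen ratio and `eps` zero-mean Gaussian noise on the log scale with
#' standard deviation `sqrt(log(1 + cv^2))` (so the multiplicative noise has
#' the configured coefficient of variation).
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `table` (a [metric_table()]) and `truth`
#'   (ground truth: the baselines and true ratios exactly as used).
#' @export
simulate_metric_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  design <- synthetic_design(config)
  metrics <- names(config$metric_effect_ratios)
  materials <- unique(design$material)
  sdlog <- sqrt(log(1 + config$metric_cv^2))
  values <- matrix(NA_real_, nrow(design), length(metrics),
                   dimnames = list(design$sample_id, metrics))
  baselines <- matrix(NA_real_, length(materials), length(metrics),
                      dimnames = list(materials, metrics))
  with_seed(config$seed, {
    for (g in metrics) {
      r <- config$metric_effect_ratios[[g]]
      for (m in materials) {
        b <- exp(stats::rnorm(1, mean = log(100), sd = 1))
        baselines[m, g] <- b
        idx <- design$material == m
        eff <- ifelse(design$treatment[idx] == "dried", r, 1)
        eps <- if (sdlog > 0) stats::rnorm(sum(idx), 0, sdlog) else rep(0, sum(idx))
        values[idx, g] <- b * eff * exp(eps)
      }
    }
  })
  truth <- list(baselines = baselines,
                true_ratios = config$metric_effect_ratios,
                seed = config$seed)
  list(table = metric_table(design, values), truth = truth)
}

# One symmetric-Dirichlet draw (alpha recycled); returns a unit-sum vector.
rdirichlet1 <- function(alpha, n) {
  if (length(alpha) == 1L) alpha <- rep(alpha, n)
  g <- stats::rgamma(n, shape = alpha, rate = 1)
  if (sum(g) == 0) {             # all-zero draw possible for tiny alpha
    g[sample.int(n, 1)] <- 1
  }
  g / sum(g)
}

#' Simulate a community feature table with known compositional perturbations
#'
#' Each material gets a base composition `pi_m ~ Dirichlet(c/K, ..., c/K)`
#' (`c` = `base_concentration`, `K` = `n_features`). The dried condition
#' composition is `pi_m * exp(delta)` renormalised, with per-feature
#' `delta ~ N(0, treatment_effect_sd^2)`; the frozen condition uses `pi_m`
#' itself. Each replicate draws its own composition from
#' `Dirichlet(overdispersion * condition composition)` and counts from a
#' multinomial at a log-normal sequencing depth (floored at 1,000 reads).
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `table` (a counts-mode [feature_table()]) and
#'   `truth` (base compositions, per-material dried log-fold effects, depths).
#' @export
simulate_feature_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  design <- synthetic_design(config)
  K <- config$n_features
  materials <- unique(design$material)
  feats <- sprintf("feat%04d", seq_len(K))
  values <- matrix(0, nrow(design), K, dimnames = list(design$sample_id, feats))
  base <- matrix(NA_real_, length(materials), K, dimnames = list(materials, feats))
  logfold <- matrix(0, length(materials), K, dimnames = list(materials, feats))
  depths <- stats::setNames(numeric(nrow(design)), design$sample_id)
  with_seed(config$seed, {
    for (m in materials) {
      pi_m <- rdirichlet1(config$base_concentration / K, K)
      base[m, ] <- pi_m
      delta <- if (config$treatment_effect_sd > 0) {
        stats::rnorm(K, 0, config$treatment_effect_sd)
      } else {
        rep(0, K)
      }
      logfold[m, ] <- delta
      dried_comp <- pi_m * exp(delta)
      dried_comp <- dried_comp / sum(dried_comp)
      idx <- which(design$material == m)
      for (i in idx) {
        cond <- if (design$treatment[i] == "dried") dried_comp else pi_m
        rep_comp <- rdirichlet1(config$within_material_overdispersion * cond, K)
        depth <- max(1000, round(exp(stats::rnorm(
          1, log(config$depth_mean), config$depth_dispersion))))
        depths[i] <- depth
        values[i, ] <- stats::rmultinom(1, size = depth, prob = rep_comp)[, 1]
      }
    }
  })
  truth <- list(base_compositions = base, dried_logfold = logfold,
                depths = depths, seed = config$seed)
  list(table = feature_table(design, values, kind = "OTU", mode = "counts"),
       truth = truth)
}

#' Write generator ground truth to a plain-text sidecar file
#'
#' Recovery tests read the truth from this sidecar rather than re-deriving it
#' from the generator's internals.
#'
#' @param truth the `truth` element returned by a simulator.
#' @param path output path (TSV-of-blocks format).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# seed\t%d", truth$seed), con)
  for (nm in setdiff(names(truth), "seed")) {
    writeLines(sprintf("## %s", nm), con)
    x <- truth[[nm]]
    if (is.matrix(x)) {
      utils::write.table(cbind(id = rownames(x), as.data.frame(x)), con,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      utils::write.table(
        data.frame(id = names(x) %||% seq_along(x), value = as.numeric(x)),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
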