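#' Treatment-mean feature proportions within one material
#'
#' For each feature, the unweighted arithmetic mean of its per-sample
#' proportions across the material's dried replicates (`X`) and across its
#' frozen replicates (`Y`). For within-OTU tables (which carry `NA` for
#' absent (OTU, sample) blocks) means are taken over the non-missing
#' replicates, and features missing in an entire treatment come back `NaN`
#' so callers can drop them pairwise.
#'
#' @param table a proportions-mode or within-OTU [feature_table()].
#' @param material material label with >= 1 sample per treatment.
#' @return A list with numeric vectors `X` (dried means) and `Y` (frozen
#'   means), named by feature.
#' @export
treatment_mean_proportions <- function(table, material) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$mode %in% c("proportions", "within_otu")) {
    stop("treatment_mean_proportions requires proportions (or within-OTU) mode",
         call. = FALSE)
  }
  sub <- subset_material(table, material)
  treat <- sub$design$treatment
  if (!any(treat == "dried") || !any(treat == "frozen")) {
    stop("material '", material, "' lacks one of the treatments", call. = FALSE)
  }
  na_rm <- table$mode == "within_otu"
  X <- colMeans(sub$values[treat == "dried", , drop = FALSE], na.rm = na_rm)
  Y <- colMeans(sub$values[treat == "frozen", , drop = FALSE], na.rm = na_rm)
  list(X = X, Y = Y)
}

#' Abundance filter on treatment-mean proportions
#'
#' Retains feature `i` iff `X[i] >= threshold` and `Y[i] >= threshold`
#' ("at least", so the boundary is kept). Thresholds are proportions:
#' 0.01% = 1e-4 (the OTU/ASV/genus filter), 0.001% = 1e-5 (the gene filter).
#' The retained vectors are deliberately NOT renormalised.
#'
#' @param X,Y equal-length numeric vectors of treatment-mean proportions.
#' @param threshold minimum mean proportion required in both treatments.
#' @return Integer indices of retained features.
#' @export
abundance_filter <- function(X, Y, threshold = 1e-4) {
  if (length(X) != length(Y)) stop("X and Y must have equal length", call. = FALSE)
  which(!is.na(X) & !is.na(Y) & X >= threshold & Y >= threshold)
}

#' Coefficient of determination between treatment means
#'
#' `R^2 = 1 - sum((Y - X)^2) / sum((Y - mean(Y))^2)`: the fraction of
#' variance in the frozen means explained by the dried means, with the dried
#' means taken as a fixed prediction (no fitted slope or intercept). Equals 1
#' iff `X == Y` elementwise; can be negative when the disagreement exceeds the
#' spread of `Y`. The frozen means are the reference in the denominator, so
#' the statistic is not symmetric in its arguments.
#'
#' @param X numeric vector of dried treatment means.
#' @param Y numeric vector of frozen treatment means (not constant).
#' @return The coefficient of determination (a real number <= 1).
#' @export
#' @examples
#' r_squared(c(0.5, 0.3, 0.2), c(0.4, 0.4, 0.2))  # 0.25
r_squared <- function(X, Y) {
  if (length(X) != length(Y)) stop("X and Y must have equal length", call. = FALSE)
  if (length(Y) < 2) stop("need at least 2 features to compute R^2", call. = FALSE)
  ss_tot <- sum((Y - mean(Y))^2)
  if (ss_tot == 0) {
    stop("Y is constant; R^2 denominator is zero", call. = FALSE)
  }
  1 - sum((Y - X)^2) / ss_tot
}

agreement_pipeline <- function(vals, treat, threshold, na_rm = FALSE) {
  X <- colMeans(vals[treat == "dried", , drop = FALSE], na.rm = na_rm)
  Y <- colMeans(vals[treat == "frozen", , drop = FALSE], na.rm = na_rm)
  keep <- abundance_filter(X, Y, threshold)
  if (length(keep) < 2) return(list(r2 = NA_real_, X = X, Y = Y, keep = keep))
  Xk <- X[keep]
  Yk <- Y[keep]
  if (sum((Yk - mean(Yk))^2) == 0) {
    return(list(r2 = NA_real_, X = X, Y = Y, keep = keep))
  }
  list(r2 = 1 - sum((Yk - Xk)^2) / sum((Yk - mean(Yk))^2),
       X = X, Y = Y, keep = keep)
}

#' Compositional agreement test between treatments within one material
#'
#' Observed pipeline: treatment means -> abundance filter -> coefficient of
#' determination. Significance comes from a null model in which the treatment
#' labels of the material's samples are randomly permuted (group sizes
#' preserved), the means re-computed, the filter re-applied and the statistic
#' re-computed; the p-value is the fraction of permutations yielding a
#' *strictly lower* statistic than observed (one-sided: a low value means
#' treatment-driven disagreement).
#'
#' @param table a proportions-mode (or within-OTU) [feature_table()].
#' @param material material label with both treatments present.
#' @param threshold abundance filter on treatment means (default 1e-4, i.e.
#'   0.01%; use 1e-5 for gene tables).
#' @param n_permutations permutations (default 10,000).
#' @param seed integer seed.
#' @param refilter if `TRUE` (default) the abundance filter is re-applied
#'   within every permutation, keeping the null exchangeable with the observed
#'   pipeline; `FALSE` freezes the observed feature set.
#' @param include_ties if `TRUE`, permutations tying the observed statistic
#'   count toward the p-value numerator; default `FALSE` counts strictly
#'   lower values only.
#' @return An `agreement_result` carrying `X`, `Y` (all features), the
#'   retained index set, `r_squared`, `n_features_retained`, `p_value` and
#'   the test metadata. Degenerate permutations (fewer than 2 retained
#'   features, or constant frozen means) are excluded from the null; if every
#'   permutation is degenerate the test errors.
#' @export
agreement_test <- function(table, material, threshold = 1e-4,
                           n_permutations = 10000, seed = 1,
                           refilter = TRUE, include_ties = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$mode %in% c("proportions", "within_otu")) {
    stop("agreement_test requires proportions (or within-OTU) mode", call. = FALSE)
  }
  n_permutations <- check_count(n_permutations, "n_permutations")
  sub <- subset_material(table, material)
  treat <- sub$design$treatment
  if (!any(treat == "dried") || !any(treat == "frozen")) {
    stop("material '", material, "' lacks one of the treatments", call. = FALSE)
  }
  na_rm <- table$mode == "within_otu"
  vals <- sub$values
  obs <- agreement_pipeline(vals, treat, threshold, na_rm)
  if (is.na(obs$r2)) {
    stop("observed pipeline is degenerate (fewer than 2 retained features, ",
         "or constant frozen means)", call. = FALSE)
  }
  n <- nrow(vals)
  frozen_set <- if (!refilter) obs$keep else NULL
  null_r2 <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      perm_treat <- treat[sample.int(n)]
      if (refilter) {
        agreement_pipeline(vals, perm_treat, threshold, na_rm)$r2
      } else {
        Xp <- colMeans(vals[perm_treat == "dried", , drop = FALSE], na.rm = na_rm)
        Yp <- colMeans(vals[perm_treat == "frozen", , drop = FALSE], na.rm = na_rm)
        Xk <- Xp[frozen_set]
        Yk <- Yp[frozen_set]
        ss <- sum((Yk - mean(Yk))^2)
        if (ss == 0) NA_real_ else 1 - sum((Yk - Xk)^2) / ss
      }
    }, numeric(1))
  })
  valid <- !is.na(null_r2)
  if (!any(valid)) {
    stop("all permutations were degenerate; agreement test undefined", call. = FALSE)
  }
  hits <- if (include_ties) {
    sum(null_r2[valid] <= obs$r2)
  } else {
    sum(null_r2[valid] < obs$r2)
  }
  structure(
    list(material = material,
         feature_kind = table$kind,
         X = obs$X, Y = obs$Y,
         retained = obs$keep,
         Y_bar = mean(obs$Y[obs$keep]),
         r_squared = obs$r2,
         n_features_retained = length(obs$keep),
         p_value = hits / sum(valid),
         abundance_threshold = threshold,
         n_permutations = n_permutations,
         n_valid_permutations = sum(valid),
         refilter = refilter,
         include_ties = include_ties,
         seed = as.integer(seed)),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Compositional agreement (%s level), material %s:\n", x$feature_kind,
    x$material))
  cat(sprintf("  R^2 = %.4g over n = %d retained features (threshold %g)\n",
              x$r_squared, x$n_features_retained, x$abundance_threshold))
  cat(sprintf("  p = %.4g (%d permutations)\n", x$p_value, x$n_permutations))
  invisible(x)
}

#' Within-OTU ASV proportion table (strain-level decomposition)
#'
#' For each sample and each OTU, renormalises the member ASVs' proportions so
#' they sum to 1 within that OTU. This separates strain-level shifts (changes
#' among conspecific ASVs) from species-level shifts: agreement tests on the
#' output are blind to whole-OTU abundance changes. (OTU, sample) blocks with
#' zero total are flagged missing (`NA`), not zero.
#'
#' @param asv_table a proportions-mode ASV [feature_table()].
#' @param membership named character vector ASV -> OTU; defaults to the
#'   table's own membership annotation. Must cover every ASV.
#' @param min_sample_proportion optional per-sample inclusion rule: ASVs must
#'   represent at least this proportion of reads in a sample to enter that
#'   sample's renormalisation (the default 1e-4 mirrors the 0.01% rule used
#'   upstream); set to 0 to include everything.
#' @return A `feature_table` of kind ASV in `"within_otu"` mode.
#' @export
within_otu_asv_table <- function(asv_table, membership = NULL,
                                 min_sample_proportion = 1e-4) {
  stopifnot(inherits(asv_table, "feature_table"))
  if (asv_table$kind != "ASV") stop("input must be an ASV table", call. = FALSE)
  if (asv_table$mode != "proportions") {
    stop("input must be in proportions mode", call. = FALSE)
  }
  membership <- membership %||% asv_table$membership
  if (is.null(membership)) stop("no ASV -> OTU membership provided", call. = FALSE)
  feats <- colnames(asv_table$values)
  missing_m <- setdiff(feats, names(membership))
  if (length(missing_m)) {
    stop("ASV(s) without membership: ",
         paste(utils::head(missing_m, 5), collapse = ", "), call. = FALSE)
  }
  otus <- membership[feats]
  vals <- asv_table$values
  vals[vals < min_sample_proportion] <- 0  # per-sample inclusion rule
  out <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  for (otu in unique(otus)) {
    cols <- which(otus == otu)
    block <- vals[, cols, drop = FALSE]
    totals <- rowSums(block)
    present <- totals > 0
    out[present, cols] <- block[present, , drop = FALSE] / totals[present]
  }
  ft <- asv_table
  ft$values <- out
  ft$mode <- "within_otu"
  ft$membership <- membership[feats]
  ft
}
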