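#' Distance matrix container
#'
#' Symmetric non-negative pairwise dissimilarities with a zero diagonal.
#'
#' @param values symmetric numeric matrix with zero diagonal.
#' @param metric_name name of the dissimilarity metric.
#' @return A `distance_matrix` object.
#' @export
distance_matrix <- function(values, metric_name = "unknown") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square", call. = FALSE)
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("s", seq_len(nrow(values)))
  }
  if (max(abs(values - t(values))) > 1e-12) {
    stop("matrix not symmetric within 1e-12", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (any(diag(values) != 0)) stop("diagonal must be exactly zero", call. = FALSE)
  if (any(values < 0)) stop("dissimilarities must be non-negative", call. = FALSE)
  structure(list(sample_ids = rownames(values), values = values,
                 metric_name = metric_name),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix (%s): %d samples\n", x$metric_name,
              length(x$sample_ids)))
  invisible(x)
}

#' @export
as.dist.distance_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

pairwise_distance <- function(mat, fun, metric_name) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- fun(mat[i, ], mat[j, ])
    }
  }
  distance_matrix(d, metric_name)
}

#' Abundance-weighted Bray-Curtis dissimilarities
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)`; on unit-sum rows this equals half
#' the L1 distance, so values lie in [0, 1].
#'
#' @param table a proportions-mode [feature_table()].
#' @return A [distance_matrix()].
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$mode != "proportions") {
    stop("bray_curtis requires a proportions-mode table", call. = FALSE)
  }
  pairwise_distance(table$values, function(x, y) {
    sum(abs(x - y)) / sum(x + y)
  }, "bray_curtis")
}

#' Abundance-weighted Jaccard (Ruzicka) dissimilarities
#'
#' `d(x, y) = 1 - sum(pmin(x, y)) / sum(pmax(x, y))`, the quantitative
#' generalisation of the Jaccard index. Undefined (error) if two all-zero
#' rows are compared.
#'
#' @param table a proportions-mode [feature_table()].
#' @return A [distance_matrix()].
#' @export
weighted_jaccard <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$mode != "proportions") {
    stop("weighted_jaccard requires a proportions-mode table", call. = FALSE)
  }
  pairwise_distance(table$values, function(x, y) {
    denom <- sum(pmax(x, y))
    if (denom == 0) stop("weighted Jaccard undefined for two all-zero rows",
                         call. = FALSE)
    1 - sum(pmin(x, y)) / denom
  }, "weighted_jaccard")
}

kruskal_stress1 <- function(embedded_d, target_d) {
  sqrt(sum((embedded_d - target_d)^2) / sum(target_d^2))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres the squared-dissimilarity matrix and eigendecomposes it;
#' coordinates come from the top positive eigenpairs. Negative eigenvalues
#' (from non-Euclidean dissimilarities) are reported, never silently clipped.
#'
#' @param D a [distance_matrix()].
#' @param dims requested embedding dimension (default 2). If fewer positive
#'   eigenvalues exist, fewer columns are returned and the result is flagged
#'   (`deficient = TRUE`).
#' @return An `ordination_result` with `coordinates`, `eigenvalues` (all of
#'   them, decreasing), `explained` (variance fractions over positive
#'   eigenvalues), `method = "pcoa"`.
#' @export
pcoa <- function(D, dims = 2) {
  stopifnot(inherits(D, "distance_matrix"))
  dims <- check_count(dims, "dims")
  n <- length(D$sample_ids)
  if (dims >= n) stop("dims must be smaller than the number of samples", call. = FALSE)
  # classical scaling via stats::cmdscale, keeping the full eigen spectrum
  cs <- stats::cmdscale(D$values, k = n - 1, eig = TRUE)
  eig <- cs$eig
  pos <- which(eig > max(eig) * 1e-12 & eig > 0)
  k <- min(dims, length(pos))
  coords <- cs$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- D$sample_ids
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(
    list(coordinates = coords,
         eigenvalues = sort(eig, decreasing = TRUE),
         explained = eig[pos] / sum(eig[pos]),
         stress = NA_real_,
         method = "pcoa",
         converged = TRUE,
         deficient = k < dims,
         n_iterations = 0L,
         seed = NA_integer_),
    class = "ordination_result"
  )
}

#' Metric multidimensional scaling by Kruskal stress minimisation
#'
#' Embeds a dissimilarity matrix into `dims` dimensions by minimising the
#' Kruskal stress-1 function
#' `sqrt(sum((d_ij - delta_ij)^2) / sum(delta_ij^2))`, where `delta` are the
#' input dissimilarities and `d` the embedded Euclidean distances. Descent
#' uses SMACOF majorisation (raw stress never increases across iterations)
#' starting from the PCoA configuration, optionally followed by seeded random
#' restarts; the best configuration wins.
#'
#' @param D a [distance_matrix()].
#' @param dims embedding dimension (default 2, as in ordination plots).
#' @param seed integer seed (used for random restarts).
#' @param n_restarts number of additional random initialisations (default 0:
#'   PCoA start only).
#' @param max_iter iteration cap per start (default 10,000).
#' @param tol relative raw-stress change declaring convergence (default 1e-10).
#' @return An `ordination_result` with `coordinates`, final `stress`
#'   (Kruskal stress-1), `converged`, `n_iterations`, `method = "mmds"`.
#'   Non-convergence flags the result rather than erroring.
#' @export
mmds <- function(D, dims = 2, seed = 1, n_restarts = 0, max_iter = 10000,
                 tol = 1e-10) {
  stopifnot(inherits(D, "distance_matrix"))
  dims <- check_count(dims, "dims")
  n <- length(D$sample_ids)
  if (dims >= n) stop("dims must be smaller than the number of samples", call. = FALSE)
  delta <- D$values
  starts <- list(pcoa_start(D, dims))
  if (n_restarts > 0) {
    extra <- with_seed(seed, {
      lapply(seq_len(n_restarts), function(r) {
        matrix(stats::rnorm(n * dims, sd = stats::sd(delta) + 1e-12), n, dims)
      })
    })
    starts <- c(starts, extra)
  }
  best <- NULL
  for (X0 in starts) {
    fit <- smacof_descent(delta, X0, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- best$X
  rownames(coords) <- D$sample_ids
  colnames(coords) <- paste0("MDS", seq_len(dims))
  structure(
    list(coordinates = coords,
         eigenvalues = NULL,
         explained = NULL,
         stress = best$stress,
         method = "mmds",
         converged = best$converged,
         deficient = FALSE,
         n_iterations = best$iterations,
         seed = as.integer(seed)),
    class = "ordination_result"
  )
}

pcoa_start <- function(D, dims) {
  n <- length(D$sample_ids)
  cs <- stats::cmdscale(D$values, k = min(dims, n - 1), eig = TRUE)
  X <- cs$points
  if (ncol(X) < dims) {  # pad when positive eigenvalues are scarce
    X <- cbind(X, matrix(0, n, dims - ncol(X)))
  }
  unname(X[, seq_len(dims), drop = FALSE])
}

# SMACOF majorisation with unit weights. Guttman transform:
# X <- (1/n) B(X) X, where b_ij = -delta_ij / d_ij for i != j (0 when
# d_ij = 0) and b_ii = -sum_j b_ij. Raw stress sum((delta - d)^2) is
# non-increasing; stress-1 is reported.
smacof_descent <- function(delta, X, max_iter, tol) {
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  raw <- sum((delta - d)^2) / 2
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(d > 0, delta / d, 0)
    diag(ratio) <- 0
    B <- -ratio
    diag(B) <- rowSums(ratio)
    X_new <- B %*% X / n
    d_new <- as.matrix(stats::dist(X_new))
    raw_new <- sum((delta - d_new)^2) / 2
    X <- X_new
    d <- d_new
    if (raw - raw_new <= tol * max(raw, .Machine$double.eps)) {
      raw <- raw_new
      converged <- TRUE
      break
    }
    raw <- raw_new
  }
  list(X = X, stress = kruskal_stress1(d[upper.tri(d)],
                                       delta[upper.tri(delta)]),
       converged = converged, iterations = it)
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("Ordination (%s): %d samples in %d dimension(s)\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates)))
  if (x$method == "mmds") {
    cat(sprintf("  Kruskal stress-1 = %.4g (%d iterations, converged: %s)\n",
                x$stress, x$n_iterations, x$converged))
  } else {
    cat(sprintf("  variance explained by shown axes: %s\n",
                paste(sprintf("%.1f%%", 100 * utils::head(
                  x$explained, ncol(x$coordinates))), collapse = ", ")))
  }
  invisible(x)
}

permanova_F <- function(d2, groups) {
  # Anderson's distance-based decomposition on squared dissimilarities.
  N <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  a <- length(unique(groups))
  F_stat <- (ss_between / (a - 1)) / (ss_within / (N - a))
  list(F = F_stat, r2 = ss_between / ss_total,
       ss_total = ss_total, ss_within = ss_within, ss_between = ss_between)
}

#' Per-material PERMANOVA for a treatment effect
#'
#' One-factor permutational multivariate ANOVA on a dissimilarity matrix,
#' restricted to one material's samples, testing separation between the two
#' treatments via the pseudo-F statistic. `SS_total = sum_{i<j} d_ij^2 / N`;
#' `SS_within` sums within-group pair terms with group-size normalisation;
#' `pseudo-F = (SS_between / (a - 1)) / (SS_within / (N - a))` with `a = 2`
#' groups. Significance is the fraction of treatment-label permutations
#' (within the material) with `F* >= F_obs`.
#'
#' @param D a [distance_matrix()] covering (at least) the material's samples.
#' @param design a [sample_design()].
#' @param material material label; both treatment groups need >= 2 samples.
#' @param n_permutations permutations (default 10,000).
#' @param seed integer seed.
#' @return A `permanova_result` with `pseudo_F`, `r_squared_between`
#'   (fraction of dissimilarity variance explained by treatment), `p_value`
#'   and metadata.
#' @export
permanova <- function(D, design, material, n_permutations = 10000, seed = 1) {
  stopifnot(inherits(D, "distance_matrix"), inherits(design, "sample_design"))
  n_permutations <- check_count(n_permutations, "n_permutations")
  sub <- design_material(design, material)
  ids <- sub$sample_id
  if (!all(ids %in% D$sample_ids)) {
    stop("distance matrix is missing samples of material '", material, "'",
         call. = FALSE)
  }
  groups <- sub$treatment
  if (any(table(groups) < 2)) {
    stop("each treatment group needs >= 2 samples for PERMANOVA", call. = FALSE)
  }
  d2 <- D$values[ids, ids, drop = FALSE]^2
  obs <- permanova_F(d2, groups)
  n <- length(groups)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(b) {
      permanova_F(d2, groups[sample.int(n)])$F >= obs$F
    }, logical(1)))
  })
  structure(
    list(material = material,
         metric_name = D$metric_name,
         pseudo_F = obs$F,
         r_squared_between = obs$r2,
         ss_total = obs$ss_total,
         ss_within = obs$ss_within,
         ss_between = obs$ss_between,
         p_value = hits / n_permutations,
         n_permutations = n_permutations,
         n_samples = n,
         seed = as.integer(seed)),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s), material %s:\n", x$metric_name, x$material))
  cat(sprintf("  pseudo-F = %.4g, R^2 = %.3f, p = %.4g (%d permutations, n = %d)\n",
              x$pseudo_F, x$r_squared_between, x$p_value, x$n_permutations,
              x$n_samples))
  invisible(x)
}
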