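#' Sample design: material / treatment / replicate assignment
#'
#' The sample design records, for every sample, the source material it came
#' from, the preservation treatment it received (`"dried"` or `"frozen"`) and
#' its replicate number. It is the exchangeability structure of every
#' permutation null model in the package: location tests shuffle values within
#' a material, agreement tests and PERMANOVA shuffle treatment labels within a
#' material.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param material character vector of source-material labels (e.g. "faeces1").
#' @param treatment character vector; each element must be "dried" or "frozen".
#' @param replicate integer vector of replicate numbers (>= 1). Defaults to a
#'   running index within each (material, treatment) stratum.
#' @return A `sample_design` object: a data frame with columns `sample_id`,
#'   `material`, `treatment`, `replicate`.
#' @export
#' @examples
#' sample_design(c("s1", "s2"), c("f1", "f1"), c("dried", "frozen"))
sample_design <- function(sample_id, material, treatment, replicate = NULL) {
  sample_id <- as.character(sample_id)
  material <- as.character(material)
  treatment <- as.character(treatment)
  n <- length(sample_id)
  if (length(material) != n || length(treatment) != n) {
    stop("sample_id, material and treatment must have equal length", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    dup <- unique(sample_id[duplicated(sample_id)])
    stop("duplicate sample_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- !(treatment %in% c("dried", "frozen"))
  if (any(bad)) {
    stop("unknown treatment label(s) in row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(treatment[bad]), collapse = ", "), call. = FALSE)
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_len(n), material, treatment, FUN = seq_along)
  }
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1L)) {
    stop("replicate numbers must be integers >= 1", call. = FALSE)
  }
  out <- data.frame(
    sample_id = sample_id,
    material = material,
    treatment = treatment,
    replicate = replicate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sample_design", "data.frame")
  out
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf(
    "Sample design: %d samples, %d material(s) (%s)\n",
    nrow(x), length(unique(x$material)),
    paste(sort(unique(x$material)), collapse = ", ")
  ))
  tab <- table(x$material, x$treatment)
  print(tab)
  invisible(x)
}

# Samples of one material, asserting both treatments present if required.
design_material <- function(design, material, require_both = TRUE) {
  sub <- design[design$material == material, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("no samples for material '", material, "'", call. = FALSE)
  }
  if (require_both && !all(c("dried", "frozen") %in% sub$treatment)) {
    stop("material '", material, "' lacks one of the treatments", call. = FALSE)
  }
  sub
}

#' Metric table: samples by scalar success metrics
#'
#' Bundles a [sample_design()] with a numeric matrix of per-sample scalar
#' success metrics (DNA yield, absorbance ratios, read counts, contig counts,
#' ...). Missing values are kept as `NA`, never silently zeroed.
#'
#' @param design a `sample_design`.
#' @param metrics numeric matrix, one row per sample (rownames must match
#'   `design$sample_id`), one column per metric.
#' @return A `metric_table` object.
#' @export
metric_table <- function(design, metrics) {
  stopifnot(inherits(design, "sample_design"))
  metrics <- as.matrix(metrics)
  storage.mode(metrics) <- "double"
  if (is.null(rownames(metrics))) rownames(metrics) <- design$sample_id
  if (!identical(rownames(metrics), design$sample_id)) {
    if (!setequal(rownames(metrics), design$sample_id)) {
      stop("metric rows do not match design sample ids", call. = FALSE)
    }
    metrics <- metrics[design$sample_id, , drop = FALSE]
  }
  if (is.null(colnames(metrics))) {
    stop("metric columns must be named", call. = FALSE)
  }
  structure(list(design = design, metrics = metrics), class = "metric_table")
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf(
    "Metric table: %d samples x %d metric(s): %s\n",
    nrow(x$metrics), ncol(x$metrics),
    paste(colnames(x$metrics), collapse = ", ")
  ))
  n_missing <- sum(is.na(x$metrics))
  if (n_missing > 0) cat(sprintf("  (%d missing values)\n", n_missing))
  invisible(x)
}

FEATURE_KINDS <- c("OTU", "ASV", "genus", "KO", "KEGG_C")

#' Feature table: samples by features (counts or proportions)
#'
#' Bundles a [sample_design()] with a non-negative samples x features matrix.
#' In `"counts"` mode entries are read counts; in `"proportions"` mode every
#' sample row sums to 1. The `"within_otu"` mode is produced by
#' [within_otu_asv_table()] and holds per-OTU renormalised ASV proportions in
#' which absent (OTU, sample) blocks are `NA`; its rows deliberately do not
#' sum to 1.
#'
#' @param design a `sample_design`.
#' @param values non-negative numeric matrix, rows = samples (rownames must
#'   match the design), columns = features.
#' @param kind one of `"OTU"`, `"ASV"`, `"genus"`, `"KO"`, `"KEGG_C"`.
#' @param mode `"counts"`, `"proportions"` or `"within_otu"`.
#' @param taxonomy optional named character vector mapping feature ->
#'   rank-prefixed, semicolon-separated lineage string.
#' @param membership optional named character vector mapping ASV -> OTU;
#'   must cover every feature exactly once when present.
#' @return A `feature_table` object.
#' @export
feature_table <- function(design, values, kind = "OTU",
                          mode = c("counts", "proportions", "within_otu"),
                          taxonomy = NULL, membership = NULL) {
  stopifnot(inherits(design, "sample_design"))
  mode <- match.arg(mode)
  kind <- match.arg(kind, FEATURE_KINDS)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) rownames(values) <- design$sample_id
  if (!identical(rownames(values), design$sample_id)) {
    if (!setequal(rownames(values), design$sample_id)) {
      stop("feature-table rows do not match design sample ids", call. = FALSE)
    }
    values <- values[design$sample_id, , drop = FALSE]
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("feature", seq_len(ncol(values)))
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("feature values must be non-negative", call. = FALSE)
  }
  if (mode == "counts" && any(is.na(values))) {
    stop("counts-mode tables cannot contain missing values", call. = FALSE)
  }
  if (mode == "proportions") {
    rs <- rowSums(values)
    off <- abs(rs - 1) > 1e-6
    if (any(off)) {
      stop("proportions rows must sum to 1 (+/- 1e-6); offending sample(s): ",
           paste(rownames(values)[off], collapse = ", "), call. = FALSE)
    }
    values <- values / rs  # renormalise rounded inputs to exact unit sums
  }
  if (!is.null(membership)) {
    feats <- colnames(values)
    if (!all(feats %in% names(membership))) {
      miss <- setdiff(feats, names(membership))
      stop("membership missing for ASV(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    membership <- membership[feats]
  }
  structure(
    list(design = design, values = values, kind = kind, mode = mode,
         taxonomy = taxonomy, membership = membership),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "Feature table (%s, %s mode): %d samples x %d features\n",
    x$kind, x$mode, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Restrict a feature table to the samples of one material
#'
#' @param table a `feature_table`.
#' @param material material label present in the design.
#' @return A `feature_table` containing only that material's samples.
#' @export
subset_material <- function(table, material) {
  stopifnot(inherits(table, "feature_table"))
  sub <- design_material(table$design, material, require_both = FALSE)
  design <- sample_design(sub$sample_id, sub$material, sub$treatment, sub$replicate)
  out <- table
  out$design <- design
  out$values <- table$values[sub$sample_id, , drop = FALSE]
  out
}
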