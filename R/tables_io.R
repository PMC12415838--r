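# TSV dialect shared by all readers/writers: header row required, tab
# delimiter only, UTF-8; "NA" and "" parse as missing. Strictness catches
# silent column shifts in hand-edited supplements.
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(
    path, header = TRUE, sep = "\t", quote = "", comment.char = "",
    stringsAsFactors = FALSE, check.names = FALSE, na.strings = c("NA", ""),
    fileEncoding = "UTF-8"
  )
}

#' Read a per-sample scalar success-metric table from TSV
#'
#' Parses a tab-separated file with one row per sample. The `schema` map names
#' which columns carry the sample identifier, material and treatment; every
#' remaining column is treated as a numeric success metric. Non-numeric cells
#' in metric columns become explicit missing values (`NA`).
#'
#' @param path path to a TSV file with a header row.
#' @param schema named list with entries `sample`, `material`, `treatment`
#'   (and optionally `replicate`) giving the corresponding column names; any
#'   other metadata columns can be excluded via `drop`.
#' @param drop optional character vector of additional columns to ignore.
#' @return A [metric_table()].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample\tmaterial\ttreatment\tyield",
#'              "s1\tf1\tdried\t10", "s2\tf1\tfrozen\t5"), tf)
#' read_metric_table(tf)
read_metric_table <- function(path,
                              schema = list(sample = "sample",
                                            material = "material",
                                            treatment = "treatment"),
                              drop = character()) {
  df <- read_tsv_strict(path)
  needed <- unlist(schema[c("sample", "material", "treatment")])
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  treatment <- tolower(as.character(df[[schema$treatment]]))
  bad <- !(treatment %in% c("dried", "frozen"))
  if (any(bad)) {
    stop("unknown treatment label in row(s) ",
         paste(which(bad), collapse = ", "), " of ", path, ": '",
         paste(unique(df[[schema$treatment]][bad]), collapse = "', '"), "'",
         call. = FALSE)
  }
  design <- sample_design(
    sample_id = as.character(df[[schema$sample]]),
    material = as.character(df[[schema$material]]),
    treatment = treatment,
    replicate = if (!is.null(schema$replicate)) df[[schema$replicate]] else NULL
  )
  meta_cols <- c(unlist(schema), drop)
  metric_cols <- setdiff(names(df), meta_cols)
  if (length(metric_cols) == 0L) {
    stop("no metric columns found in ", path, call. = FALSE)
  }
  metrics <- vapply(
    metric_cols,
    function(cl) suppressWarnings(as.numeric(df[[cl]])),
    numeric(nrow(df))
  )
  metrics <- matrix(metrics, nrow = nrow(df),
                    dimnames = list(design$sample_id, metric_cols))
  metric_table(design, metrics)
}

#' Write a metric table to TSV
#'
#' @param table a [metric_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  stopifnot(inherits(table, "metric_table"))
  df <- cbind(
    as.data.frame(table$design)[c("sample_id", "material", "treatment", "replicate")],
    as.data.frame(table$metrics)
  )
  names(df)[1] <- "sample"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature abundance table from TSV
#'
#' Reads a samples x features table (or its transpose, via `orientation`).
#' The table is returned in counts mode if every entry is a whole number,
#' otherwise in proportions mode after validating that each sample row sums
#' to 1 within 1e-6. A leading `#OTU ID` header line (the BIOM-TSV flavour)
#' is accepted when features are in rows.
#'
#' @param path path to a TSV file.
#' @param design a [sample_design()] covering the table's samples.
#' @param kind feature kind, one of `"OTU"`, `"ASV"`, `"genus"`, `"KO"`,
#'   `"KEGG_C"`.
#' @param orientation `"samples_in_rows"` or `"features_in_rows"`.
#' @param taxonomy,membership optional annotations, see [feature_table()].
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, design, kind = "OTU",
                               orientation = c("samples_in_rows",
                                               "features_in_rows"),
                               taxonomy = NULL, membership = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  # BIOM-TSV flavour: "# Constructed from biom file" comment then "#OTU ID..."
  if (length(lines) && startsWith(lines[1], "#") && !startsWith(lines[1], "#OTU ID")) {
    lines <- lines[-1]
  }
  if (length(lines) && startsWith(lines[1], "#OTU ID")) {
    lines[1] <- sub("^#OTU ID", "feature_id", lines[1])
    if (orientation != "features_in_rows") {
      stop("'#OTU ID' header implies features_in_rows orientation", call. = FALSE)
    }
  }
  df <- utils::read.table(
    text = lines, header = TRUE, sep = "\t", quote = "", comment.char = "",
    stringsAsFactors = FALSE, check.names = FALSE, na.strings = c("NA", "")
  )
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (orientation == "features_in_rows") mat <- t(mat)
  if (any(is.na(mat))) {
    stop("feature table contains non-numeric or missing entries", call. = FALSE)
  }
  if (any(mat < 0)) stop("negative entries in feature table", call. = FALSE)
  is_counts <- all(mat == round(mat))
  feature_table(design, mat, kind = kind,
                mode = if (is_counts) "counts" else "proportions",
                taxonomy = taxonomy, membership = membership)
}

#' Write a feature table to TSV
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @param orientation `"samples_in_rows"` or `"features_in_rows"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path,
                                orientation = c("samples_in_rows",
                                                "features_in_rows")) {
  stopifnot(inherits(table, "feature_table"))
  orientation <- match.arg(orientation)
  mat <- table$values
  if (orientation == "features_in_rows") mat <- t(mat)
  id_name <- if (orientation == "features_in_rows") "feature_id" else "sample_id"
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an ASV-to-OTU membership map
#'
#' Two-column TSV (`asv_id`, `otu_id`).
#'
#' @param path path to the TSV file.
#' @return Named character vector mapping ASV id -> OTU id.
#' @export
read_membership <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L) stop("membership file needs two columns", call. = FALSE)
  if (anyDuplicated(df[[1]])) {
    stop("ASV(s) listed more than once in membership file", call. = FALSE)
  }
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Convert a counts-mode feature table to proportions
#'
#' Each sample row is divided by its total so rows sum to 1; zero counts stay
#' zero. Idempotent on proportions-mode input.
#'
#' @param table a [feature_table()].
#' @return A proportions-mode `feature_table`.
#' @export
to_proportions <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$mode == "proportions") return(table)
  if (table$mode != "counts") {
    stop("to_proportions expects a counts- or proportions-mode table", call. = FALSE)
  }
  totals <- rowSums(table$values)
  zero <- totals == 0
  if (any(zero)) {
    stop("all-zero sample row(s): ",
         paste(rownames(table$values)[zero], collapse = ", "), call. = FALSE)
  }
  out <- table
  out$values <- table$values / totals
  out$mode <- "proportions"
  out
}

#' Aggregate features into groups (e.g. KOs into KEGG level-C groups)
#'
#' Each group's value per sample is the sum of its member features' values.
#' Groups named in `omit` are removed *before* any renormalisation; in
#' proportions mode the remaining groups are then renormalised to sum 1 per
#' sample, mirroring how non-functional catalogue groups are excluded from
#' functional profiles.
#'
#' @param table a [feature_table()].
#' @param grouping either a named character vector (feature -> group) or a
#'   two-column data frame (feature, group). A feature mapped to two distinct
#'   groups is an error. Features absent from the map are dropped.
#' @param new_kind feature kind of the output table.
#' @param omit character vector of group labels to remove before aggregation.
#' @return A `feature_table` of kind `new_kind` whose features are the groups.
#' @export
aggregate_features <- function(table, grouping, new_kind = "KEGG_C",
                               omit = character()) {
  stopifnot(inherits(table, "feature_table"))
  if (is.data.frame(grouping)) {
    g <- unique(grouping[, 1:2])
    if (anyDuplicated(g[[1]])) {
      dups <- unique(g[[1]][duplicated(g[[1]])])
      stop("feature(s) mapped to two groups: ",
           paste(utils::head(dups, 5), collapse = ", "), call. = FALSE)
    }
    grouping <- stats::setNames(as.character(g[[2]]), as.character(g[[1]]))
  }
  feats <- intersect(colnames(table$values), names(grouping))
  if (length(feats) == 0L) stop("grouping covers no features of the table", call. = FALSE)
  groups <- grouping[feats]
  keep <- !(groups %in% omit)
  feats <- feats[keep]
  groups <- as.character(groups[keep])
  vals <- table$values[, feats, drop = FALSE]
  agg <- t(rowsum(t(vals), group = groups))
  out <- table
  out$kind <- match.arg(new_kind, FEATURE_KINDS)
  out$taxonomy <- NULL
  out$membership <- NULL
  if (table$mode == "proportions") {
    rs <- rowSums(agg)
    if (any(rs == 0)) {
      stop("aggregation left all-zero sample row(s): ",
           paste(rownames(agg)[rs == 0], collapse = ", "), call. = FALSE)
    }
    out$values <- agg / rs
    out$mode <- "proportions"
  } else {
    out$values <- agg
  }
  out
}

#' Build a feature -> genus grouping from lineage strings
#'
#' Lineages are rank-prefixed, semicolon-separated strings (e.g.
#' `"d__Bacteria;p__...;g__Prevotella"`). Features with no assignment at the
#' requested rank pool into an `"unclassified <parent>"` group keyed on the
#' deepest assigned rank, so proportion mass is preserved rather than dropped.
#'
#' @param taxonomy named character vector mapping feature -> lineage string.
#' @param rank single rank prefix letter, default `"g"` (genus).
#' @return Named character vector mapping feature -> group label, suitable for
#'   [aggregate_features()].
#' @export
taxonomy_grouping <- function(taxonomy, rank = "g") {
  prefix <- paste0(rank, "__")
  vapply(names(taxonomy), function(f) {
    parts <- trimws(strsplit(taxonomy[[f]], ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    hit <- parts[startsWith(parts, prefix)]
    hit <- hit[nzchar(sub(prefix, "", hit, fixed = TRUE))]
    if (length(hit)) {
      sub(prefix, "", hit[1], fixed = TRUE)
    } else {
      assigned <- parts[nzchar(sub("^[a-z]__", "", parts))]
      parent <- if (length(assigned)) assigned[length(assigned)] else "root"
      paste("unclassified", sub("^[a-z]__", "", parent))
    }
  }, character(1))
}

#' Rarefy a counts-mode feature table to a common depth
#'
#' For each sample, exactly `depth` reads are drawn uniformly without
#' replacement from that sample's reads (a multivariate hypergeometric draw
#' over features). Samples are processed in lexicographic sample-id order from
#' a single seeded generator, so the result is reproducible for a fixed seed
#' regardless of input row order.
#'
#' @param table a counts-mode [feature_table()].
#' @param depth target number of reads per sample; must not exceed any
#'   sample's total.
#' @param seed integer seed.
#' @return A counts-mode `feature_table` in which every sample sums to `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(inherits(table, "feature_table"))
  if (table$mode != "counts") stop("rarefy requires a counts-mode table", call. = FALSE)
  depth <- check_count(depth, "depth")
  totals <- rowSums(table$values)
  under <- totals < depth
  if (any(under)) {
    stop("sample(s) below requested depth ", depth, ": ",
         paste(rownames(table$values)[under], collapse = ", "), call. = FALSE)
  }
  out <- table
  with_seed(seed, {
    for (sid in sort(rownames(table$values))) {
      counts <- table$values[sid, ]
      out$values[sid, ] <- rhyper_vector(counts, depth)
    }
  })
  out
}

# Sequential conditional hypergeometric draw: a multivariate hypergeometric
# sample of size `depth` from urn contents `counts`, feature by feature.
rhyper_vector <- function(counts, depth) {
  n_feat <- length(counts)
  draw <- numeric(n_feat)
  remaining <- sum(counts)
  k <- depth
  for (j in seq_len(n_feat)) {
    if (k == 0) break
    cj <- counts[j]
    if (remaining == cj) {
      draw[j] <- k
      k <- 0
      break
    }
    x <- stats::rhyper(1, m = cj, n = remaining - cj, k = k)
    draw[j] <- x
    k <- k - x
    remaining <- remaining - cj
  }
  draw
}
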