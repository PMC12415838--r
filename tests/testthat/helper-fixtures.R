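# Small in-code fixtures shared across the suite.

# Balanced design: n_materials x 2 treatments x n_reps replicates.
make_design <- function(n_materials = 1, n_reps = 2) {
  grid <- expand.grid(replicate = seq_len(n_reps),
                      treatment = c("dried", "frozen"),
                      material = sprintf("mat%d", seq_len(n_materials)),
                      stringsAsFactors = FALSE)
  sample_design(sprintf("%s_%s_%d", grid$material, grid$treatment,
                        grid$replicate),
                grid$material, grid$treatment, grid$replicate)
}

# Metric table from per-(material, treatment) value lists, e.g.
# make_metric(list(A = list(dried = c(2, 4), frozen = c(1, 3)))).
make_metric <- function(values, metric = "yield") {
  rows <- list()
  for (m in names(values)) {
    for (tr in names(values[[m]])) {
      v <- values[[m]][[tr]]
      rows[[length(rows) + 1]] <- data.frame(
        material = m, treatment = tr, value = v,
        sample_id = sprintf("%s_%s_%d", m, tr, seq_along(v)),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  d <- sample_design(df$sample_id, df$material, df$treatment)
  metric_table(d, matrix(df$value, ncol = 1,
                         dimnames = list(df$sample_id, metric)))
}

# Proportions-mode feature table from a row-wise matrix (one design row per
# matrix row).
make_props <- function(mat, design, kind = "OTU") {
  rownames(mat) <- design$sample_id
  feature_table(design, mat, kind = kind, mode = "proportions")
}

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# Exhaustive ratio-of-means p-value: enumerate every within-material
# assignment of values to the dried/frozen slots (independent brute force of
# the location-test null).
exact_location_p <- function(per_material_values, obs_extreme) {
  splits <- lapply(per_material_values, function(v) {
    n <- length(v$dried) + length(v$frozen)
    utils::combn(n, length(v$dried), simplify = FALSE)
  })
  grid <- expand.grid(lapply(splits, seq_along))
  stats <- apply(grid, 1, function(choice) {
    rhos <- mapply(function(v, s, k) {
      all_vals <- c(v$dried, v$frozen)
      idx <- s[[k]]
      mean(all_vals[idx]) / mean(all_vals[-idx])
    }, per_material_values, splits, choice)
    mean(rhos)
  })
  mean(abs(stats - 1) >= obs_extreme)
}
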