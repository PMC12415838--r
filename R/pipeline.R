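# Result TSVs carry a commented provenance header (stage, seed, inputs) so a
# rerun with the same config is byte-identical; timestamps are deliberately
# omitted.
write_result_tsv <- function(df, path, header) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param analyses character vector of stages to run, in any order; available:
#'   `"simulate"`, `"location_test"`, `"agreement"`, `"betadiv"`,
#'   `"ordinate"`, `"permanova"`. Dependencies are resolved automatically
#'   (e.g. `"permanova"` computes distances if `"betadiv"` products are
#'   missing).
#' @param seed master seed; every stage derives its own child seed from it via
#'   [derive_seed()], so adding stages never perturbs other stages' draws.
#' @param n_permutations permutations for every permutation test.
#' @param threshold abundance filter for agreement tests (1e-4 for taxa,
#'   1e-5 for genes).
#' @param metric_table_path optional TSV of scalar success metrics (see
#'   [read_metric_table()]); if absent and `"simulate"` is requested, the
#'   simulated table is used.
#' @param metric_schema schema map for [read_metric_table()].
#' @param feature_table_path optional feature-table TSV; as above.
#' @param feature_kind,feature_orientation options for [read_feature_table()].
#' @param simulate_config a [synthetic_config()] for the `"simulate"` stage.
#' @param distance one of `"bray_curtis"`, `"weighted_jaccard"`.
#' @param rarefy_depth optional rarefaction depth applied to a counts-mode
#'   feature table before analysis (one seeded draw).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       analyses = c("simulate", "location_test", "agreement",
                                    "betadiv", "ordinate", "permanova"),
                       seed = 1,
                       n_permutations = 10000,
                       threshold = 1e-4,
                       metric_table_path = NULL,
                       metric_schema = list(sample = "sample",
                                            material = "material",
                                            treatment = "treatment"),
                       feature_table_path = NULL,
                       feature_kind = "OTU",
                       feature_orientation = "samples_in_rows",
                       simulate_config = synthetic_config(seed = seed),
                       distance = c("bray_curtis", "weighted_jaccard"),
                       rarefy_depth = NULL) {
  structure(
    list(out_dir = out_dir, analyses = analyses, seed = as.integer(seed),
         n_permutations = check_count(n_permutations, "n_permutations"),
         threshold = as.numeric(threshold),
         metric_table_path = metric_table_path,
         metric_schema = metric_schema,
         feature_table_path = feature_table_path,
         feature_kind = feature_kind,
         feature_orientation = feature_orientation,
         simulate_config = simulate_config,
         distance = match.arg(distance),
         rarefy_depth = rarefy_depth),
    class = "run_config")
}

#' Run the full paired-treatment analysis pipeline
#'
#' Executes the requested stages in dependency order, writing every result as
#' a TSV with a commented provenance header, plus a manifest recording input
#' checksums, seeds and per-stage status. A failed stage is recorded in the
#' manifest and independent stages still run. Rerunning with the same config
#' reproduces all stochastic outputs byte-identically.
#'
#' @param config a [run_config()].
#' @return The run manifest (data frame with columns `stage`, `status`,
#'   `detail`, `output`, `seed`), invisibly written to
#'   `manifest.tsv` in the output directory. The manifest carries an
#'   `ok` attribute that is `FALSE` if any stage failed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(), status = character(),
                         detail = character(), output = character(),
                         seed = integer(), stringsAsFactors = FALSE)
  note <- function(stage, status, detail = "", output = "", seed = NA_integer_) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, status = status, detail = detail, output = output,
      seed = seed, stringsAsFactors = FALSE))
  }
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      note(stage, "failed", conditionMessage(res))
      FALSE
    } else {
      TRUE
    }
  }

  # --- inputs -------------------------------------------------------------
  load_metric_table <- function() {
    if (!is.null(state$metric_table)) return(state$metric_table)
    if (!is.null(config$metric_table_path)) {
      if (!file.exists(config$metric_table_path)) {
        stop("metric table not found: ", config$metric_table_path, call. = FALSE)
      }
      note("input_metric_table", "ok",
           detail = unname(tools::md5sum(config$metric_table_path)),
           output = config$metric_table_path)
      state$metric_table <- read_metric_table(config$metric_table_path,
                                              config$metric_schema)
    } else if ("simulate" %in% config$analyses) {
      state$metric_table <- state$sim_metrics$table
    } else {
      stop("no metric table available (no path, no simulate stage)", call. = FALSE)
    }
    state$metric_table
  }

  load_feature_table <- function() {
    if (!is.null(state$feature_table)) return(state$feature_table)
    if (!is.null(config$feature_table_path)) {
      if (!file.exists(config$feature_table_path)) {
        stop("feature table not found: ", config$feature_table_path, call. = FALSE)
      }
      note("input_feature_table", "ok",
           detail = unname(tools::md5sum(config$feature_table_path)),
           output = config$feature_table_path)
      design <- load_metric_table()$design
      ft <- read_feature_table(config$feature_table_path, design,
                               kind = config$feature_kind,
                               orientation = config$feature_orientation)
    } else if ("simulate" %in% config$analyses) {
      ft <- state$sim_features$table
    } else {
      stop("no feature table available (no path, no simulate stage)", call. = FALSE)
    }
    if (ft$mode == "counts") {
      if (!is.null(config$rarefy_depth)) {
        ft <- rarefy(ft, config$rarefy_depth,
                     seed = derive_seed(config$seed, "rarefy"))
      }
      ft <- to_proportions(ft)
    }
    state$feature_table <- ft
    ft
  }

  get_distances <- function() {
    if (is.null(state$distances)) {
      ft <- load_feature_table()
      state$distances <- switch(config$distance,
                                bray_curtis = bray_curtis(ft),
                                weighted_jaccard = weighted_jaccard(ft))
    }
    state$distances
  }

  # --- stages -------------------------------------------------------------
  if ("simulate" %in% config$analyses) {
    run_stage("simulate", function() {
      state$sim_metrics <- simulate_metric_table(config$simulate_config)
      state$sim_features <- simulate_feature_table(config$simulate_config)
      mpath <- file.path(config$out_dir, "simulated_metrics.tsv")
      fpath <- file.path(config$out_dir, "simulated_features.tsv")
      write_metric_table(state$sim_metrics$table, mpath)
      write_feature_table(state$sim_features$table, fpath)
      write_ground_truth(state$sim_metrics$truth,
                         file.path(config$out_dir, "simulated_metrics.truth.tsv"))
      write_ground_truth(state$sim_features$truth,
                         file.path(config$out_dir, "simulated_features.truth.tsv"))
      note("simulate", "ok", output = paste(mpath, fpath, sep = ";"),
           seed = config$simulate_config$seed)
    })
  }

  if ("location_test" %in% config$analyses) {
    run_stage("location_test", function() {
      mt <- load_metric_table()
      res <- location_test_all(mt, n_permutations = config$n_permutations,
                               seed = config$seed)
      path <- file.path(config$out_dir, "location_tests.tsv")
      write_result_tsv(res, path, sprintf(
        "ratio-of-means location tests; master_seed=%d; n_permutations=%d",
        config$seed, config$n_permutations))
      note("location_test", "ok", output = path, seed = config$seed)
    })
  }

  if ("agreement" %in% config$analyses) {
    run_stage("agreement", function() {
      ft <- load_feature_table()
      rows <- lapply(sort(unique(ft$design$material)), function(m) {
        sd_m <- derive_seed(config$seed, "agreement", m)
        r <- agreement_test(ft, m, threshold = config$threshold,
                            n_permutations = config$n_permutations, seed = sd_m)
        data.frame(material = m, kind = r$feature_kind,
                   r_squared = r$r_squared, n = r$n_features_retained,
                   p_value = r$p_value, threshold = r$abundance_threshold,
                   seed = r$seed, stringsAsFactors = FALSE)
      })
      res <- do.call(rbind, rows)
      path <- file.path(config$out_dir, "agreement.tsv")
      write_result_tsv(res, path, sprintf(
        "compositional agreement tests; master_seed=%d; n_permutations=%d",
        config$seed, config$n_permutations))
      note("agreement", "ok", output = path, seed = config$seed)
    })
  }

  if ("betadiv" %in% config$analyses || "ordinate" %in% config$analyses ||
      "permanova" %in% config$analyses) {
    run_stage("betadiv", function() {
      D <- get_distances()
      path <- file.path(config$out_dir,
                        paste0("distances_", config$distance, ".tsv"))
      df <- data.frame(sample_id = D$sample_ids, D$values,
                       check.names = FALSE, stringsAsFactors = FALSE)
      write_result_tsv(df, path, sprintf("%s dissimilarities", config$distance))
      note("betadiv", "ok", output = path)
    })
  }

  if ("ordinate" %in% config$analyses) {
    run_stage("ordinate", function() {
      D <- get_distances()
      sd_o <- derive_seed(config$seed, "ordinate")
      ord <- mmds(D, dims = 2, seed = sd_o)
      path <- file.path(config$out_dir, "mmds_coordinates.tsv")
      df <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, stringsAsFactors = FALSE)
      write_result_tsv(df, path, sprintf(
        "MMDS embedding; stress1=%.6g; seed=%d; converged=%s",
        ord$stress, sd_o, ord$converged))
      note("ordinate", "ok", output = path, seed = sd_o)
    })
  }

  if ("permanova" %in% config$analyses) {
    run_stage("permanova", function() {
      D <- get_distances()
      design <- load_feature_table()$design
      rows <- lapply(sort(unique(design$material)), function(m) {
        sd_m <- derive_seed(config$seed, "permanova", m)
        r <- permanova(D, design, m, n_permutations = config$n_permutations,
                       seed = sd_m)
        data.frame(material = m, metric = r$metric_name,
                   pseudo_F = r$pseudo_F, r_squared = r$r_squared_between,
                   p_value = r$p_value, seed = r$seed,
                   stringsAsFactors = FALSE)
      })
      res <- do.call(rbind, rows)
      path <- file.path(config$out_dir, "permanova.tsv")
      write_result_tsv(res, path, sprintf(
        "per-material PERMANOVA; master_seed=%d; n_permutations=%d",
        config$seed, config$n_permutations))
      note("permanova", "ok", output = path, seed = config$seed)
    })
  }

  manifest_path <- file.path(config$out_dir, "manifest.tsv")
  write_result_tsv(manifest, manifest_path, sprintf(
    "run manifest; master_seed=%d", config$seed))
  attr(manifest, "ok") <- !any(manifest$status == "failed")
  invisible(manifest)
}
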