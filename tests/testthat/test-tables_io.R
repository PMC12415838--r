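test_that("metric table TSV parsing binds schema columns and flags problems", {
  tf <- write_tsv_lines(c("sample\tmaterial\ttreatment\tyield",
                          "s1\tf1\tdried\t10",
                          "s2\tf1\tfrozen\t5"))
  mt <- read_metric_table(tf)
  expect_s3_class(mt, "metric_table")
  expect_equal(nrow(mt$metrics), 2)
  expect_equal(colnames(mt$metrics), "yield")
  expect_equal(unname(mt$metrics[, "yield"]), c(10, 5))

  # non-numeric metric cells become explicit missing values
  tf2 <- write_tsv_lines(c("sample\tmaterial\ttreatment\tyield",
                           "s1\tf1\tdried\tlow",
                           "s2\tf1\tfrozen\t5"))
  mt2 <- read_metric_table(tf2)
  expect_true(is.na(mt2$metrics["s1", "yield"]))

  dup <- write_tsv_lines(c("sample\tmaterial\ttreatment\tyield",
                           "s1\tf1\tdried\t10",
                           "s1\tf1\tfrozen\t5"))
  expect_error(read_metric_table(dup), "duplicate sample_id")

  badt <- write_tsv_lines(c("sample\tmaterial\ttreatment\tyield",
                            "s1\tf1\tdried\t10",
                            "s2\tf1\tthawed\t5"))
  expect_error(read_metric_table(badt), "row\\(s\\) 2")
})

test_that("a full-design 60-row table parses into 6 materials x 2 x 5", {
  grid <- expand.grid(rep = 1:5, trt = c("dried", "frozen"),
                      mat = c(paste0("faeces", 1:3), paste0("soil", 1:3)),
                      stringsAsFactors = FALSE)
  lines <- c("sample\tmaterial\ttreatment\tyield",
             sprintf("%s_%s_%d\t%s\t%s\t%g", grid$mat, grid$trt, grid$rep,
                     grid$mat, grid$trt, seq_len(60)))
  mt <- read_metric_table(write_tsv_lines(lines))
  expect_equal(nrow(mt$design), 60)
  expect_equal(length(unique(mt$design$material)), 6)
  tab <- table(mt$design$material, mt$design$treatment)
  expect_true(all(tab == 5))
})

test_that("feature table reading is orientation-symmetric and validates input", {
  d <- make_design(1, 1)  # 2 samples
  m <- rbind(c(3, 0, 2), c(1, 4, 5))
  rownames(m) <- d$sample_id
  colnames(m) <- c("otu1", "otu2", "otu3")
  by_rows <- write_tsv_lines(c(
    paste(c("sample_id", colnames(m)), collapse = "\t"),
    apply(cbind(rownames(m), m), 1, paste, collapse = "\t")))
  tm <- t(m)
  by_cols <- write_tsv_lines(c(
    paste(c("feature_id", colnames(tm)), collapse = "\t"),
    apply(cbind(rownames(tm), tm), 1, paste, collapse = "\t")))

  ft1 <- read_feature_table(by_rows, d, orientation = "samples_in_rows")
  ft2 <- read_feature_table(by_cols, d, orientation = "features_in_rows")
  expect_equal(ft1$mode, "counts")
  expect_identical(ft1$values, ft2$values)

  # BIOM-TSV flavour with a leading "#OTU ID" header line
  biom <- write_tsv_lines(c(
    paste(c("#OTU ID", colnames(tm)), collapse = "\t"),
    apply(cbind(rownames(tm), tm), 1, paste, collapse = "\t")))
  ft3 <- read_feature_table(biom, d, orientation = "features_in_rows")
  expect_identical(ft3$values, ft1$values)

  neg <- write_tsv_lines(c("sample_id\totu1\totu2",
                           paste(d$sample_id[1], "-1", "2", sep = "\t"),
                           paste(d$sample_id[2], "1", "2", sep = "\t")))
  expect_error(read_feature_table(neg, d), "negative")

  bad_prop <- write_tsv_lines(c("sample_id\totu1\totu2",
                                paste(d$sample_id[1], "0.5", "0.4", sep = "\t"),
                                paste(d$sample_id[2], "0.5", "0.5", sep = "\t")))
  expect_error(read_feature_table(bad_prop, d), "sum to 1")
})

test_that("read-write-read round trips reproduce tables in both orientations", {
  d <- make_design(2, 2)
  set.seed(11)
  counts <- matrix(rpois(8 * 5, 40), 8, 5,
                   dimnames = list(d$sample_id, paste0("otu", 1:5)))
  ft <- feature_table(d, counts, mode = "counts")
  for (orient in c("samples_in_rows", "features_in_rows")) {
    tf <- tempfile(fileext = ".tsv")
    write_feature_table(ft, tf, orientation = orient)
    back <- read_feature_table(tf, d, orientation = orient)
    expect_identical(back$values, ft$values)
  }
  mtf <- tempfile(fileext = ".tsv")
  mt <- metric_table(d, matrix(rnorm(8, 100, 5), ncol = 1,
                               dimnames = list(d$sample_id, "yield")))
  write_metric_table(mt, mtf)
  mt2 <- read_metric_table(mtf,
                           schema = list(sample = "sample",
                                         material = "material",
                                         treatment = "treatment",
                                         replicate = "replicate"))
  expect_equal(mt2$metrics, mt$metrics)
  expect_equal(as.data.frame(mt2$design), as.data.frame(mt$design))
})

test_that("to_proportions normalises rows, keeps zeros and is idempotent", {
  d <- make_design(1, 1)
  ft <- feature_table(d, rbind(c(2, 2, 0), c(1, 1, 1)), mode = "counts")
  p <- to_proportions(ft)
  expect_equal(unname(p$values[1, ]), c(0.5, 0.5, 0))
  expect_equal(unname(p$values[2, ]), rep(1 / 3, 3))
  expect_identical(to_proportions(p), p)

  zero <- feature_table(d, rbind(c(0, 0, 0), c(1, 1, 1)), mode = "counts")
  expect_error(to_proportions(zero), d$sample_id[1])
})

test_that("large simulated tables normalise to exact unit row sums", {
  cfg <- synthetic_config(n_features = 800, seed = 42)
  sim <- simulate_feature_table(cfg)
  p <- to_proportions(sim$table)
  expect_equal(nrow(p$values), 60)
  expect_true(all(abs(rowSums(p$values) - 1) < 1e-12))
})

test_that("aggregate_features sums members, honours omit-list, conserves totals", {
  d <- make_design(1, 1)
  ft <- make_props(rbind(c(0.2, 0.3, 0.5), c(0.1, 0.1, 0.8)), d)
  grouping <- c(feature1 = "G1", feature2 = "G1", feature3 = "G2")
  agg <- aggregate_features(ft, grouping, new_kind = "KEGG_C")
  expect_equal(unname(agg$values[1, c("G1", "G2")]), c(0.5, 0.5))

  # omit before renormalisation: remaining group renormalises to 1
  agg2 <- aggregate_features(ft, grouping, new_kind = "KEGG_C", omit = "G2")
  expect_equal(unname(agg2$values[, "G1"]), c(1, 1))

  # counts mode conserves per-sample totals with empty omit-list
  ftc <- feature_table(d, rbind(c(2, 3, 5), c(1, 1, 8)), mode = "counts")
  aggc <- aggregate_features(ftc, grouping, new_kind = "KEGG_C")
  expect_equal(rowSums(aggc$values), rowSums(ftc$values))

  dup_map <- data.frame(feature = c("feature1", "feature1"),
                        group = c("G1", "G2"))
  expect_error(aggregate_features(ft, dup_map), "two groups")
})

test_that("taxonomy grouping extracts genus and pools unassigned by parent", {
  tax <- c(a = "d__Bacteria;f__Lachnospiraceae;g__Blautia",
           b = "d__Bacteria;f__Lachnospiraceae;g__",
           c = "d__Bacteria;f__Ruminococcaceae")
  g <- taxonomy_grouping(tax, rank = "g")
  expect_equal(unname(g["a"]), "Blautia")
  expect_equal(unname(g["b"]), "unclassified Lachnospiraceae")
  expect_equal(unname(g["c"]), "unclassified Ruminococcaceae")
})

test_that("rarefy hits forced outcomes and is seed-reproducible", {
  d <- make_design(1, 1)
  ft <- feature_table(d, rbind(c(5, 0), c(1000000, 0)), mode = "counts")
  r <- rarefy(ft, 5, seed = 1)
  expect_equal(unname(r$values[1, ]), c(5, 0))
  expect_equal(unname(r$values[2, ]), c(5, 0))

  ft2 <- feature_table(d, rbind(c(40, 60), c(10, 90)), mode = "counts")
  a <- rarefy(ft2, 30, seed = 7)
  b <- rarefy(ft2, 30, seed = 7)
  expect_identical(a$values, b$values)
  expect_true(all(rowSums(a$values) == 30))
  expect_false(identical(a$values, rarefy(ft2, 30, seed = 8)$values))

  expect_error(rarefy(ft2, 200, seed = 1), "below requested depth")
})

test_that("rarefaction marginals follow the multivariate hypergeometric law", {
  d <- sample_design("s1", "m", "dried")
  ft <- feature_table(d, matrix(c(500, 500), 1, 2,
                                dimnames = list("s1", c("f1", "f2"))),
                      mode = "counts")
  n_draws <- 6000
  firsts <- vapply(seq_len(n_draws), function(s)
    rarefy(ft, 100, seed = s)$values[1, 1], numeric(1))
  # closed-form hypergeometric moments: N = 1000, K = 500, k = 100
  expect_equal(mean(firsts), 50, tolerance = 0.01)
  v_expected <- 100 * 0.5 * 0.5 * (1000 - 100) / 999
  expect_equal(var(firsts), v_expected, tolerance = 0.06)
  # chi-square goodness of fit against dhyper at alpha = 0.01
  support <- 30:70
  probs <- dhyper(support, 500, 500, 100)
  obs <- tabulate(factor(pmin(pmax(firsts, 30), 70), levels = support),
                  nbins = length(support))
  keep <- probs * n_draws >= 5
  gof <- chisq.test(obs[keep], p = probs[keep] / sum(probs[keep]))
  expect_gt(gof$p.value, 0.01)
})
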