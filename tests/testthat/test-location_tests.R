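test_that("ratio statistic matches direct arithmetic and handles errors", {
  mt <- make_metric(list(A = list(dried = c(2, 4), frozen = c(1, 3)),
                         B = list(dried = c(10, 10), frozen = c(5, 5))))
  rs <- ratio_statistic(mt, "yield")
  expect_equal(unname(rs$per_material["A"]), 1.5)
  expect_equal(unname(rs$per_material["B"]), 2)
  expect_equal(rs$overall, 1.75)
  expect_equal(rs$n, 8)

  ident <- make_metric(list(A = list(dried = c(3, 7), frozen = c(3, 7))))
  expect_equal(ratio_statistic(ident, "yield")$overall, 1)

  zero <- make_metric(list(A = list(dried = c(1, 2), frozen = c(0, 0))))
  expect_error(ratio_statistic(zero, "yield"), "material 'A'")
  expect_error(ratio_statistic(mt, "nope"), "unknown metric")
})

test_that("overall ratio equals the mean of per-material ratios", {
  set.seed(21)
  cfg <- synthetic_config(metric_effect_ratios = c(yield = 1.3), seed = 21)
  res <- location_test(simulate_metric_table(cfg)$table, "yield",
                       n_permutations = 100, seed = 1)
  expect_equal(res$overall_ratio, mean(res$per_material_ratio),
               tolerance = 1e-12)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("degenerate no-variation tables give rho = 1 and p = 1", {
  mt <- make_metric(list(A = list(dried = c(5, 5), frozen = c(5, 5)),
                         B = list(dried = c(2, 2), frozen = c(2, 2))))
  res <- location_test(mt, "yield", n_permutations = 500, seed = 3)
  expect_equal(res$overall_ratio, 1)
  expect_equal(res$p_value, 1)
})

test_that("Monte-Carlo p matches exhaustive enumeration on a tiny instance", {
  vals <- list(A = list(dried = c(3, 4), frozen = c(1, 2)))
  mt <- make_metric(vals)
  obs <- ratio_statistic(mt, "yield")$overall
  p_exact <- exact_location_p(vals, abs(obs - 1))  # C(4,2) = 6 splits
  n_perm <- 100000
  res <- location_test(mt, "yield", n_permutations = n_perm, seed = 17)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1e-12)
})

test_that("two-material enumeration agrees with the Monte-Carlo null too", {
  vals <- list(A = list(dried = c(3, 9), frozen = c(2, 5)),
               B = list(dried = c(8, 4), frozen = c(7, 6)))
  mt <- make_metric(vals)
  obs <- ratio_statistic(mt, "yield")$overall
  p_exact <- exact_location_p(vals, abs(obs - 1))  # 6 x 6 = 36 joint splits
  n_perm <- 50000
  res <- location_test(mt, "yield", n_permutations = n_perm, seed = 23)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1e-12)
})

test_that("p-value is invariant to metric rescaling and order-preserving relabeling", {
  vals <- list(A = list(dried = c(3, 9, 6), frozen = c(2, 5, 4)),
               B = list(dried = c(8, 4, 5), frozen = c(7, 6, 9)))
  mt <- make_metric(vals)
  res <- location_test(mt, "yield", n_permutations = 2000, seed = 5)
  scaled <- make_metric(lapply(vals, function(v) lapply(v, `*`, 137.5)))
  res_scaled <- location_test(scaled, "yield", n_permutations = 2000, seed = 5)
  expect_identical(res$p_value, res_scaled$p_value)
  expect_equal(res$per_material_ratio, res_scaled$per_material_ratio,
               tolerance = 1e-12, ignore_attr = TRUE)
  # renaming that preserves lexicographic material order reuses the same draws
  renamed <- make_metric(setNames(vals, c("mat01", "mat02")))
  res_renamed <- location_test(renamed, "yield", n_permutations = 2000, seed = 5)
  expect_identical(res$p_value, res_renamed$p_value)
})

test_that("missing metric values are excluded and reported in n", {
  mt <- make_metric(list(A = list(dried = c(2, 4, 6), frozen = c(1, 3, 5))))
  mt$metrics[1, "yield"] <- NA
  res <- location_test(mt, "yield", n_permutations = 200, seed = 1)
  expect_equal(res$n_samples, 5)
  rs <- ratio_statistic(mt, "yield")
  expect_equal(unname(rs$per_material["A"]), mean(c(4, 6)) / mean(c(1, 3, 5)))
})

test_that("few permutations trigger a recorded warning and add_one estimator shifts p", {
  mt <- make_metric(list(A = list(dried = c(3, 4), frozen = c(1, 2))))
  res <- location_test(mt, "yield", n_permutations = 50, seed = 2)
  expect_true(length(res$warnings) > 0)
  r1 <- location_test(mt, "yield", n_permutations = 400, seed = 2)
  r2 <- location_test(mt, "yield", n_permutations = 400, seed = 2,
                      estimator = "add_one")
  expect_equal(r2$p_value, (r1$p_value * 400 + 1) / 401)
})

test_that("Welch group statistics match the hand oracle and exact enumeration", {
  d <- sample_design(paste0("s", 1:4), rep("m", 4),
                     c("dried", "dried", "frozen", "frozen"))
  ft <- make_props(cbind(g1 = c(0.1, 0.2, 0.3, 0.4),
                         g2 = c(0.9, 0.8, 0.7, 0.6)), d)
  res <- welch_group_test(ft, "m", n_permutations = 50000, seed = 11)
  expect_equal(res$groups$statistic[1], -0.2 / sqrt(0.005 / 2 + 0.005 / 2),
               tolerance = 1e-12)
  # exact p over the C(4,2) = 6 label splits
  splits <- combn(4, 2, simplify = FALSE)
  t_all <- vapply(splits, function(idx) {
    x <- ft$values[idx, "g1"]; y <- ft$values[-idx, "g1"]
    (mean(x) - mean(y)) / sqrt(var(x) / 2 + var(y) / 2)
  }, numeric(1))
  p_exact <- mean(abs(t_all) >= abs(res$groups$statistic[1]))
  expect_equal(p_exact, 2 / 6)
  se <- sqrt(p_exact * (1 - p_exact) / 50000)
  expect_lt(abs(res$groups$p_value[1] - p_exact), 3 * se)
  # Bonferroni across the 2 groups tested in the material
  expect_equal(res$groups$p_adjusted,
               pmin(1, res$groups$p_value * 2))
})

test_that("identical proportions give t = 0 and p = 1; zero-variance shifts flag infinite", {
  d <- make_design(1, 2)
  flat <- make_props(matrix(rep(c(0.4, 0.6), each = 4), 4, 2), d)
  res <- welch_group_test(flat, "mat1", n_permutations = 200, seed = 1)
  expect_true(all(res$groups$statistic == 0))
  expect_true(all(res$groups$p_value == 1))

  shifted <- make_props(cbind(c(0.2, 0.2, 0.4, 0.4), c(0.8, 0.8, 0.6, 0.6)), d)
  res2 <- welch_group_test(shifted, "mat1", n_permutations = 2000, seed = 1)
  expect_true(all(is.infinite(res2$groups$statistic)))
  # minimum attainable p: only the 2 of C(4,2)=6 splits separating the
  # constant pairs reproduce an infinite statistic
  expect_equal(res2$groups$p_value[1], 2 / 6, tolerance = 0.05)
})

test_that("Bonferroni keeps family-wise error controlled under the null", {
  # 10 null groups per simulation; FWER after correction should be <= alpha
  n_sims <- 120
  fwe <- vapply(seq_len(n_sims), function(s) {
    cfg <- synthetic_config(n_materials = 1, n_features = 10,
                            treatment_effect_sd = 0,
                            within_material_overdispersion = 150,
                            depth_mean = 4000, seed = s)
    p <- to_proportions(simulate_feature_table(cfg)$table)
    res <- welch_group_test(p, "material1", n_permutations = 199,
                            seed = s + 1000)
    any(res$groups$p_adjusted < 0.05)
  }, logical(1))
  expect_lte(mean(fwe), 0.05 + 3 * sqrt(0.05 * 0.95 / n_sims))
  # and adjusted p never drops below raw p
  cfg <- synthetic_config(n_materials = 1, n_features = 10, seed = 77)
  p <- to_proportions(simulate_feature_table(cfg)$table)
  res <- welch_group_test(p, "material1", n_permutations = 199, seed = 7)
  expect_true(all(res$groups$p_adjusted >= res$groups$p_value))
})
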