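# Association battery: winsorization, residualization, partial correlation
# tests, Holm, elastic net, cross-sample prediction, overlap, handedness.

test_that("winsorization replaces values beyond mean +/- 3 IQR by the bound", {
  set.seed(80)
  x <- rnorm(200)
  iqr <- quantile(x, 0.75) - quantile(x, 0.25)
  x[1] <- mean(x) + 10 * iqr
  m <- mean(x)
  q <- quantile(x, c(0.25, 0.75))
  out <- winsorize(x)
  expect_equal(out[1], unname(m + 3 * (q[2] - q[1])))
  # in-bounds values untouched
  y <- rnorm(50)
  expect_identical(winsorize(y)[abs(y - mean(y)) < 1], y[abs(y - mean(y)) < 1])
  # count of replacements equals count outside bounds (exhaustive oracle)
  set.seed(81)
  z <- rt(500, df = 2)
  qz <- quantile(z, c(0.25, 0.75))
  lo <- mean(z) - 3 * (qz[2] - qz[1]); hi <- mean(z) + 3 * (qz[2] - qz[1])
  expect_identical(sum(winsorize(z) != z), sum(z < lo | z > hi))
  # identical input returns unchanged
  expect_identical(winsorize(rep(2, 10)), rep(2, 10))
})

test_that("residualization produces residuals orthogonal to the design", {
  design <- rand_design(200, seed = 82)
  set.seed(83)
  y <- rnorm(200)
  r <- residualize(y, design)
  expect_true(all(abs(crossprod(cbind(1, design), r)) < 1e-8 *
                    max(abs(crossprod(cbind(1, design))))))
  expect_true(all(abs(crossprod(scale(design, scale = FALSE), r)) < 1e-6))
  # y linear in age leaves near-zero residuals
  y2 <- 3 + 0.5 * design[, "age"]
  expect_lt(max(abs(residualize(y2, design))), 1e-10)
  # rank-deficient designs are reported
  bad <- cbind(design, age_copy = design[, "age"])
  expect_error(residualize(y, bad), "age_copy")
})

test_that("a metric identical to g has partial correlation one", {
  design <- rand_design(100, seed = 84)
  set.seed(85)
  g <- rnorm(100)
  res <- partial_correlation_test(g, g, design)
  expect_equal(res$r, 1)
  expect_identical(res$df, 100L - 2L - 8L)
})

test_that("partial correlation recovers a planted effect net of covariates", {
  design <- rand_design(500, seed = 86)
  set.seed(87)
  confound_part <- design[, "age"] / sd(design[, "age"])
  lat <- rnorm(500)
  g <- 0.3 * lat + sqrt(1 - 0.09) * rnorm(500) + 0.5 * confound_part
  metric <- lat + 0.8 * confound_part
  res <- partial_correlation_test(g, metric, design)
  se <- 1 / sqrt(500 - 3)
  expect_lt(abs(atanh(res$r) - atanh(0.3)), 3 * se)
})

test_that("the partial-correlation test keeps its nominal size", {
  design <- rand_design(120, seed = 88)
  set.seed(89)
  pvals <- replicate(400, {
    partial_correlation_test(rnorm(120), rnorm(120), design)$p_raw
  })
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 0.035)
})

test_that("Holm adjustment follows the step-down rule", {
  expect_identical(holm_adjust(0.03), 0.03)
  # hand application: sorted (0.01, 0.03, 0.04) -> (0.03, 0.06, cummax ->
  # 0.06); mapped back to the input order
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(90)
  p <- runif(10)
  expect_true(all(holm_adjust(p) >= p))
  expect_error(holm_adjust(c(0.2, 1.3)), class = "omstnet_data_error")
})

test_that("elastic net recovers a strong single-node signal and kills noise", {
  design <- rand_design(300, seed = 91)
  hits <- 0L
  for (s in 1:5) {
    set.seed(600 + s)
    X <- matrix(rnorm(300 * 60), 300)
    y <- 0.8 * X[, 5] + rnorm(300)
    fit <- elastic_net_select(X, y, design, seed = s)
    hits <- hits + (5L %in% fit$selected)
  }
  expect_gte(hits, 4L)

  # under the null the conservative one-SE penalty keeps the support
  # near-empty; the CV-MSE minimizer trades that sparsity for sensitivity
  # and can admit noise nodes, which is why both rules are exposed
  false_pos <- vapply(1:8, function(s) {
    set.seed(640 + s)
    X <- matrix(rnorm(300 * 60), 300)
    y <- rnorm(300)
    length(elastic_net_select(X, y, design, seed = s,
                              lambda_rule = "1se")$selected)
  }, numeric(1))
  expect_lte(mean(false_pos), 2)

  # beta = 0 at the top of the penalty grid
  set.seed(92)
  X <- matrix(rnorm(200 * 30), 200)
  y <- rnorm(200)
  fit0 <- elastic_net_select(X, y, design[1:200, ], seed = 1)
  expect_true(all(abs(fit0$fit$glmnet.fit$beta[, 1]) < 1e-12))
})

test_that("elastic-net fits are reproducible and tidy-accessible", {
  design <- rand_design(100, seed = 93)
  set.seed(94)
  X <- matrix(rnorm(100 * 20), 100)
  y <- 0.6 * X[, 3] + rnorm(100)
  f1 <- elastic_net_select(X, y, design, seed = 7)
  f2 <- elastic_net_select(X, y, design, seed = 7)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$selected, unname(which(f1$beta != 0)))
  td <- tidy(f1)
  expect_identical(td$term[td$selected], names(f1$beta)[f1$selected])
  gl <- glance(f1)
  expect_identical(gl$n_selected, length(f1$selected))
})

test_that("cross-sample prediction handles perfect, null and empty predictor sets", {
  design <- rand_design(80, seed = 95)
  set.seed(96)
  g <- rnorm(80)
  X <- cbind(g, matrix(rnorm(80 * 3), 80))
  # single predictor equal to g
  res <- cross_sample_predict(1L, X, g, design)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  # empty set is flagged, not an error
  res0 <- cross_sample_predict(integer(0), X, g, design)
  expect_true(res0$no_predictors)
  expect_identical(res0$n_predictors, 0L)
  expect_false(res0$significant_bonferroni)
})

test_that("null predictors produce calibrated F-tests and small R-squared", {
  design <- rand_design(150, seed = 97)
  set.seed(98)
  rejections <- replicate(200, {
    X <- matrix(rnorm(150 * 5), 150)
    g <- rnorm(150)
    cross_sample_predict(1:5, X, g, design, m_bonferroni = 1L)$p_raw < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.05)
})

test_that("predictor overlap reports intersections and averaged effects", {
  ov <- predictor_overlap(list(a = c(1, 2, 3), b = c(2, 3, 4)),
                          effects = list(a = c(0.5, 0.4, 0.3, 0),
                                         b = c(0, 0.2, 0.1, 0.6)))
  expect_identical(ov$all_way, c(2, 3))
  expect_equal(ov$pairwise$n_intersect, 2L)
  expect_equal(ov$pairwise$overlap_pct, 50)
  expect_equal(ov$averaged_effects$mean_effect, c((0.4 + 0.2) / 2,
                                                  (0.3 + 0.1) / 2))
  ident <- predictor_overlap(list(a = 1:3, b = 1:3))
  expect_equal(ident$overlap_pct, 100)
  disjoint <- predictor_overlap(list(a = 1:2, b = 3:4))
  expect_identical(length(disjoint$all_way), 0L)
})

test_that("ICC(3,1) matches the ANOVA-table oracle and its fixed points", {
  set.seed(99)
  M <- cbind(rnorm(20), rnorm(20))
  expect_equal(icc_3_1(M), aov_icc_oracle(M), tolerance = 1e-10)
  # 3 x 2 hand fixture
  M32 <- matrix(c(1, 2, 3, 1.5, 2.5, 3.5), 3, 2)
  expect_equal(icc_3_1(M32), aov_icc_oracle(M32), tolerance = 1e-10)
  # identical sessions with varying subjects
  s1 <- rnorm(10)
  expect_equal(icc_3_1(cbind(s1, s1)), 1)
  # pure noise: near-zero ICC
  set.seed(100)
  expect_lt(abs(icc_3_1(matrix(rnorm(1000), 500, 2))), 0.05)
  expect_error(icc_3_1(cbind(c(1, NA, 3), c(1, 2, 3))),
               class = "omstnet_data_error")
})

test_that("ICC recovers planted variance-component ratios", {
  set.seed(101)
  n <- 1000
  subj <- rnorm(n, sd = 1)
  M <- cbind(subj + rnorm(n), subj + rnorm(n))  # true ICC = 0.5
  expect_lt(abs(icc_3_1(M) - 0.5), 0.05)
})

test_that("the Spearman-Brown formula behaves at its fixed points", {
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0.5), 2 / 3)
  r <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(spearman_brown(r) >= r))
})

test_that("lateralization quotients code handedness at the inclusive cutoff", {
  expect_equal(lateralization_quotient(10, 0),
               tibble::tibble(LQ = 100, handedness = 1L))
  expect_equal(lateralization_quotient(5, 5),
               tibble::tibble(LQ = 0, handedness = 0L))
  # boundary: LQ = 60 is coded right-handed
  expect_equal(lateralization_quotient(8, 2),
               tibble::tibble(LQ = 60, handedness = 1L))
  expect_error(lateralization_quotient(0, 0), class = "omstnet_data_error")
})

test_that("association tables carry Holm-corrected partial correlations", {
  gspec <- ground_truth_spec(n_nodes = 20, n_modules = 2, seed = 102)
  syn <- generate_cohort(80, gspec, effect_spec(true_r = 0), seed = 103)
  metrics_df <- tibble::tibble(
    g = syn$cohort$g,
    global_efficiency = vapply(syn$networks, function(w) efficiency(w)$E,
                               numeric(1)),
    global_clustering = vapply(syn$networks, function(w) clustering(w)$C,
                               numeric(1)))
  at <- association_table(metrics_df, syn$cohort,
                          metrics = c("global_efficiency",
                                      "global_clustering"))
  expect_s3_class(at, "association_table")
  expect_true(all(at$p_holm >= at$p_raw))
  expect_true(all(abs(at$r) <= 1))
  expect_identical(at$df, rep(80L - 2L - 8L, 2))
})
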