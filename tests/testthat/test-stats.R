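# small cohort builder with registry-named columns
mini_table <- function(..., outcome) {
  df <- data.frame(..., outcome = outcome)
  df
}

test_that("group comparison detects shifts and reports identity as null", {
  # identical groups record-for-record: t statistic 0, p = 1
  x <- c(1, 2, 3, 4, 5)
  tab <- mini_table(lesion_length = c(x, x),
                    outcome = rep(c(1, 0), each = 5))
  res <- compare_groups(tab)
  expect_equal(res$statistic[res$feature == "lesion_length"], 0)
  expect_equal(res$p_value[res$feature == "lesion_length"], 1)

  # a +10 shift at tiny spread is overwhelmingly significant
  set.seed(1)
  tab2 <- mini_table(lesion_length = c(rnorm(20, 10, 0.01),
                                       rnorm(20, 0, 0.01)),
                     outcome = rep(c(1, 0), each = 20))
  expect_lt(compare_groups(tab2)$p_value, 1e-3)

  # zero-variance feature warns and reports NA
  tab3 <- mini_table(lesion_length = rep(2, 10),
                     outcome = rep(c(1, 0), each = 5))
  expect_warning(res3 <- compare_groups(tab3), "zero variance")
  expect_true(is.na(res3$p_value))
})

test_that("the printed cholesterol-crystal 2x2 table is highly significant", {
  # 17/24 positives among events vs 12/80 among non-events
  tab <- mini_table(
    cholesterol_crystal = c(rep(1, 17), rep(0, 7), rep(1, 12), rep(0, 68)),
    outcome = c(rep(1, 24), rep(0, 80)))
  res <- compare_groups(tab)
  expect_lt(res$p_value, 1e-3)
  expect_match(res$event_summary, "17 \\(70.8%\\)")
  # matches a direct chi-square without continuity correction
  ref <- stats::chisq.test(matrix(c(68, 12, 7, 17), 2), correct = FALSE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("redundancy pruning removes duplicates and monotone copies", {
  set.seed(4)
  n <- 120
  base <- rnorm(n)
  tab <- mini_table(lesion_length = base,
                    min_lumen_area = base,              # exact copy
                    avg_lumen_area = exp(base),         # monotone transform
                    max_fc_angle = rnorm(n),
                    outcome = rbinom(n, 1, 0.3))
  pr <- spearman_prune(tab)
  # the whole rank-identical trio collapses to its first-listed member
  expect_identical(pr$retained, c("lesion_length", "max_fc_angle"))
  expect_setequal(pr$dropped, c("min_lumen_area", "avg_lumen_area"))
  expect_equal(unname(pr$rho["lesion_length", "avg_lumen_area"]), 1)

  # two independent gaussians both survive at n = 500
  set.seed(11)
  tab2 <- mini_table(lesion_length = rnorm(500),
                     max_fc_angle = rnorm(500),
                     outcome = rbinom(500, 1, 0.3))
  expect_length(spearman_prune(tab2)$retained, 2)

  # constant features are excluded with a warning
  tab3 <- mini_table(lesion_length = rnorm(50),
                     min_lumen_area = rep(1, 50),
                     max_fc_angle = rnorm(50),
                     outcome = rbinom(50, 1, 0.4))
  expect_warning(pr3 <- spearman_prune(tab3), "constant")
  expect_false("min_lumen_area" %in% rownames(pr3$rho))
})

test_that("pruning is invariant to feature-column permutation", {
  tab <- simulate_cohort(cohort_spec(seed = 12))
  pr1 <- spearman_prune(tab)
  perm <- sample(seq_len(ncol(tab) - 1))
  tab2 <- tab[c(perm, ncol(tab))]
  pr2 <- spearman_prune(tab2)
  expect_identical(pr1$retained, pr2$retained)
  expect_identical(pr1$dropped, pr2$dropped)
})

test_that("binary univariate odds ratio equals the cross-product ratio", {
  # 2x2 counts a=10, b=10, c=5, d=20 -> OR (10*20)/(10*5) = 4
  tab <- mini_table(microchannel = c(rep(1, 10), rep(0, 5),
                                     rep(1, 10), rep(0, 20)),
                    outcome = c(rep(1, 15), rep(0, 30)))
  res <- univariate_logistic(tab, "microchannel")
  expect_equal(res$odds_ratio, 4, tolerance = 1e-6)
  expect_true(res$ci_low <= res$odds_ratio & res$odds_ratio <= res$ci_high)

  # a predictor independent of the outcome has OR near 1 at n = 1000
  set.seed(8)
  tab2 <- mini_table(lesion_length = rnorm(1000),
                     outcome = sample(rep(c(1, 0), c(300, 700))))
  or <- univariate_logistic(tab2, "lesion_length")$odds_ratio
  expect_gt(or, 0.8); expect_lt(or, 1.25)

  # predictor equal to the outcome: flagged separation, not an error
  tab3 <- mini_table(microchannel = rep(c(1, 0), c(12, 20)),
                     outcome = rep(c(1, 0), c(12, 20)))
  res3 <- univariate_logistic(tab3, "microchannel")
  expect_true(res3$separation)
  expect_equal(res3$ci_low, 0)
  expect_equal(res3$ci_high, Inf)
})

test_that("multivariate logistic reduces, recovers and rejects properly", {
  # single selected feature: identical to the univariate fit
  tab <- simulate_cohort(cohort_spec(seed = 13))
  uni <- univariate_logistic(tab, "fc_surface_area_t")
  mult <- multivariate_logistic(tab, "fc_surface_area_t")
  expect_equal(mult$odds_ratio, uni$odds_ratio, tolerance = 1e-8)
  expect_equal(mult$p_value, uni$p_value, tolerance = 1e-8)

  # duplicated predictor column: rank-deficiency error naming the column
  tab$min_lumen_area <- tab$fc_surface_area_t
  expect_error(
    suppressWarnings(multivariate_logistic(
      tab, c("fc_surface_area_t", "min_lumen_area"))),
    "rank-deficient.*min_lumen_area")

  # low events-per-variable triggers the instability warning
  small <- simulate_cohort(cohort_spec(seed = 14))
  expect_warning(multivariate_logistic(
    small, c("fc_surface_area_t", "max_fc_angle", "lesion_length")),
    "events-per-variable")
})

test_that("joint fits recover generative coefficients within Wald bands", {
  covered <- 0L
  for (rep_i in 1:50) {
    set.seed(300 + rep_i)
    n <- 2000
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 0.7 * x1 + 0 * x2))
    tab <- data.frame(lesion_length = x1, max_fc_angle = x2, outcome = y)
    fit <- multivariate_logistic(tab, c("lesion_length", "max_fc_angle"))
    lo <- log(fit$ci_low[1]); hi <- log(fit$ci_high[1])
    if (lo <= 0.7 && 0.7 <= hi) covered <- covered + 1L
  }
  expect_gte(covered, 43L)   # >= 85% of 50
})

test_that("ROC analysis handles separation, ties and binormal truth", {
  # perfect separation
  r <- roc_analysis(c(0, 1, 2, 3), c(0, 0, 1, 1), n_boot = 200, seed = 1)
  expect_equal(r$auc, 1)
  expect_equal(r$optimal_cutoff, 2)
  expect_equal(r$sensitivity_at_cutoff, 1)
  expect_equal(r$specificity_at_cutoff, 1)

  # all scores identical: chance discrimination
  r2 <- roc_analysis(rep(1, 40), rep(c(0, 1), 20), n_boot = 200, seed = 1)
  expect_equal(r2$auc, 0.5)

  expect_error(roc_analysis(1:5, rep(1, 5), n_boot = 200), "both outcome")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  sc <- rnorm(200); y <- rbinom(200, 1, plogis(sc))
  a1 <- roc_analysis(sc, y, n_boot = 200, seed = 2)$auc
  a2 <- roc_analysis(exp(sc), y, n_boot = 200, seed = 2)$auc
  a3 <- roc_analysis(rank(sc), y, n_boot = 200, seed = 2)$auc
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("our AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  sc <- c(rnorm(80, 1), rnorm(120, 0))
  y <- rep(c(1, 0), c(80, 120))
  ours <- roc_analysis(sc, y, n_boot = 200, seed = 3)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("bootstrap CI narrows with sample size", {
  width <- vapply(c(100, 1000), function(n) {
    set.seed(23)
    sc <- c(rnorm(n, 1), rnorm(n, 0))
    y <- rep(c(1, 0), c(n, n))
    r <- roc_analysis(sc, y, n_boot = 500, seed = 4)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("the full pipeline finds the generative driver and is reproducible", {
  tab <- simulate_cohort(cohort_spec(seed = 7))
  cfg <- oct_config(seed = 7)
  rep1 <- suppressWarnings(run_pipeline(tab, cfg))
  expect_true("fc_surface_area_t" %in% rep1$significant)
  expect_gt(rep1$roc[["fc_surface_area_t"]]$auc, 0.7)

  rep2 <- suppressWarnings(run_pipeline(tab, cfg))
  expect_identical(report_json(rep1), report_json(rep2))

  bad <- tab; bad$outcome <- 1
  expect_error(run_pipeline(bad, cfg), "single class")
})
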