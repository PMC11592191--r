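test_that("inclusion criteria follow the age-specific RMP and Rs rules", {
  recs <- tibble::tibble(
    neuron_id = paste0("n", 1:6),
    age = c("E13", "E13", "E13", "E20_21", "E20_21", "E13"),
    rmp_mV = c(-49, -55, -60, -54, -56, -70),
    series_resistance_MOhm = c(8, 8, 12, 8, 8, 10)
  )
  out <- apply_inclusion(recs)
  expect_equal(out$included, c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$exclusion_reason[1], "rmp")             # -49 not below -50
  expect_equal(out$exclusion_reason[3], "series_resistance")
  expect_equal(out$exclusion_reason[4], "rmp")             # -54 not below -55
  expect_true(is.na(out$exclusion_reason[6]))              # Rs = 10 is kept
  # idempotent
  expect_equal(apply_inclusion(out)$included, out$included)
  expect_error(apply_inclusion(recs[, 1:2]), "Missing QC columns")
})

test_that("the 2-SD outlier rule is single-pass and order-preserving", {
  x <- c(1, 1, 1, 1, 1, 10)
  # mean 2.5, sample SD sqrt(13.5): |10 - 2.5| = 7.5 > 2 * 3.674
  res <- exclude_outliers(x)
  expect_equal(res$excluded, 10)
  expect_equal(res$kept, rep(1, 5))
  # all equal: SD = 0, nothing excluded
  expect_equal(exclude_outliers(rep(3, 5))$excluded, numeric(0))
  # symmetric set with no point beyond 2 SD: identity
  y <- c(-2, -1, 0, 1, 2)
  expect_equal(exclude_outliers(y)$kept, y)
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
  # kept is always a subset in original order
  withr::with_seed(1, z <- rnorm(50))
  expect_identical(exclude_outliers(z)$kept, z[exclude_outliers(z)$keep])
})

test_that("Welch t matches a from-scratch summary-statistic computation", {
  ident <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  res <- welch_t(a, b)
  # hand computation from means and variances
  se2 <- var(a) / 4 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_error(welch_t(c(1), c(1, 2)), "at least 2")
})

test_that("classic ANOVA F matches a manual sum-of-squares decomposition", {
  g <- list(a = c(3, 5, 4), b = c(6, 7, 8, 7), c = c(2, 3, 2, 3))
  res <- anova_bonferroni(g)
  all_v <- unlist(g)
  grand <- mean(all_v)
  ss_b <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2,
                     numeric(1)))
  ss_w <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  f_hand <- (ss_b / 2) / (ss_w / (length(all_v) - 3))
  expect_equal(res$statistic, f_hand, tolerance = 1e-12)
  expect_equal(unname(res$df), c(2, length(all_v) - 3))
  # identical groups: F = 0, p = 1
  same <- anova_bonferroni(list(a = c(1, 2), b = c(1, 2), c = c(2, 1)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("Bonferroni adjustment multiplies raw p by the family size, capped at 1", {
  g <- list(a = c(3, 5, 4), b = c(6, 7, 8, 7), c = c(2, 3, 2, 3))
  res <- anova_bonferroni(g)
  comp <- res$comparisons
  expect_equal(nrow(comp), 3)
  expect_equal(comp$p.adj, pmin(1, comp$p.value * 3))
  expect_true(all(comp$p.adj >= comp$p.value))
  # control-referenced family has 2 comparisons
  ref <- anova_bonferroni(g, reference = "a")
  expect_equal(nrow(ref$comparisons), 2)
  expect_equal(ref$comparisons$p.adj,
               pmin(1, ref$comparisons$p.value * 2))
})

test_that("Brown-Forsythe and Welch ANOVAs match textbook formulas", {
  g <- list(a = c(12, 14, 11, 13), b = c(18, 17, 19, 21, 20),
            c = c(15, 16, 14))
  res <- bf_welch_anova(g)
  # Welch W from the textbook weighting formula
  n <- vapply(g, length, numeric(1)); m <- vapply(g, mean, numeric(1))
  s2 <- vapply(g, var, numeric(1))
  w <- n / s2
  mw <- sum(w * m) / sum(w)
  k <- 3
  A <- sum(w * (m - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (n - 1))
  W_hand <- A / (1 + 2 * (k - 2) / (k^2 - 1) * lam)
  df2_hand <- (k^2 - 1) / (3 * lam)
  expect_equal(res$statistic, W_hand, tolerance = 1e-10)
  expect_equal(res$df[2], df2_hand, tolerance = 1e-10)
  # Brown-Forsythe F* from its definition
  N <- sum(n); grand <- sum(n * m) / N
  f_hand <- sum(n * (m - grand)^2) / sum((1 - n / N) * s2)
  expect_equal(res$brown_forsythe$statistic, f_hand, tolerance = 1e-12)
  ci <- (1 - n / N) * s2 / sum((1 - n / N) * s2)
  expect_equal(res$brown_forsythe$df[2], 1 / sum(ci^2 / (n - 1)),
               tolerance = 1e-12)
  # equal-mean groups give statistic ~ 0, p ~ 1
  null <- bf_welch_anova(list(a = c(1, 2, 3), b = c(2, 1, 3), c = c(3, 2, 1)))
  expect_lt(null$statistic, 1e-12)
  expect_equal(null$p_value, 1, tolerance = 1e-8)
  expect_lt(null$brown_forsythe$statistic, 1e-12)
})

test_that("star coding follows the figure-legend convention", {
  expect_equal(nmephys:::stars_for(c(0.2, 0.04, 0.009, 5e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("the battery routes two-condition strata to Welch t and larger ones to ANOVA", {
  withr::with_seed(11, {
    feats <- tibble::tibble(
      neuron_id = paste0("n", 1:36),
      age = "E13", region = "high_freq",
      condition = rep(c("control", "BDNF"), c(16, 20)),
      metric_x = c(rnorm(16, 20, 3), rnorm(20, 12, 4)),
      included = TRUE
    )
  })
  res <- run_condition_battery(feats, metrics = "metric_x")
  expect_equal(res$test, "welch_t")
  expect_lt(res$p.value, 0.05)
  # add a third condition: ANOVA battery
  withr::with_seed(12, {
    extra <- tibble::tibble(
      neuron_id = paste0("m", 1:11), age = "E13", region = "high_freq",
      condition = "BDNF_ANA12", metric_x = rnorm(11, 18, 5), included = TRUE)
  })
  res3 <- run_condition_battery(dplyr::bind_rows(feats, extra),
                                metrics = "metric_x")
  expect_equal(res3$test, "bf_welch_anova")
  expect_false(is.null(res3$anova[[1]]))
  expect_equal(nrow(res3$comparisons[[1]]), 3)
  # naming an absent metric lists the available ones
  expect_error(run_condition_battery(feats, metrics = "nope"),
               "Available")
})

test_that("shapiro wrapper reports the normality check without gating", {
  withr::with_seed(2, x <- rnorm(30))
  res <- shapiro_wilk(x)
  expect_equal(res$test, "shapiro_wilk")
  expect_gt(res$p_value, 0.01)
})
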