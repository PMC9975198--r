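test_that("2x2 Fisher matches hypergeometric enumeration on canonical tables", {
  got <- fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))
  expect_equal(got$p, 0.485714285714, tolerance = 1e-9)
  flat <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$p, 1)
  expect_equal(flat$odds_ratio, 1)
  extreme <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(extreme$p, oracle_fisher_2x2(matrix(c(10, 0, 0, 10), 2)),
               tolerance = 1e-12)
  expect_true(extreme$haldane_corrected)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")
})

test_that("Freeman-Halton reduces to Fisher on 2x2 and matches enumeration", {
  t22 <- matrix(c(4, 2, 1, 5), 2)
  expect_equal(freeman_halton(t22)$p, fisher_exact_2x2(t22)$p, tolerance = 1e-9)
  # identical rows -> p = 1
  t23 <- matrix(c(2, 3, 4, 2, 3, 4), nrow = 2, byrow = TRUE)
  expect_equal(freeman_halton(t23)$p, 1, tolerance = 1e-9)
  # exact p matches full fixed-margin enumeration
  t_rc <- matrix(c(5, 1, 2, 1, 4, 3), nrow = 2, byrow = TRUE)
  expect_equal(freeman_halton(t_rc)$p, oracle_freeman_halton(t_rc),
               tolerance = 1e-9)
  # Monte-Carlo agrees with exact within 3 standard errors
  mc <- freeman_halton(t_rc, exact_max = 1, n_mc = 2e4, seed = 5)
  expect_equal(mc$method, "monte_carlo")
  expect_lt(abs(mc$p - oracle_freeman_halton(t_rc)), 3 * mc$mc_se + 1e-4)
  expect_warning(freeman_halton(matrix(c(2, 0, 3, 0), 2)), "zero-margin")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.04, 0.001, 0.5, 0.02)
  q <- bh_fdr(p)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_fdr(p[perm]), q[perm])   # order equivariance
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("log-rank statistic matches the hand O-E computation", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1L, 6)
  group <- rep(c("a", "b"), each = 3)
  df <- tibble::tibble(ttp_days = time, progression_event = event, group = group)
  km <- km_logrank(df)
  expect_equal(km$logrank_chisq, oracle_logrank_chisq(time, event, group),
               tolerance = 1e-9)
  # identical groups -> statistic 0, p = 1
  df_same <- tibble::tibble(ttp_days = rep(c(2, 4, 6), 2),
                            progression_event = 1L,
                            group = rep(c("a", "b"), each = 3))
  km_same <- km_logrank(df_same)
  expect_equal(km_same$logrank_chisq, 0, tolerance = 1e-9)
  expect_equal(km_same$logrank_p, 1, tolerance = 1e-9)
  # doubling all times preserves the rank-based p
  df2 <- df
  df2$ttp_days <- df2$ttp_days * 2
  expect_equal(km_logrank(df2)$logrank_p, km$logrank_p)
  # all-censored group: median not reached
  df3 <- tibble::tibble(ttp_days = c(1, 2, 3, 9, 9, 9),
                        progression_event = c(1L, 1L, 1L, 0L, 0L, 0L),
                        group = rep(c("a", "b"), each = 3))
  km3 <- km_logrank(df3)
  expect_true(is.na(km3$medians$median[km3$medians$group == "b"]))
})

test_that("risk models recover planted effects with sane intervals", {
  d_log <- simulate_logistic_cohort(n = 400, or = 4, seed = 8)
  d_cox <- simulate_cox_cohort(n = 400, log_hr = 0.7, seed = 8)
  d <- dplyr::bind_cols(d_log, tibble::tibble(time = d_cox$time,
                                              ev = d_cox$event,
                                              z = rnorm(400)))
  fit <- fit_risk_models(d, "y", c("x", "z"), time = "time", event = "ev")
  est <- fit$estimates
  x_uni <- est[est$term == "x" & est$mode == "univariate" & est$model == "logistic", ]
  expect_gt(x_uni$estimate, 2.5)
  expect_lt(x_uni$estimate, 6.5)
  expect_true(x_uni$ci_low < x_uni$estimate & x_uni$estimate < x_uni$ci_high)
  # covariate independent of outcome: CI covers 1
  z_uni <- est[est$term == "z" & est$mode == "univariate" & est$model == "logistic", ]
  expect_true(z_uni$ci_low < 1 & 1 < z_uni$ci_high)
  # orthogonal covariates -> VIF ~ 1, no warning
  expect_lt(max(fit$vif$vif), 1.2)
  expect_length(fit$warnings, 0)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_false(glance(fit)$collinearity_warning)
})

test_that("collinear covariates trigger the VIF warning and separation is flagged", {
  set.seed(16)
  n <- 120
  x <- rnorm(n)
  d <- tibble::tibble(x = x, x2 = x + rnorm(n, 0, 0.1),
                      y = rbinom(n, 1, plogis(x)))
  fit <- fit_risk_models(d, "y", c("x", "x2"), time = NULL)
  expect_gt(max(fit$vif$vif), 2)
  expect_match(fit$warnings, "VIF")
  # complete separation -> penalized fallback flagged
  sep <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)),
                        y = c(rep(0L, 20), rep(1L, 20)))
  fit_sep <- fit_risk_models(sep, "y", "x", time = NULL)
  expect_true(any(fit_sep$estimates$flagged))
  expect_true(is.finite(fit_sep$estimates$estimate[1]))
})

test_that("MWW helper uses exact p for tiny samples", {
  got <- mww_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$p, wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)$p.value)
})
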