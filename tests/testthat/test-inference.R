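# Regression stages: OLS oracles, multivariate tests, tiers, errors.

make_small <- function(n = 8, seed = 2) {
  set.seed(seed)
  tibble::tibble(
    y = stats::rnorm(n),
    commute_class = rep(c("inactive", "active"), length.out = n),
    age = stats::rnorm(n, 50, 5)
  )
}

test_that("balance model equals the normal-equations oracle on tiny data", {
  d <- make_small(12)
  f <- fit_balance_model(d, "y", covariates = "age")
  X <- cbind(1, d$commute_class == "active", d$age)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(coef(f$fit)), drop(beta), tolerance = 1e-10)
  expect_true(f$contrasts$conf.low < f$contrasts$estimate &&
                f$contrasts$estimate < f$contrasts$conf.high)
  expect_equal(f$n, 12)
})

test_that("log-total model: doubling all totals shifts only the intercept", {
  set.seed(4)
  d <- tibble::tibble(total_min_wk = exp(stats::rnorm(50, 7, 0.5)),
                      commute_class = rep(c("inactive", "active"), 25),
                      age = stats::rnorm(50, 50, 5))
  f1 <- fit_total_model(d, covariates = "age")
  d2 <- d
  d2$total_min_wk <- 2 * d$total_min_wk
  f2 <- fit_total_model(d2, covariates = "age")
  expect_equal(coef(f2$fit)[-1], coef(f1$fit)[-1], tolerance = 1e-10)
  expect_equal(unname(coef(f2$fit)[1] - coef(f1$fit)[1]), log(2),
               tolerance = 1e-10)
  d$total_min_wk[1] <- 0
  expect_error(fit_total_model(d, covariates = "age"), "strictly positive")
})

test_that("degenerate designs error informatively", {
  d <- make_small(20)
  d$commute_class <- "inactive"
  expect_error(fit_balance_model(d, "y"), "constant")
  d2 <- make_small(20)
  d2$age_copy <- d2$age
  expect_error(fit_balance_model(d2, "y", covariates = c("age", "age_copy")),
               "aliased")
})

test_that("multivariate statistics are invariant across pivot coordinate sets", {
  cfg <- cohort_config(1200, true_balance_effects = c(z1 = -0.2, z2 = 0.1),
                       seed = 41)
  g <- generate_cross_sectional(cfg)
  prep <- prep_analysis(g$raw)
  stats_by_basis <- sapply(pivot_bases(), function(b) {
    z <- ilr_transform(prep$imputed, b)
    d <- cbind(prep$records[, setdiff(names(prep$records), c("z1", "z2"))],
               z1 = z[, 1], z2 = z[, 2])
    f <- fit_coordinate_set(d, tier = 2)
    c(f$multivariate$value, f$multivariate$p.value)
  })
  expect_lt(max(abs(stats_by_basis - stats_by_basis[, 1])), 1e-8)
})

test_that("MANCOVA p-values are uniform under the null", {
  set.seed(77)
  pvals <- replicate(500, {
    n <- 150
    d <- tibble::tibble(commute_class = sample(c("inactive", "active"), n, TRUE))
    z <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, 0.3, 0.3, 1), 2))
    d$z1 <- z[, 1]
    d$z2 <- z[, 2]
    fit_coordinate_set(d, tier = 1)$multivariate$p.value[1]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("tier covariate sets nest and the sensitivity variant drops income/children", {
  expect_length(tier_covariates(1), 0)
  expect_true(all(tier_covariates(2) %in% tier_covariates(3)))
  expect_true(all(c("years_elapsed", "season_differs") %in%
                    tier_covariates(3, longitudinal = TRUE)))
  expect_false(any(c("income", "has_child") %in%
                     tier_covariates(3, sensitivity = TRUE)))
})

test_that("without confounding, unadjusted and adjusted estimates agree", {
  cfg <- cohort_config(3000, true_balance_effects = c(z1 = -0.15, z2 = 0),
                       seed = 55)
  g <- generate_cross_sectional(cfg)
  prep <- prep_analysis(g$raw)
  f1 <- fit_balance_model(prep$records, "balance_screen", tier = 1)
  f3 <- fit_balance_model(prep$records, "balance_screen", tier = 3)
  expect_lt(abs(f1$contrasts$estimate - f3$contrasts$estimate), 0.05)
})

test_that("longitudinal model recovers an identity relationship", {
  set.seed(9)
  n <- 400
  d <- tibble::tibble(
    commute_change = factor(sample(c("stable_inactive", "stable_active",
                                     "inactive_to_active", "active_to_inactive"),
                                   n, TRUE)),
    y_bl = stats::rnorm(n))
  d$y_fu <- d$y_bl + stats::rnorm(n, 0, 0.01)
  f <- fit_longitudinal(d, "y_fu", "y_bl", tier = 1)
  expect_equal(unname(coef(f$fit)["y_bl"]), 1, tolerance = 0.01)
  expect_true(all(abs(f$contrasts$estimate) < 0.01))
  expect_identical(f$reference_levels$commute_change, "stable_inactive")
})

test_that("sensitivity reruns enlarge the sample when income is missing", {
  cfg <- cohort_config(1500, missing_rates = c(income = 0.3), seed = 19)
  g <- generate_cross_sectional(cfg)
  rcfg <- run_config(cohort = cfg, tiers = c(1, 3), sensitivity = TRUE)
  bundle <- run_pipeline(rcfg)
  main <- bundle$cross_sectional
  sens <- bundle$cross_sectional_sensitivity
  expect_gt(sens$n_analysis, main$n_analysis)
  expect_true(all(sens$fits_balance$variant == "sensitivity"))
  expect_true(all(main$fits_balance$variant == "main"))
})
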