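# Reference grids, adjusted means, back-transformation.

fit_with_data <- function(n = 300, seed = 6) {
  set.seed(seed)
  d <- tibble::tibble(
    commute_class = sample(c("inactive", "active"), n, TRUE, c(0.65, 0.35)),
    sex = sample(c("male", "female"), n, TRUE),
    age = stats::rnorm(n, 52, 7)
  )
  z <- MASS::mvrnorm(n, c(3, -0.7), matrix(c(1.3, 0.3, 0.3, 1.1), 2))
  d$z1 <- z[, 1] - 0.2 * (d$commute_class == "active") + 0.01 * (d$age - 52)
  d$z2 <- z[, 2]
  d$total_min_wk <- exp(stats::rnorm(n, 7.3, 0.5))
  d
}

test_that("reference grid holds covariates at frequency-weighted means", {
  d <- fit_with_data()
  f <- fit_balance_model(d, "z1", covariates = c("sex", "age"))
  grid <- build_reference_grid(f$fit)
  expect_identical(grid$levels, c("inactive", "active"))
  X <- stats::model.matrix(f$fit)
  sex_col <- grep("^sex", colnames(X), value = TRUE)
  expect_equal(unname(grid$design[, sex_col]), rep(mean(X[, sex_col]), 2))
  expect_equal(unname(grid$design[, "age"]), rep(mean(d$age), 2))
  expect_equal(unname(grid$design[, "commute_classactive"]), c(0, 1))

  # no covariates: the grid is just the exposure levels
  f0 <- fit_balance_model(d, "z1", tier = 1)
  g0 <- build_reference_grid(f0$fit)
  expect_equal(dim(g0$design), c(2L, 2L))
  expect_error(build_reference_grid(f0$fit, exposure = "bmi"), "not a term")
})

test_that("grid predictions equal the predict-then-average oracle", {
  d <- fit_with_data(seed = 8)
  fz <- fit_coordinate_set(d, covariates = c("sex", "age"))
  gz <- build_reference_grid(fz$fit)
  zhat <- adjusted_ilr_means(fz, gz)
  for (lev in c("inactive", "active")) {
    nd <- fz$fit$model
    nd$commute_class <- factor(lev, levels = levels(nd$commute_class))
    oracle <- colMeans(stats::predict(fz$fit, newdata = nd))
    expect_equal(unname(zhat[lev, ]), unname(oracle), tolerance = 1e-10)
  }
  ft <- fit_total_model(d, covariates = c("sex", "age"))
  gt <- build_reference_grid(ft$fit)
  tot <- adjusted_total(ft, gt)
  nd <- ft$fit$model
  nd$commute_class <- factor("active", levels = levels(nd$commute_class))
  expect_equal(unname(log(tot["active"])),
               mean(stats::predict(ft$fit, newdata = nd)), tolerance = 1e-10)
})

test_that("adjusted means match emmeans with proportional weighting", {
  skip_if_not_installed("emmeans")
  d <- fit_with_data(seed = 10)
  f <- fit_balance_model(d, "z1", covariates = c("sex", "age"))
  grid <- build_reference_grid(f$fit)
  ours <- drop(adjusted_ilr_means(f, grid))
  em <- emmeans::emmeans(f$fit, "commute_class", weights = "proportional")
  theirs <- summary(em)$emmean
  expect_equal(unname(ours), theirs, tolerance = 1e-8)
})

test_that("back-transformed parts sum exactly to each group's adjusted total", {
  zm <- rbind(inactive = c(3.1, -0.7), active = c(2.9, -0.5))
  totals <- c(inactive = 1678, active = 1616)
  out <- back_transform_means(zm, default_basis(), totals)
  mins <- as.matrix(out[, paste0(DT_PARTS, "_min_wk")])
  expect_equal(unname(rowSums(mins)), unname(totals))
  props <- as.matrix(out[, paste0(DT_PARTS, "_prop")])
  expect_equal(unname(rowSums(props)), c(1, 1))
  # zero coordinates split the total in thirds
  flat <- back_transform_means(matrix(0, 1, 2), default_basis(), 300)
  expect_equal(unlist(flat[, paste0(DT_PARTS, "_min_wk")], use.names = FALSE),
               rep(100, 3))
})

test_that("a means-only back-transform reproduces the compositional mean", {
  x <- random_parts(120, seed = 13)
  z <- ilr_transform(x)
  totals <- rowSums(x)
  zbar <- matrix(colMeans(z), 1)
  gm_total <- exp(mean(log(totals)))
  bt <- back_transform_means(zbar, default_basis(), gm_total)
  cm <- compositional_mean(x, total_scale = gm_total)
  expect_equal(unlist(bt[, paste0(DT_PARTS, "_prop")], use.names = FALSE),
               cm$proportion, tolerance = 1e-8)
  expect_equal(unlist(bt[, paste0(DT_PARTS, "_min_wk")], use.names = FALSE),
               cm$minutes_wk, tolerance = 1e-8)
})

test_that("adjusted means recover generating group compositions without confounding", {
  cfg <- cohort_config(10000, true_balance_effects = c(z1 = -0.15, z2 = 0.1),
                       true_logtotal_effect = -0.05, seed = 29)
  g <- generate_cross_sectional(cfg)
  prep <- prep_analysis(g$raw)
  am <- adjusted_means(prep$records, tier = 1)
  diff_z <- ilr_transform(as.matrix(am[am$group == "active",
                                       paste0(DT_PARTS, "_prop")])) -
    ilr_transform(as.matrix(am[am$group == "inactive",
                               paste0(DT_PARTS, "_prop")]))
  expect_lt(abs(diff_z[1, 1] - (-0.15)), 0.06)
  expect_lt(abs(diff_z[1, 2] - 0.1), 0.06)
  expect_lt(abs(log(am$total_min_wk[am$group == "active"] /
                      am$total_min_wk[am$group == "inactive"]) - (-0.05)), 0.04)
})
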