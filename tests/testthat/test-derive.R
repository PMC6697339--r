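# Questionnaire derivation and exclusion filters.

test_that("commute mode dichotomises to car-only inactive vs anything-else active", {
  expect_identical(code_commute_mode("car"), "inactive")
  expect_identical(code_commute_mode(c("car", "walk")), "active")
  expect_identical(code_commute_mode("cycle"), "active")
  expect_identical(code_commute_mode("car|public_transport"), "active")
  expect_error(code_commute_mode(character(0)), "missing commute mode")
  expect_error(code_commute_mode("horse"), "unknown travel mode")
  expect_identical(code_commute_mode_vec(c("car", "walk|cycle", NA)),
                   c("inactive", "active", NA))
})

test_that("commute change maps to the four stability/switch categories", {
  expect_identical(
    as.character(code_commute_change(
      c("inactive", "inactive", "active", "active"),
      c("inactive", "active", "active", "inactive"))),
    c("stable_inactive", "inactive_to_active", "stable_active",
      "active_to_inactive"))
  expect_error(code_commute_change(NA, "active"), "missing")
  expect_error(code_commute_change("car", "active"), "inactive")
})

test_that("screen time sums TV and computer hours, truncates at 9 h/day", {
  expect_equal(derive_screen_time(4, 2), 2520)
  expect_equal(derive_screen_time(6, 6), 3780) # truncated to 9 h/day
  expect_equal(derive_screen_time(0, 0), 0)    # flagged downstream
  expect_equal(derive_screen_time(c(1, 9), c(0.5, 3)), c(630, 3780))
  expect_error(derive_screen_time(-1, 2), "negative")
})

test_that("activity minutes = weekly frequency x midpoint duration", {
  maps <- default_category_maps()
  expect_equal(code_activity_minutes("2-3 times a week", "15-30 minutes", maps),
               2.5 * 22.5)
  expect_equal(code_activity_minutes(NA, NA, maps), 0)
  # monthly frequencies divided by weeks-per-month (hand oracle)
  expect_equal(code_activity_minutes("once a month", "15-30 minutes", maps),
               22.5 * 12 * 7 / 365.25)
  expect_error(code_activity_minutes("sometimes", "15-30 minutes", maps),
               "sometimes")
  expect_error(code_activity_minutes("once a week", "ages", maps), "ages")

  # monotone in both category orders
  freqs <- names(maps$frequency)
  durs <- names(maps$duration)
  by_freq <- code_activity_minutes(freqs, durs[2], maps)
  expect_true(all(diff(by_freq) > 0))
  by_dur <- code_activity_minutes(freqs[3], durs, maps)
  expect_true(all(diff(by_dur) > 0))
})

test_that("subcomposition amalgamates sport and DIY, total is the exact sum", {
  sub <- build_subcomposition(2520, 30, 40, 20, 10, 5)
  expect_equal(sub$walking_min_wk, 30)
  expect_equal(sub$sportdiy_min_wk, 75)
  expect_equal(sub$total_min_wk, 2625)
  expect_false(sub$flag_over_24h)

  none <- build_subcomposition(2520, 0)
  expect_equal(unlist(none[, c("walking_min_wk", "sportdiy_min_wk")]),
               c(walking_min_wk = 0, sportdiy_min_wk = 0))

  over <- build_subcomposition(3780, 4000, 4000)
  expect_true(over$flag_over_24h)

  set.seed(1)
  s <- matrix(stats::runif(60, 0, 500), ncol = 6)
  sub <- build_subcomposition(s[, 1], s[, 2], s[, 3], s[, 4], s[, 5], s[, 6])
  expect_equal(sub$total_min_wk,
               sub$screen_min_wk + sub$walking_min_wk + sub$sportdiy_min_wk)
})

test_that("follow-up covariates: elapsed years and meteorological season change", {
  fu <- derive_followup_covariates("2008-07-01", "2012-10-01")
  expect_equal(fu$years_elapsed, 4.25, tolerance = 0.01)
  expect_true(fu$season_differs)
  expect_false(derive_followup_covariates("2008-07-01", "2012-07-01")$season_differs)
  expect_error(derive_followup_covariates("2008-07-01", "2008-06-30"),
               "not after")
})

test_that("exclusions apply in order with a one-reason-per-record ledger", {
  raw <- rbind(
    raw_row(1),                                    # retained
    raw_row(2, commute_freq = 0.5),                # works from home
    raw_row(3, commute_miles = 0),                 # works from home
    raw_row(4, able_to_walk = FALSE),
    raw_row(5, tv = 0, pc = 0),                    # zero screen time
    raw_row(6, employed = FALSE),
    raw_row(7, commute_modes = NA),
    raw_row(8, income = NA),                       # incomplete covariates
    raw_row(9, commute_freq = 0.5, able_to_walk = FALSE) # first reason wins
  )
  derived <- derive_records(raw)
  out <- apply_exclusions(derived)
  expect_equal(out$records$id, 1)
  expect_equal(sum(out$ledger$n), nrow(raw) - nrow(out$records))
  counts <- stats::setNames(out$ledger$n, out$ledger$reason)
  expect_equal(unname(counts["works_from_home"]), 3L)
  expect_equal(unname(counts["not_employed_or_no_commute"]), 2L)
  expect_equal(unname(counts["unable_to_walk"]), 1L)
  expect_equal(unname(counts["zero_screen_time"]), 1L)
  expect_equal(unname(counts["incomplete_covariates"]), 1L)

  # over-24h totals excluded
  big <- raw_row(10, tv = 9, pc = 0)
  big$walking_pleasure_freq <- "every day"
  big$walking_pleasure_dur <- "over 3 hours"
  for (act in c("strenuous_sport", "other_sport", "light_diy", "heavy_diy")) {
    big[[paste0(act, "_freq")]] <- "every day"
    big[[paste0(act, "_dur")]] <- "over 3 hours"
  }
  d2 <- derive_records(rbind(raw_row(1), big))
  out2 <- apply_exclusions(d2)
  expect_equal(out2$ledger$n[out2$ledger$reason == "over_24h_discretionary"],
               1L, ignore_attr = TRUE)

  # sensitivity covariate list retains records missing only income
  sens <- apply_exclusions(derived,
                           required_covariates = setdiff(
                             c(tier_covariates(3)), c("income", "has_child")))
  expect_true(8L %in% sens$records$id)
  expect_gt(nrow(sens$records), nrow(out$records))
})

test_that("derive_records codes a full row consistently end to end", {
  d <- derive_records(raw_row(1))
  expect_identical(d$commute_class, "inactive")
  expect_equal(d$screen_min_wk, 4 * 60 * 7)
  expect_equal(d$walking_min_wk, 2.5 * 22.5)
  expect_equal(d$sportdiy_min_wk, 1 * 45)
  expect_equal(d$total_min_wk, d$screen_min_wk + d$walking_min_wk + d$sportdiy_min_wk)
})
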