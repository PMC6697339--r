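# Regression stages: multivariate tests on the full coordinate set
# (MANCOVA), OLS on single balances, OLS on the log total, and the
# follow-up-adjusted-for-baseline longitudinal models, each under three
# progressively adjusted covariate tiers.

#' Covariates entering each model tier
#'
#' Tier 1 is exposure only. Tier 2 adds commute frequency and distance,
#' age, sex, ethnicity, home ownership, car ownership, income, education,
#' children in the household and Townsend score. Tier 3 adds BMI,
#' occupational activity, recent fracture, vascular and non-vascular
#' conditions, and - in longitudinal models - elapsed years and whether
#' the season differed between assessments.
#'
#' @param tier 1, 2 or 3.
#' @param longitudinal Add the elapsed-time / season covariates at tier 3.
#' @param sensitivity Drop income and children (the sensitivity variant
#'   enlarging the complete-case sample).
#' @return Character vector of covariate names (empty for tier 1).
#' @export
tier_covariates <- function(tier, longitudinal = FALSE, sensitivity = FALSE) {
  stopifnot(tier %in% 1:3)
  covs <- character(0)
  if (tier >= 2) covs <- TIER2_COVARIATES
  if (tier >= 3) {
    covs <- c(covs, TIER3_EXTRA)
    if (longitudinal) covs <- c(covs, "years_elapsed", "season_differs")
  }
  if (sensitivity) covs <- setdiff(covs, c("income", "has_child"))
  covs
}

# Categorical columns become factors with the most frequent level as
# reference (treatment contrasts); reference levels are recorded.
prepare_model_data <- function(data, exposure, covariates, exposure_levels = NULL) {
  cols <- c(exposure, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop("columns absent from data: ", paste(missing_cols, collapse = ", "))
  }
  refs <- list()
  for (nm in cols) {
    x <- data[[nm]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      x <- factor(x)
      if (nm == exposure && !is.null(exposure_levels)) {
        x <- factor(x, levels = exposure_levels)
      } else if (nm != exposure) {
        tab <- sort(table(x), decreasing = TRUE)
        x <- stats::relevel(x, ref = names(tab)[1L])
      }
      refs[[nm]] <- levels(x)[1L]
      data[[nm]] <- x
    }
  }
  if (is.factor(data[[exposure]]) && length(unique(stats::na.omit(data[[exposure]]))) < 2L) {
    stop("exposure '", exposure, "' is constant in the data")
  }
  list(data = data, reference_levels = refs)
}

check_aliased <- function(fit) {
  cf <- coef(fit)
  if (is.matrix(cf)) cf <- cf[, 1L]
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
}

new_fit_result <- function(outcome, tier, fit, contrasts, multivariate = NULL,
                           reference_levels = list(), variant = "main") {
  structure(list(
    outcome = outcome, tier = tier, n = stats::nobs(fit),
    contrasts = contrasts, multivariate = multivariate,
    reference_levels = reference_levels, variant = variant, fit = fit
  ), class = "coda_fit")
}

#' @export
print.coda_fit <- function(x, ...) {
  cat(sprintf("<coda_fit> outcome: %s | tier %d | n = %d%s\n", x$outcome,
              x$tier, x$n, if (x$variant != "main") paste0(" | ", x$variant) else ""))
  if (!is.null(x$multivariate)) {
    print(as.data.frame(x$multivariate), row.names = FALSE, digits = 4)
  }
  if (nrow(x$contrasts) > 0L) {
    print(as.data.frame(x$contrasts), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

# Exposure rows of a univariate lm as a contrast table.
exposure_contrasts <- function(fit, exposure) {
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  keep <- grep(paste0("^", exposure), rownames(sm))
  tibble::tibble(
    term = rownames(sm)[keep],
    estimate = sm[keep, "Estimate"],
    conf.low = ci[keep, 1L],
    conf.high = ci[keep, 2L],
    p.value = sm[keep, "Pr(>|t|)"]
  )
}

#' Multivariate model for the full ilr coordinate set (MANCOVA)
#'
#' Fits a multivariate linear model with the two balance coordinates as
#' joint outcome and reports Pillai's trace and Wilks' lambda (with their F
#' approximations) for the exposure term. The statistics are invariant to
#' which pivot coordinate set is used, since the sets are orthogonal
#' rotations of one another.
#'
#' @param data Data frame containing the coordinate columns, exposure and
#'   covariates (complete cases are used).
#' @param coords Names of the two coordinate columns.
#' @param exposure Exposure column name.
#' @param tier Model tier (1-3); determines default covariates.
#' @param covariates Covariate names; defaults to [tier_covariates()].
#' @param longitudinal,sensitivity Passed to [tier_covariates()].
#' @return A `coda_fit` with a `multivariate` table (Pillai and Wilks rows)
#'   and per-coordinate exposure contrasts.
#' @export
fit_coordinate_set <- function(data, coords = c("z1", "z2"),
                               exposure = "commute_class", tier = 1,
                               covariates = NULL, longitudinal = FALSE,
                               sensitivity = FALSE) {
  covariates <- covariates %||% tier_covariates(tier, longitudinal, sensitivity)
  data <- data[stats::complete.cases(data[, c(coords, exposure, covariates)]), ]
  prep <- prepare_model_data(data, exposure, covariates,
                             exposure_levels = exposure_reference(data[[exposure]]))
  d <- prep$data
  Y <- as.matrix(d[, coords])
  rhs <- paste(c("1", exposure, covariates), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste("Y ~", rhs)), data = d)
  check_aliased(full)
  red_rhs <- paste(c("1", covariates), collapse = " + ")
  reduced <- stats::lm(stats::as.formula(paste("Y ~", red_rhs)), data = d)
  mv <- do.call(rbind, lapply(c("Pillai", "Wilks"), function(tst) {
    a <- stats::anova(full, reduced, test = tst)
    i <- 2L
    tibble::tibble(statistic = tst, value = a[i, tst],
                   approx_F = a[i, "approx F"], df1 = a[i, "num Df"],
                   df2 = a[i, "den Df"], p.value = a[i, "Pr(>F)"])
  }))
  cf <- coef(full)
  keep <- grep(paste0("^", exposure), rownames(cf))
  se <- sqrt(diag(stats::vcov(full)))
  cn <- outer(rownames(cf), colnames(cf), function(a, b) paste(b, a, sep = ":"))
  se <- matrix(se[match(as.vector(cn), names(se))], nrow(cf), ncol(cf))
  tq <- stats::qt(0.975, full$df.residual)
  contrasts <- do.call(rbind, lapply(seq_along(coords), function(j) {
    tibble::tibble(
      term = paste0(coords[j], ":", rownames(cf)[keep]),
      estimate = cf[keep, j],
      conf.low = cf[keep, j] - tq * se[keep, j],
      conf.high = cf[keep, j] + tq * se[keep, j],
      p.value = 2 * stats::pt(-abs(cf[keep, j] / se[keep, j]), full$df.residual)
    )
  }))
  new_fit_result(paste(coords, collapse = "+"), tier, full, contrasts, mv,
                 prep$reference_levels,
                 variant = if (sensitivity) "sensitivity" else "main")
}

# Reference level conventions: inactive first cross-sectionally,
# stable_inactive first longitudinally; anything else alphabetical.
exposure_reference <- function(x) {
  lev <- sort(unique(as.character(stats::na.omit(x))))
  if ("stable_inactive" %in% lev) return(intersect(COMMUTE_CHANGE_LEVELS, lev))
  if ("inactive" %in% lev) return(c("inactive", setdiff(lev, "inactive")))
  lev
}

#' Single-balance regression
#'
#' OLS of the first coordinate of a pivot set (one part versus the rest)
#' on the exposure and tier covariates. A positive exposure coefficient
#' means relatively more of the isolated part among the exposed.
#'
#' @inheritParams fit_coordinate_set
#' @param outcome Name of the balance column.
#' @return A `coda_fit` with exposure contrasts (estimate, 95% CI, p).
#' @export
fit_balance_model <- function(data, outcome, exposure = "commute_class",
                              tier = 1, covariates = NULL,
                              longitudinal = FALSE, sensitivity = FALSE) {
  covariates <- covariates %||% tier_covariates(tier, longitudinal, sensitivity)
  data <- data[stats::complete.cases(data[, c(outcome, exposure, covariates)]), ]
  prep <- prepare_model_data(data, exposure, covariates,
                             exposure_levels = exposure_reference(data[[exposure]]))
  rhs <- paste(c("1", exposure, covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(outcome, "~", rhs)), data = prep$data)
  check_aliased(fit)
  new_fit_result(outcome, tier, fit, exposure_contrasts(fit, exposure),
                 reference_levels = prep$reference_levels,
                 variant = if (sensitivity) "sensitivity" else "main")
}

#' Regression on log total discretionary time
#'
#' OLS of `log(total)` on exposure and tier covariates; the exposure
#' coefficient is the log-ratio of (geometric-mean-scale) totals between
#' groups.
#'
#' @inheritParams fit_coordinate_set
#' @param total Name of the total minutes/week column.
#' @return A `coda_fit`.
#' @export
fit_total_model <- function(data, total = "total_min_wk",
                            exposure = "commute_class", tier = 1,
                            covariates = NULL, longitudinal = FALSE,
                            sensitivity = FALSE) {
  if (any(data[[total]] <= 0, na.rm = TRUE)) {
    stop("total discretionary time must be strictly positive for the log transform")
  }
  covariates <- covariates %||% tier_covariates(tier, longitudinal, sensitivity)
  data <- data[stats::complete.cases(data[, c(total, exposure, covariates)]), ]
  data$.log_total <- log(data[[total]])
  prep <- prepare_model_data(data, exposure, covariates,
                             exposure_levels = exposure_reference(data[[exposure]]))
  rhs <- paste(c("1", exposure, covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".log_total ~", rhs)), data = prep$data)
  check_aliased(fit)
  new_fit_result(paste0("log(", total, ")"), tier, fit,
                 exposure_contrasts(fit, exposure),
                 reference_levels = prep$reference_levels,
                 variant = if (sensitivity) "sensitivity" else "main")
}

#' Longitudinal change model
#'
#' Models the follow-up outcome adjusted for its baseline value (the
#' change-over-time representation): OLS of the follow-up value on the
#' baseline value, the four-level commute-change variable (reference
#' stable_inactive) and the tier covariates; tier 3 additionally adjusts
#' for elapsed years and season change.
#'
#' @param data Paired data, one row per participant, containing
#'   `outcome_fu`, `outcome_bl` and the exposure/covariates.
#' @param outcome_fu,outcome_bl Follow-up and baseline outcome columns.
#' @inheritParams fit_coordinate_set
#' @return A `coda_fit` with the three change contrasts.
#' @export
fit_longitudinal <- function(data, outcome_fu, outcome_bl,
                             exposure = "commute_change", tier = 1,
                             covariates = NULL, sensitivity = FALSE) {
  covariates <- covariates %||% tier_covariates(tier, longitudinal = TRUE,
                                                sensitivity = sensitivity)
  need <- c(outcome_fu, outcome_bl, exposure, covariates)
  data <- data[stats::complete.cases(data[, need]), ]
  prep <- prepare_model_data(data, exposure, covariates,
                             exposure_levels = exposure_reference(data[[exposure]]))
  rhs <- paste(c("1", outcome_bl, exposure, covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(outcome_fu, "~", rhs)), data = prep$data)
  check_aliased(fit)
  new_fit_result(paste0(outcome_fu, " | ", outcome_bl), tier, fit,
                 exposure_contrasts(fit, exposure),
                 reference_levels = prep$reference_levels,
                 variant = if (sensitivity) "sensitivity" else "main")
}
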