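# Model-predicted (adjusted) means: the reference-grid machinery behind
# the adjusted compositional mean tables. Continuous covariates are held
# at their sample mean and categorical covariates are averaged over their
# levels with observed-frequency weights; only the exposure is varied.
# For a linear model this equals averaging per-row predictions with the
# exposure overridden.

#' Build a covariate reference grid from a fitted model
#'
#' One design row per exposure level: the exposure dummy columns take that
#' level's contrast pattern, every other design column its observed mean
#' (which, for treatment-coded factor dummies, is the observed level
#' frequency - i.e. proportional level weighting).
#'
#' @param fit A fitted `lm`/`mlm` (must retain its model frame).
#' @param exposure Name of the exposure term in the model.
#' @return A `coda_ref_grid`: exposure levels and the levels x coefficients
#'   design matrix.
#' @export
build_reference_grid <- function(fit, exposure = "commute_class") {
  tt <- stats::terms(fit)
  labels <- attr(tt, "term.labels")
  if (!exposure %in% labels) {
    stop("exposure '", exposure, "' is not a term of the fitted model")
  }
  X <- stats::model.matrix(fit)
  asgn <- attr(X, "assign")
  exp_cols <- which(asgn == which(labels == exposure))
  xbar <- colMeans(X)
  fac <- fit$model[[exposure]]
  if (!is.factor(fac)) stop("exposure must be a factor in the model frame")
  ctr <- stats::contrasts(fac)
  levs <- levels(fac)
  design <- do.call(rbind, lapply(seq_along(levs), function(l) {
    row <- xbar
    row[exp_cols] <- ctr[l, ]
    row
  }))
  rownames(design) <- levs
  structure(list(levels = levs, design = design, exposure = exposure),
            class = "coda_ref_grid")
}

#' Adjusted mean ilr coordinates per exposure group
#'
#' @param fit The multivariate (two-coordinate) linear model, e.g.
#'   `fit_coordinate_set(...)$fit`, or a `coda_fit`.
#' @param grid A [build_reference_grid()] grid built from the same model.
#' @return Matrix (groups x coordinates) of adjusted coordinate means.
#' @export
adjusted_ilr_means <- function(fit, grid) {
  if (inherits(fit, "coda_fit")) fit <- fit$fit
  stopifnot(inherits(grid, "coda_ref_grid"))
  grid$design %*% stats::coef(fit)
}

#' Adjusted total discretionary time per exposure group
#'
#' Back-transforms the adjusted mean of the log total:
#' `exp(adjusted mean log total)` - a geometric-mean-scale total, matching
#' the compositional-mean convention (no log-normal bias correction).
#'
#' @param fit The log-total model (`fit_total_model(...)$fit` or a
#'   `coda_fit`).
#' @param grid Matching reference grid.
#' @param smearing Apply Duan's smearing factor (mean of
#'   exponentiated residuals) to approximate an arithmetic-mean total.
#' @return Named vector of minutes/week per exposure group.
#' @export
adjusted_total <- function(fit, grid, smearing = FALSE) {
  if (inherits(fit, "coda_fit")) fit <- fit$fit
  stopifnot(inherits(grid, "coda_ref_grid"))
  out <- exp(drop(grid$design %*% stats::coef(fit)))
  if (smearing) out <- out * mean(exp(stats::residuals(fit)))
  out
}

#' Back-transform adjusted ilr means to minutes per week
#'
#' Inverts the ilr transform group by group into proportions, then rescales
#' each group's proportions by that group's adjusted total, so per-part
#' minutes sum exactly to the group total.
#'
#' @param ilr_means Groups x coordinates matrix ([adjusted_ilr_means()]).
#' @param basis The `balance_basis` the coordinates were computed under.
#' @param totals Adjusted total minutes/week, one per group
#'   ([adjusted_total()]).
#' @return Tibble: group, per-part proportions, per-part minutes/week and
#'   the group total.
#' @export
back_transform_means <- function(ilr_means, basis, totals) {
  stopifnot(nrow(ilr_means) == length(totals))
  prop <- ilr_inverse(ilr_means, basis, total_scale = 1)
  minutes <- prop * totals
  groups <- rownames(ilr_means) %||% paste0("group", seq_len(nrow(ilr_means)))
  out <- tibble::tibble(group = groups)
  for (p in basis$parts) {
    out[[paste0(p, "_prop")]] <- prop[, p]
    out[[paste0(p, "_min_wk")]] <- minutes[, p]
  }
  out$total_min_wk <- unname(totals)
  out
}

#' Adjusted compositional means and totals per exposure group
#'
#' Convenience wrapper running the full adjusted-means machinery: fit the
#' coordinate-set and log-total models at a tier, build the reference
#' grid, predict the adjusted coordinate means and totals, and
#' back-transform to minutes/week.
#'
#' @param data Analysis data containing coordinates, total, exposure and
#'   covariates.
#' @inheritParams fit_coordinate_set
#' @param total Total minutes/week column.
#' @param basis Balance basis of the coordinate columns.
#' @return Tibble as from [back_transform_means()].
#' @export
adjusted_means <- function(data, coords = c("z1", "z2"),
                           total = "total_min_wk",
                           exposure = "commute_class", tier = 3,
                           covariates = NULL, basis = default_basis(),
                           longitudinal = FALSE, sensitivity = FALSE) {
  fz <- fit_coordinate_set(data, coords, exposure, tier, covariates,
                           longitudinal, sensitivity)
  ft <- fit_total_model(data, total, exposure, tier, covariates,
                        longitudinal, sensitivity)
  gz <- build_reference_grid(fz$fit, exposure)
  gt <- build_reference_grid(ft$fit, exposure)
  back_transform_means(adjusted_ilr_means(fz, gz), basis,
                       adjusted_total(ft, gt))
}
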