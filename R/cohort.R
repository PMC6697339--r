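# Synthetic cohort generator.
#
# Generates cross-sectional and longitudinal cohorts with the statistical
# structure the downstream analysis assumes and known ground-truth effects:
# latent three-part compositions are drawn as ilr-normal (bivariate normal
# balance coordinates given exposure and covariates) with an independent
# log-normal total, mapped to minutes/week, and then coarsened the way the
# questionnaire reports them - screen time as whole daily TV/computer
# hours, walking and sport/DIY through categorical frequency x duration
# scales. Zeros arise from the coarsening itself: participants whose latent
# minutes fall below a reporting threshold answer "none".

LONG_CONTRASTS <- c("stable_active", "inactive_to_active", "active_to_inactive")

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the printed study conditions: baseline composition with
#' geometric means (1270, 18, 51) minutes/week of screen / walking /
#' sport-DIY and arithmetic mean total 1724; 35% active commuters; a
#' commute-mode transition matrix with ~11% of car-only commuters switching
#' to active modes and ~24% the reverse; elapsed time between assessments
#' ~ Normal(4.3, 0.9) years truncated positive; covariate marginals of a
#' middle-aged, predominantly White, employed UK cohort. Residual spread on
#' the balance scale (SDs ~1.3 and ~1.1) and on the log total (~0.5) are
#' calibrated to the precision such cohorts report for commute-mode
#' contrasts.
#'
#' @param n_participants Number of participants.
#' @param commute_active_prob Baseline probability of an active commute.
#' @param baseline_composition Named geometric means (minutes/week) of the
#'   three parts.
#' @param mean_total Arithmetic mean of total discretionary minutes/week.
#' @param followup_composition,followup_mean_total Follow-up analogues
#'   (longitudinal cohorts).
#' @param true_balance_effects Length-2 vector: additive effect of an
#'   active commute on the two default-basis ilr coordinates
#'   (screen-vs-rest, walking-vs-sportdiy). Effects on the first
#'   coordinate of the other pivot sets follow by rotation.
#' @param true_logtotal_effect Additive effect of an active commute on
#'   log total discretionary time.
#' @param long_balance_effects 3 x 2 matrix of follow-up coordinate effects
#'   for stable_active, inactive_to_active, active_to_inactive (vs
#'   stable_inactive).
#' @param long_logtotal_effects Length-3 vector, same contrasts, on the log
#'   total.
#' @param covariate_effects Named list: continuous covariate ->
#'   `c(z1, z2, logtotal)` effect per SD of the covariate.
#' @param confounding Named numeric: continuous covariate -> shift in the
#'   log-odds of active commuting per SD (0 = covariates independent of
#'   exposure).
#' @param zero_rate_walking,zero_rate_sport Fraction of participants
#'   reporting none of the activity (latent minutes below the reporting
#'   threshold).
#' @param residual_covariance 2 x 2 symmetric positive-definite covariance
#'   of the balance-coordinate residuals.
#' @param sd_log_total Residual SD of log total.
#' @param ar_coef Autoregression of coordinates / log total between
#'   assessments (longitudinal).
#' @param transition_matrix 2 x 2 row-stochastic matrix of commute-mode
#'   transitions, rows/cols ordered (inactive, active).
#' @param elapsed_mean_years,elapsed_sd_years Elapsed-time distribution
#'   (truncated positive).
#' @param prob_work_from_home,prob_unable_walk Rates of records destined
#'   for the corresponding exclusion filters.
#' @param missing_rates Named numeric: covariate -> probability of a
#'   missing value (exercises the complete-case and sensitivity paths).
#' @param maps `category_maps` used for the categorical coarsening.
#' @param seed Integer seed; full determinism given the config.
#' @return A `cohort_config` list (validated).
#' @export
cohort_config <- function(n_participants,
                          commute_active_prob = 0.35,
                          baseline_composition = c(screen = 1270, walking = 18, sportdiy = 51),
                          mean_total = 1724,
                          followup_composition = c(screen = 1343, walking = 20, sportdiy = 58),
                          followup_mean_total = 1787,
                          true_balance_effects = c(z1 = 0, z2 = 0),
                          true_logtotal_effect = 0,
                          long_balance_effects = matrix(0, 3, 2, dimnames = list(LONG_CONTRASTS, c("z1", "z2"))),
                          long_logtotal_effects = stats::setNames(numeric(3), LONG_CONTRASTS),
                          covariate_effects = list(),
                          confounding = numeric(0),
                          zero_rate_walking = 0.30,
                          zero_rate_sport = 0.10,
                          residual_covariance = matrix(c(1.69, 0.40, 0.40, 1.21), 2),
                          sd_log_total = 0.5,
                          ar_coef = 0.5,
                          transition_matrix = rbind(c(0.889, 0.111), c(0.243, 0.757)),
                          elapsed_mean_years = 4.3,
                          elapsed_sd_years = 0.9,
                          prob_work_from_home = 0.02,
                          prob_unable_walk = 0.005,
                          missing_rates = numeric(0),
                          maps = default_category_maps(),
                          seed = 1L) {
  stopifnot(n_participants >= 1)
  probs <- c(commute_active_prob, zero_rate_walking, zero_rate_sport,
             prob_work_from_home, prob_unable_walk, missing_rates)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  rc <- as.matrix(residual_covariance)
  if (!isTRUE(all.equal(rc, t(rc))) || any(eigen(rc, only.values = TRUE)$values <= 0)) {
    stop("residual_covariance must be symmetric positive-definite")
  }
  tm <- as.matrix(transition_matrix)
  if (any(dim(tm) != 2L) || any(tm < 0) ||
      !isTRUE(all.equal(rowSums(tm), c(1, 1), tolerance = 1e-8))) {
    stop("transition_matrix must be 2x2 row-stochastic")
  }
  if (!(abs(ar_coef) < 1)) stop("ar_coef must lie in (-1, 1)")
  lbe <- as.matrix(long_balance_effects)
  stopifnot(nrow(lbe) == 3L, ncol(lbe) == 2L)
  rownames(lbe) <- LONG_CONTRASTS
  structure(list(
    n_participants = as.integer(n_participants),
    commute_active_prob = commute_active_prob,
    baseline_composition = baseline_composition[DT_PARTS],
    mean_total = mean_total,
    followup_composition = followup_composition[DT_PARTS],
    followup_mean_total = followup_mean_total,
    true_balance_effects = stats::setNames(as.numeric(true_balance_effects), c("z1", "z2")),
    true_logtotal_effect = true_logtotal_effect,
    long_balance_effects = lbe,
    long_logtotal_effects = stats::setNames(as.numeric(long_logtotal_effects), LONG_CONTRASTS),
    covariate_effects = covariate_effects,
    confounding = confounding,
    zero_rate_walking = zero_rate_walking,
    zero_rate_sport = zero_rate_sport,
    residual_covariance = rc,
    sd_log_total = sd_log_total,
    ar_coef = ar_coef,
    transition_matrix = tm,
    elapsed_mean_years = elapsed_mean_years,
    elapsed_sd_years = elapsed_sd_years,
    prob_work_from_home = prob_work_from_home,
    prob_unable_walk = prob_unable_walk,
    missing_rates = missing_rates,
    maps = maps,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# ---- covariates -----------------------------------------------------------

# Table-1-style marginals of an employed UK cohort aged 40-69.
draw_covariates <- function(n) {
  tibble::tibble(
    age = pmin(pmax(round(stats::rnorm(n, 52.2, 6.9)), 40), 69),
    sex = sample(c("male", "female"), n, TRUE, c(0.493, 0.507)),
    ethnicity = sample(c("white", "mixed", "asian", "black", "chinese", "other"),
                       n, TRUE, c(0.949, 0.006, 0.019, 0.015, 0.003, 0.008)),
    home_owner = sample(c("owner", "other"), n, TRUE, c(0.938, 0.062)),
    car_owner = sample(c("yes", "no"), n, TRUE, c(0.967, 0.033)),
    income = sample(c("<18k", "18-31k", "31-52k", "52-100k", ">100k"),
                    n, TRUE, c(0.067, 0.190, 0.327, 0.330, 0.086)),
    education = sample(c("degree", "further", "higher_secondary", "secondary",
                         "vocational", "professional", "none"),
                       n, TRUE, c(0.390, 0.126, 0.219, 0.071, 0.068, 0.042, 0.085)),
    has_child = sample(c("yes", "no"), n, TRUE, c(0.962, 0.038)),
    townsend = round(pmin(pmax(stats::rnorm(n, -1.7, 2.8), -6.3), 11), 2),
    bmi = round(pmin(pmax(stats::rnorm(n, 27.2, 4.6), 16), 55), 1),
    work_activity = sample(c("sitting", "standing_manual"), n, TRUE, c(0.659, 0.341)),
    fracture = sample(c("no", "yes"), n, TRUE, c(0.914, 0.086)),
    vascular = sample(c("no", "yes"), n, TRUE, c(0.783, 0.217)),
    nonvascular = sample(c("no", "yes"), n, TRUE, c(0.790, 0.210))
  )
}

# Standardised numeric covariate matrix for effect injection.
covariate_design <- function(covs, names_needed) {
  if (length(names_needed) == 0L) return(NULL)
  out <- sapply(names_needed, function(nm) {
    x <- covs[[nm]]
    if (is.null(x)) stop("covariate_effects/confounding names an unknown covariate: ", nm)
    if (!is.numeric(x)) stop("effects are supported for continuous covariates only: ", nm)
    as.numeric(scale(x))
  })
  matrix(out, nrow = nrow(covs), dimnames = list(NULL, names_needed))
}

# ---- categorical coarsening ----------------------------------------------

category_grid <- function(maps) {
  g <- expand.grid(f = seq_along(maps$frequency), d = seq_along(maps$duration))
  list(freq = names(maps$frequency)[g$f],
       dur = names(maps$duration)[g$d],
       value = as.numeric(maps$frequency[g$f] * maps$duration[g$d]))
}

# Nearest category pair on the log scale (deterministic tie-break: first).
match_grid <- function(v, grid) {
  d <- abs(outer(log(v), log(grid$value), "-"))
  max.col(-d, ties.method = "first")
}

# Coarsen latent sport/DIY minutes into 1-2 of the four sport/DIY
# activities; returns a list of per-activity (freq, dur) label vectors.
coarsen_sportdiy <- function(s, report, grid) {
  n <- length(s)
  acts <- ACTIVITIES[-1L] # strenuous_sport, other_sport, light_diy, heavy_diy
  out <- stats::setNames(rep(list(
    list(freq = rep(NA_character_, n), dur = rep(NA_character_, n))), 4L), acts)
  idx <- which(report)
  if (length(idx) == 0L) return(out)
  two <- stats::rbinom(length(idx), 1L, 0.4) == 1L
  primary <- sample.int(4L, length(idx), TRUE, prob = c(0.20, 0.35, 0.25, 0.20))
  secondary <- (primary + sample.int(3L, length(idx), TRUE) - 1L) %% 4L + 1L
  share <- ifelse(two, stats::runif(length(idx), 0.3, 0.7), 1)
  assign_part <- function(rows, act_id, minutes) {
    keep <- minutes > 0
    rows <- rows[keep]; act_id <- act_id[keep]; minutes <- minutes[keep]
    g <- match_grid(minutes, grid)
    for (a in 1:4) {
      sel <- act_id == a
      if (any(sel)) {
        out[[acts[a]]]$freq[rows[sel]] <<- grid$freq[g[sel]]
        out[[acts[a]]]$dur[rows[sel]] <<- grid$dur[g[sel]]
      }
    }
  }
  assign_part(idx, primary, s[idx] * share)
  if (any(two)) {
    assign_part(idx[two], secondary[two], s[idx][two] * (1 - share[two]))
  }
  out
}

# Coarsen one cohort's latent part matrix into raw questionnaire fields.
coarsen_latent <- function(latent, config) {
  n <- nrow(latent)
  grid <- category_grid(config$maps)

  # screen: whole daily TV / computer hours
  h <- latent[, "screen"] / 420
  tv_share <- stats::runif(n, 0.4, 0.8)
  tv <- round(h * tv_share)
  pc <- round(h * (1 - tv_share))

  # walking: report "none" below the threshold implied by the zero rate
  w <- latent[, "walking"]
  tau_w <- stats::quantile(w, config$zero_rate_walking, names = FALSE)
  walk_report <- w >= tau_w
  wf <- rep(NA_character_, n); wd <- rep(NA_character_, n)
  if (any(walk_report)) {
    g <- match_grid(w[walk_report], grid)
    wf[walk_report] <- grid$freq[g]
    wd[walk_report] <- grid$dur[g]
  }

  s <- latent[, "sportdiy"]
  tau_s <- stats::quantile(s, config$zero_rate_sport, names = FALSE)
  sport <- coarsen_sportdiy(s, s >= tau_s, grid)

  list(tv = tv, pc = pc,
       walking_pleasure_freq = wf, walking_pleasure_dur = wd,
       sport = sport, thresholds = c(walking = tau_w, sportdiy = tau_s))
}

# Latent coordinates -> minutes/week matrix.
latent_parts <- function(z, log_total) {
  ilr_inverse(z, default_basis(), total_scale = exp(log_total))
}

# Draw latent balance coordinates and log totals given group effects.
draw_latent <- function(n, config, mean_comp, mean_total, effect_z, effect_t, xeff) {
  mu0 <- drop(ilr_transform(mean_comp))
  s <- config$sd_log_total
  mu_t0 <- log(mean_total) - s^2 / 2   # arithmetic-mean calibration
  mu_z <- matrix(mu0, n, 2, byrow = TRUE) + effect_z
  mu_t <- mu_t0 + effect_t
  if (!is.null(xeff)) {
    mu_z <- mu_z + xeff$z
    mu_t <- mu_t + xeff$t
  }
  eps <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = config$residual_covariance)
  z <- mu_z + eps
  colnames(z) <- c("z1", "z2")
  log_total <- mu_t + stats::rnorm(n, 0, s)
  list(z = z, log_total = log_total, mu_z = mu_z, mu_t = mu_t)
}

# Covariate effect contributions (z and log-total).
covariate_contrib <- function(covs, config) {
  eff <- config$covariate_effects
  if (length(eff) == 0L) return(NULL)
  X <- covariate_design(covs, names(eff))
  B <- do.call(rbind, lapply(eff, function(e) rep_len(as.numeric(e), 3L)))
  contrib <- X %*% B
  list(z = contrib[, 1:2, drop = FALSE], t = contrib[, 3])
}

# Assemble raw questionnaire rows shared by both generators.
assemble_raw <- function(ids, assessment, date, covs, modes, freq, miles,
                         able, coarse) {
  tibble::tibble(
    id = ids,
    assessment = assessment,
    assessment_date = date,
    employed = TRUE,
    commute_modes = modes,
    commute_freq = freq,
    commute_miles = miles,
    able_to_walk = able,
    tv_hours_day = coarse$tv,
    pc_hours_day = coarse$pc,
    walking_pleasure_freq = coarse$walking_pleasure_freq,
    walking_pleasure_dur = coarse$walking_pleasure_dur,
    strenuous_sport_freq = coarse$sport$strenuous_sport$freq,
    strenuous_sport_dur = coarse$sport$strenuous_sport$dur,
    other_sport_freq = coarse$sport$other_sport$freq,
    other_sport_dur = coarse$sport$other_sport$dur,
    light_diy_freq = coarse$sport$light_diy$freq,
    light_diy_dur = coarse$sport$light_diy$dur,
    heavy_diy_freq = coarse$sport$heavy_diy$freq,
    heavy_diy_dur = coarse$sport$heavy_diy$dur
  )
}

draw_commute_modes <- function(active) {
  n <- length(active)
  out <- rep("car", n)
  idx <- which(active)
  if (length(idx) > 0L) {
    out[idx] <- sample(
      c("public_transport", "walk", "cycle", "car|walk",
        "car|public_transport", "walk|cycle"),
      length(idx), TRUE, prob = c(0.35, 0.25, 0.12, 0.10, 0.12, 0.06))
  }
  out
}

inject_missing <- function(covs, missing_rates) {
  for (nm in names(missing_rates)) {
    if (!nm %in% names(covs)) next
    hit <- stats::runif(nrow(covs)) < missing_rates[[nm]]
    covs[[nm]][hit] <- NA
  }
  covs
}

# ---- generators -----------------------------------------------------------

#' Generate a cross-sectional synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return `list(raw = participant table, truth = cohort_truth)`. `raw`
#'   follows the column schema read by [derive_records()]; `truth` stores
#'   the config, the per-participant latent compositions and coordinates
#'   before categorical coarsening, and the reporting thresholds.
#' @export
generate_cross_sectional <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  covs <- draw_covariates(n)

  lp <- stats::qlogis(config$commute_active_prob)
  if (length(config$confounding) > 0L) {
    Xc <- covariate_design(covs, names(config$confounding))
    lp <- lp + drop(Xc %*% as.numeric(config$confounding))
  }
  active <- stats::rbinom(n, 1L, stats::plogis(lp)) == 1L

  xeff <- covariate_contrib(covs, config)
  lat <- draw_latent(n, config,
                     mean_comp = config$baseline_composition,
                     mean_total = config$mean_total,
                     effect_z = outer(as.numeric(active), config$true_balance_effects),
                     effect_t = as.numeric(active) * config$true_logtotal_effect,
                     xeff = xeff)
  parts <- latent_parts(lat$z, lat$log_total)
  coarse <- coarsen_latent(parts, config)

  date0 <- as.Date("2006-03-13") + floor(stats::runif(n, 0, 1662))
  freq <- pmin(pmax(round(stats::rnorm(n, 4.6, 1.6)), 1), 10)
  miles <- round(pmin(stats::rlnorm(n, log(6), 1.0), 200), 1)
  miles[miles < 0.1] <- 0.1
  wfh <- stats::runif(n) < config$prob_work_from_home
  freq[wfh] <- 0
  able <- stats::runif(n) >= config$prob_unable_walk

  raw <- assemble_raw(seq_len(n), 0L, date0, covs,
                      draw_commute_modes(active), freq, miles, able, coarse)
  raw <- tibble::as_tibble(cbind(raw, inject_missing(covs, config$missing_rates)))

  truth <- structure(list(
    config = config,
    latent = tibble::as_tibble(cbind(
      tibble::tibble(id = seq_len(n), active = active),
      as.data.frame(parts),
      tibble::tibble(total = exp(lat$log_total),
                     z1 = lat$z[, 1], z2 = lat$z[, 2],
                     log_total = lat$log_total))),
    thresholds = coarse$thresholds
  ), class = "cohort_truth")
  list(raw = raw, truth = truth)
}

#' Generate a longitudinal synthetic cohort (baseline + first repeat)
#'
#' Baseline is generated as in [generate_cross_sectional()]; the follow-up
#' commute mode is drawn from the transition matrix, and the follow-up
#' composition is autoregressive in the baseline coordinates with additive
#' commute-change effects. Elapsed time between assessments is
#' Normal(mean, sd) truncated positive, so seasons vary between
#' assessments.
#'
#' @param config A [cohort_config()].
#' @return `list(raw = table with baseline (assessment 0) and follow-up
#'   (assessment 1) rows, truth = cohort_truth)`. `truth$long_true_coef` /
#'   `truth$long_true_total_coef` hold the regression coefficients implied
#'   for the follow-up-adjusted-for-baseline model (they equal the
#'   configured change effects, minus the autoregressive carry-over of any
#'   baseline exposure effect for groups active at baseline).
#' @export
generate_longitudinal <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  covs <- draw_covariates(n)

  lp <- stats::qlogis(config$commute_active_prob)
  if (length(config$confounding) > 0L) {
    Xc <- covariate_design(covs, names(config$confounding))
    lp <- lp + drop(Xc %*% as.numeric(config$confounding))
  }
  active0 <- stats::rbinom(n, 1L, stats::plogis(lp)) == 1L
  p_stay <- ifelse(active0, config$transition_matrix[2, 2], config$transition_matrix[1, 2])
  active1 <- stats::rbinom(n, 1L, p_stay) == 1L
  change <- code_commute_change(ifelse(active0, "active", "inactive"),
                                ifelse(active1, "active", "inactive"))

  xeff <- covariate_contrib(covs, config)
  lat0 <- draw_latent(n, config,
                      mean_comp = config$baseline_composition,
                      mean_total = config$mean_total,
                      effect_z = outer(as.numeric(active0), config$true_balance_effects),
                      effect_t = as.numeric(active0) * config$true_logtotal_effect,
                      xeff = xeff)
  parts0 <- latent_parts(lat0$z, lat0$log_total)

  rho <- config$ar_coef
  eff_z <- matrix(0, n, 2)
  eff_t <- numeric(n)
  for (g in LONG_CONTRASTS) {
    sel <- which(change == g)
    if (length(sel) == 0L) next
    eff_z[sel, ] <- matrix(config$long_balance_effects[g, ], length(sel), 2,
                           byrow = TRUE)
    eff_t[sel] <- config$long_logtotal_effects[g]
  }
  mu_fu <- drop(ilr_transform(config$followup_composition))
  s <- config$sd_log_total
  mu_t_fu <- log(config$followup_mean_total) - s^2 / 2
  eps <- MASS::mvrnorm(n, c(0, 0), config$residual_covariance * (1 - rho^2))
  z1m <- matrix(mu_fu, n, 2, byrow = TRUE) + rho * (lat0$z - lat0$mu_z) + eff_z
  if (!is.null(xeff)) z1m <- z1m + xeff$z
  zf <- z1m + eps
  colnames(zf) <- c("z1", "z2")
  log_total_f <- mu_t_fu + eff_t + (if (is.null(xeff)) 0 else xeff$t) +
    rho * (lat0$log_total - lat0$mu_t) + stats::rnorm(n, 0, s * sqrt(1 - rho^2))
  parts1 <- latent_parts(zf, log_total_f)

  coarse0 <- coarsen_latent(parts0, config)
  coarse1 <- coarsen_latent(parts1, config)

  date0 <- as.Date("2006-03-13") + floor(stats::runif(n, 0, 1662))
  elapsed <- rnorm_trunc(n, config$elapsed_mean_years, config$elapsed_sd_years, lower = 0.5)
  date1 <- date0 + round(elapsed * 365.25)
  freq <- pmin(pmax(round(stats::rnorm(n, 4.6, 1.4)), 1), 10)
  miles <- round(pmin(stats::rlnorm(n, log(6), 1.0), 200), 1)
  miles[miles < 0.1] <- 0.1
  wfh <- stats::runif(n) < config$prob_work_from_home
  freq[wfh] <- 0
  able <- stats::runif(n) >= config$prob_unable_walk

  covs_m <- inject_missing(covs, config$missing_rates)
  raw0 <- assemble_raw(seq_len(n), 0L, date0, covs,
                       draw_commute_modes(active0), freq, miles, able, coarse0)
  raw1 <- assemble_raw(seq_len(n), 1L, date1, covs,
                       draw_commute_modes(active1), freq, miles, able, coarse1)
  raw <- rbind(tibble::as_tibble(cbind(raw0, covs_m)),
               tibble::as_tibble(cbind(raw1, covs_m)))

  # Regression coefficients implied for follow-up ~ baseline + change:
  # the AR term carries -rho * baseline effect for groups active at baseline.
  carry <- cbind(stable_active = 1, inactive_to_active = 0, active_to_inactive = 1)
  long_true_coef <- config$long_balance_effects -
    rho * outer(drop(carry), config$true_balance_effects)
  long_true_total_coef <- config$long_logtotal_effects -
    rho * drop(carry) * config$true_logtotal_effect

  truth <- structure(list(
    config = config,
    latent = tibble::as_tibble(cbind(
      tibble::tibble(id = rep(seq_len(n), 2L),
                     assessment = rep(c(0L, 1L), each = n),
                     active = c(active0, active1),
                     change = rep(as.character(change), 2L)),
      as.data.frame(rbind(parts0, parts1)),
      tibble::tibble(total = exp(c(lat0$log_total, log_total_f)),
                     z1 = c(lat0$z[, 1], zf[, 1]),
                     z2 = c(lat0$z[, 2], zf[, 2])))),
    thresholds = rbind(baseline = coarse0$thresholds, followup = coarse1$thresholds),
    long_true_coef = long_true_coef,
    long_true_total_coef = long_true_total_coef
  ), class = "cohort_truth")
  list(raw = raw, truth = truth)
}
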