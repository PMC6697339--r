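# End-to-end orchestration: generate (or accept) raw records -> derive ->
# exclude -> impute -> transform -> fit all tiers -> adjusted means ->
# descriptive tables, with an exclusion ledger and a stage log.

#' Pipeline run configuration
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort, or
#'   `NULL` when `raw_cross_sectional` / `raw_longitudinal` tables are
#'   supplied directly.
#' @param mode Which analyses to run.
#' @param tiers Model tiers to fit (subset of 1:3).
#' @param sensitivity Also run the variant dropping income / children from
#'   the adjustment sets (rerun on the enlarged complete-case sample).
#' @param maps `category_maps` for the derivation step.
#' @param detection_limits Named per-part detection limits for zero
#'   imputation; default: the per-activity smallest observable value from
#'   `maps` for walking, and its double for the amalgamated sport/DIY part.
#' @param raw_cross_sectional,raw_longitudinal Pre-existing raw tables
#'   (same schema as the generator output); used instead of `cohort`.
#' @param out_dir If non-`NULL`, all bundle tables are written there as
#'   tab-delimited text plus a run log and a config echo.
#' @param seed Root seed; defaults to the cohort seed.
#' @return A `run_config`.
#' @export
run_config <- function(cohort = NULL,
                       mode = c("cross_sectional", "longitudinal", "both"),
                       tiers = 1:3, sensitivity = FALSE,
                       maps = default_category_maps(),
                       detection_limits = NULL,
                       raw_cross_sectional = NULL, raw_longitudinal = NULL,
                       out_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(cohort) && is.null(raw_cross_sectional) && is.null(raw_longitudinal)) {
    stop("provide either a cohort config or raw input tables")
  }
  if (!is.null(cohort) && (!is.null(raw_cross_sectional) || !is.null(raw_longitudinal))) {
    stop("provide exactly one input source (synthetic cohort or raw tables)")
  }
  if (is.null(seed)) seed <- if (!is.null(cohort)) cohort$seed else 1L
  if (is.null(detection_limits)) {
    detection_limits <- c(walking = maps$detection_limit,
                          sportdiy = 2 * maps$detection_limit)
  }
  structure(list(cohort = cohort, mode = mode, tiers = sort(unique(tiers)),
                 sensitivity = sensitivity, maps = maps,
                 detection_limits = detection_limits,
                 raw_cross_sectional = raw_cross_sectional,
                 raw_longitudinal = raw_longitudinal,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

part_matrix_from_records <- function(records) {
  m <- as.matrix(records[, paste0(DT_PARTS, "_min_wk")])
  colnames(m) <- DT_PARTS
  m
}

# Derive + exclude + impute + transform one assessment's records.
prepare_analysis <- function(raw, maps, dl, sensitivity = FALSE) {
  derived <- derive_records(raw, maps)
  req <- c(TIER2_COVARIATES, TIER3_EXTRA)
  if (sensitivity) req <- setdiff(req, c("income", "has_child"))
  excl <- apply_exclusions(derived, required_covariates = req)
  rec <- excl$records
  rawm <- part_matrix_from_records(rec)
  imputed <- replace_zeros(rawm, dl = dl)
  bases <- pivot_bases()
  zs <- ilr_transform(imputed, bases$screen)
  rec$z1 <- zs[, 1]
  rec$z2 <- zs[, 2]
  rec$balance_screen <- zs[, 1]
  rec$balance_walking <- ilr_transform(imputed, bases$walking)[, 1]
  rec$balance_sportdiy <- ilr_transform(imputed, bases$sportdiy)[, 1]
  list(records = rec, ledger = excl$ledger, raw_parts = rawm,
       imputed = imputed, n_in = nrow(derived))
}

# Tidy table of exposure contrasts across tiers (Table 3 / Table 6 shape).
fits_contrast_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    ct <- f$contrasts
    ct$outcome <- f$outcome
    ct$tier <- f$tier
    ct$n <- f$n
    ct$variant <- f$variant
    ct[, c("variant", "outcome", "tier", "n", "term", "estimate",
           "conf.low", "conf.high", "p.value")]
  }))
}

fits_multivariate_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    if (is.null(f$multivariate)) return(NULL)
    mv <- f$multivariate
    mv$tier <- f$tier
    mv$n <- f$n
    mv$variant <- f$variant
    mv
  }))
}

# Table-1-shaped covariate descriptives.
describe_covariates <- function(records,
                                covariates = c(TIER2_COVARIATES, TIER3_EXTRA)) {
  covariates <- intersect(covariates, names(records))
  rows <- lapply(covariates, function(nm) {
    x <- records[[nm]]
    if (is.numeric(x)) {
      tibble::tibble(variable = nm, level = NA_character_,
                     mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
                     n = NA_integer_, pct = NA_real_)
    } else {
      tab <- table(x, useNA = "no")
      tibble::tibble(variable = nm, level = names(tab),
                     mean = NA_real_, sd = NA_real_,
                     n = as.integer(tab), pct = 100 * as.integer(tab) / sum(tab))
    }
  })
  do.call(rbind, rows)
}

fit_all_tiers <- function(records, exposure, tiers, longitudinal = FALSE,
                          sensitivity = FALSE, extra_covariates = NULL) {
  balances <- c("balance_screen", "balance_walking", "balance_sportdiy")
  fits <- list(multivariate = list(), balance = list(), total = list())
  for (tier in tiers) {
    covs <- c(extra_covariates,
              tier_covariates(tier, longitudinal, sensitivity))
    if (longitudinal) {
      for (b in balances) {
        fits$balance[[paste0(b, "_t", tier)]] <-
          fit_longitudinal(records, paste0(b, "_fu"), paste0(b, "_bl"),
                           exposure, tier, sensitivity = sensitivity)
      }
      fits$total[[paste0("total_t", tier)]] <-
        fit_longitudinal(records, "log_total_fu", "log_total_bl",
                         exposure, tier, sensitivity = sensitivity)
      fits$multivariate[[paste0("t", tier)]] <-
        fit_coordinate_set(records, c("z1_fu", "z2_fu"), exposure, tier,
                           covariates = c("z1_bl", "z2_bl", covs),
                           sensitivity = sensitivity)
    } else {
      fits$multivariate[[paste0("t", tier)]] <-
        fit_coordinate_set(records, c("z1", "z2"), exposure, tier,
                           covariates = covs, sensitivity = sensitivity)
      for (b in balances) {
        fits$balance[[paste0(b, "_t", tier)]] <-
          fit_balance_model(records, b, exposure, tier, covariates = covs,
                            sensitivity = sensitivity)
      }
      fits$total[[paste0("total_t", tier)]] <-
        fit_total_model(records, "total_min_wk", exposure, tier,
                        covariates = covs, sensitivity = sensitivity)
    }
  }
  fits
}

# Assemble the paired (baseline + follow-up) analysis table.
pair_longitudinal <- function(prep0, prep1) {
  r0 <- prep0$records
  r1 <- prep1$records
  ids <- intersect(r0$id, r1$id)
  r0 <- r0[match(ids, r0$id), ]
  r1 <- r1[match(ids, r1$id), ]
  fu <- derive_followup_covariates(r0$assessment_date, r1$assessment_date)
  out <- r0[, setdiff(names(r0), c("z1", "z2", "balance_screen",
                                   "balance_walking", "balance_sportdiy"))]
  out$commute_change <- code_commute_change(r0$commute_class, r1$commute_class)
  out$years_elapsed <- fu$years_elapsed
  out$season_differs <- fu$season_differs
  for (b in c("z1", "z2", "balance_screen", "balance_walking", "balance_sportdiy")) {
    out[[paste0(b, "_bl")]] <- r0[[b]]
    out[[paste0(b, "_fu")]] <- r1[[b]]
  }
  out$log_total_bl <- log(r0$total_min_wk)
  out$log_total_fu <- log(r1$total_min_wk)
  out$total_fu <- r1$total_min_wk
  out
}

run_cross_sectional <- function(raw, config, sensitivity = FALSE) {
  prep <- prepare_analysis(raw, config$maps, config$detection_limits,
                           sensitivity = sensitivity)
  rec <- prep$records
  fits <- fit_all_tiers(rec, "commute_class", config$tiers,
                        sensitivity = sensitivity)
  max_tier <- max(config$tiers)
  adj <- adjusted_means(rec, coords = c("z1", "z2"), total = "total_min_wk",
                        exposure = "commute_class", tier = max_tier,
                        covariates = tier_covariates(max_tier, FALSE, sensitivity))
  list(
    n_in = prep$n_in, n_analysis = nrow(rec),
    exclusions = prep$ledger,
    covariate_descriptives = describe_covariates(rec),
    composition_descriptives = describe_composition(prep$raw_parts, prep$imputed),
    fits = fits,
    fits_balance = fits_contrast_table(c(fits$balance, fits$total)),
    fits_multivariate = fits_multivariate_table(fits$multivariate),
    adjusted_means = adj
  )
}

run_longitudinal <- function(raw, config, sensitivity = FALSE) {
  prep0 <- prepare_analysis(raw[raw$assessment == 0L, ], config$maps,
                            config$detection_limits, sensitivity)
  prep1 <- prepare_analysis(raw[raw$assessment == 1L, ], config$maps,
                            config$detection_limits, sensitivity)
  pairs <- pair_longitudinal(prep0, prep1)
  fits <- fit_all_tiers(pairs, "commute_change", config$tiers,
                        longitudinal = TRUE, sensitivity = sensitivity)
  max_tier <- max(config$tiers)
  adj <- adjusted_means(
    pairs, coords = c("z1_fu", "z2_fu"), total = "total_fu",
    exposure = "commute_change", tier = max_tier,
    covariates = c("z1_bl", "z2_bl", "log_total_bl",
                   tier_covariates(max_tier, TRUE, sensitivity)))
  desc <- rbind(
    cbind(assessment = "baseline",
          describe_composition(prep0$raw_parts, prep0$imputed)),
    cbind(assessment = "followup",
          describe_composition(prep1$raw_parts, prep1$imputed))
  )
  list(
    n_in = prep0$n_in, n_analysis = nrow(pairs),
    exclusions = rbind(cbind(assessment = "baseline", prep0$ledger),
                       cbind(assessment = "followup", prep1$ledger)),
    covariate_descriptives = describe_covariates(pairs),
    composition_descriptives = tibble::as_tibble(desc),
    fits = fits,
    fits_balance = fits_contrast_table(c(fits$balance, fits$total)),
    fits_multivariate = fits_multivariate_table(fits$multivariate),
    adjusted_means = adj
  )
}

#' Run the full analysis pipeline
#'
#' Generate -> derive -> exclude -> impute -> transform -> fit ->
#' marginalise, emitting descriptive tables, fit tables across tiers,
#' adjusted compositional means, exclusion ledgers and a stage log. With a
#' fixed seed the whole bundle is reproducible.
#'
#' @param config A [run_config()].
#' @return A named bundle (list) with `cross_sectional` and/or
#'   `longitudinal` results, the stage `log`, and the echoed config. When
#'   `config$out_dir` is set, every table is also written there as
#'   tab-delimited text.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- tibble::tibble(stage = stage, n_in = n_in,
                                               n_out = n_out)
  }
  bundle <- list(seed = config$seed)
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (config$mode %in% c("cross_sectional", "both")) {
    raw <- with_stage("simulate", {
      if (!is.null(config$cohort)) generate_cross_sectional(config$cohort)$raw
      else config$raw_cross_sectional
    })
    if (is.null(raw)) stop("no cross-sectional input available")
    cs <- with_stage("cross_sectional", run_cross_sectional(raw, config))
    note("cross_sectional", cs$n_in, cs$n_analysis)
    bundle$cross_sectional <- cs
    if (config$sensitivity) {
      css <- with_stage("cross_sectional_sensitivity",
                        run_cross_sectional(raw, config, sensitivity = TRUE))
      note("cross_sectional_sensitivity", css$n_in, css$n_analysis)
      bundle$cross_sectional_sensitivity <- css
    }
  }
  if (config$mode %in% c("longitudinal", "both")) {
    rawl <- with_stage("simulate_longitudinal", {
      if (!is.null(config$cohort)) generate_longitudinal(config$cohort)$raw
      else config$raw_longitudinal
    })
    if (is.null(rawl)) stop("no longitudinal input available")
    lg <- with_stage("longitudinal", run_longitudinal(rawl, config))
    note("longitudinal", lg$n_in, lg$n_analysis)
    bundle$longitudinal <- lg
    if (config$sensitivity) {
      lgs <- with_stage("longitudinal_sensitivity",
                        run_longitudinal(rawl, config, sensitivity = TRUE))
      note("longitudinal_sensitivity", lgs$n_in, lgs$n_analysis)
      bundle$longitudinal_sensitivity <- lgs
    }
  }
  bundle$log <- do.call(rbind, log)
  if (!is.null(config$out_dir)) write_bundle(bundle, config)
  invisible(bundle)
}

# Write every tabular bundle element as tab-delimited text plus a run log.
write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(x, name) {
    utils::write.table(x, file.path(config$out_dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (scope in intersect(names(bundle),
                          c("cross_sectional", "cross_sectional_sensitivity",
                            "longitudinal", "longitudinal_sensitivity"))) {
    res <- bundle[[scope]]
    for (tab in c("exclusions", "covariate_descriptives",
                  "composition_descriptives", "fits_balance",
                  "fits_multivariate", "adjusted_means")) {
      if (!is.null(res[[tab]])) emit(res[[tab]], paste(scope, tab, sep = "_"))
    }
  }
  emit(bundle$log, "run_log")
  cfg <- config[c("mode", "tiers", "sensitivity", "seed", "detection_limits")]
  cfg$cohort_n <- if (!is.null(config$cohort)) config$cohort$n_participants else NA
  writeLines(paste(names(unlist(cfg)), unlist(cfg), sep = "\t"),
             file.path(config$out_dir, "config_echo.tsv"))
  invisible(NULL)
}

#' Sensitivity analysis: drop income and children from the adjustment sets
#'
#' Reruns the cross-sectional (and, for paired input, longitudinal)
#' analysis with income and household children removed from tiers >= 2,
#' which enlarges the complete-case sample when those covariates carry
#' missing values. Outputs are tagged `"sensitivity"`.
#'
#' @param raw Raw participant table (cross-sectional schema, or with both
#'   assessments for longitudinal mode).
#' @param config A [run_config()] (its `mode` decides what is rerun).
#' @return The sensitivity-analysis result list (same shape as the main
#'   analysis element of the pipeline bundle).
#' @export
run_sensitivity <- function(raw, config) {
  if (config$mode == "longitudinal") {
    run_longitudinal(raw, config, sensitivity = TRUE)
  } else {
    run_cross_sectional(raw, config, sensitivity = TRUE)
  }
}
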