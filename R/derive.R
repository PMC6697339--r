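# Derivation of analysis variables from raw questionnaire responses.
#
# Raw participant records (one row per participant per assessment) carry:
# commute mode selections, commute frequency/distance, TV and computer
# hours/day, five discretionary-activity (frequency, duration) category
# responses, covariates and the assessment date. This module codes them
# into the analysis variables: commute class, the three-part
# discretionary-time subcomposition in minutes/week, and follow-up
# covariates - and applies the exclusion filters in a fixed order.

TRAVEL_MODES <- c("car", "public_transport", "walk", "cycle")

ACTIVITIES <- c("walking_pleasure", "strenuous_sport", "other_sport",
                "light_diy", "heavy_diy")

COMMUTE_CHANGE_LEVELS <- c("stable_inactive", "stable_active",
                           "inactive_to_active", "active_to_inactive")

# Covariate sets used by the model tiers and the complete-case filter.
TIER2_COVARIATES <- c("commute_freq", "commute_miles", "age", "sex",
                      "ethnicity", "home_owner", "car_owner", "income",
                      "education", "has_child", "townsend")
TIER3_EXTRA <- c("bmi", "work_activity", "fracture", "vascular", "nonvascular")

#' Category-to-value maps for activity frequency and duration
#'
#' Frequency categories map to occasions/week (monthly categories are
#' divided by the number of weeks in an average month,
#' `365.25 / 7 / 12 ~ 4.348`); duration categories map to the midpoint of
#' the category in minutes (e.g. 22.5 for "15-30 minutes"). The full
#' questionnaire category lists are configurable; these defaults anchor on
#' the standard scales used in large UK cohort questionnaires.
#'
#' @param monthly_divisor Weeks per month used to convert monthly to weekly
#'   frequencies.
#' @param open_duration_midpoint Nominal value (minutes) for the open-ended
#'   top duration category.
#' @return A `category_maps` list: `frequency` and `duration` named numeric
#'   vectors plus the per-activity `detection_limit` (lowest frequency x
#'   lowest duration midpoint), i.e. the smallest observable non-zero
#'   minutes/week.
#' @export
default_category_maps <- function(monthly_divisor = 365.25 / 7 / 12,
                                  open_duration_midpoint = 240) {
  frequency <- c(
    "once a month"        = 1 / monthly_divisor,
    "2-3 times a month"   = 2.5 / monthly_divisor,
    "once a week"         = 1,
    "2-3 times a week"    = 2.5,
    "4-5 times a week"    = 4.5,
    "every day"           = 7
  )
  duration <- c(
    "less than 15 minutes" = 7.5,
    "15-30 minutes"        = 22.5,
    "30-60 minutes"        = 45,
    "1-1.5 hours"          = 75,
    "1.5-2 hours"          = 105,
    "2-3 hours"            = 150,
    "over 3 hours"         = open_duration_midpoint
  )
  structure(list(frequency = frequency, duration = duration,
                 detection_limit = min(frequency) * min(duration)),
            class = "category_maps")
}

#' Dichotomise commute mode
#'
#' Car only is inactive; any other mode or combination of modes (including
#' combinations containing the car) is active.
#'
#' @param modes Character vector of selected modes for one participant, or
#'   a single `|`-separated string (e.g. `"car|walk"`); vectorised over a
#'   character vector of such strings via [code_commute_mode_vec()].
#' @return `"inactive"` or `"active"`.
#' @examples
#' code_commute_mode("car")            # inactive
#' code_commute_mode(c("car", "walk")) # active
#' @export
code_commute_mode <- function(modes) {
  if (length(modes) == 1L && grepl("|", modes, fixed = TRUE)) {
    modes <- strsplit(modes, "|", fixed = TRUE)[[1L]]
  }
  modes <- modes[!is.na(modes) & nzchar(modes)]
  if (length(modes) == 0L) stop("missing commute mode (empty selection)")
  bad <- setdiff(modes, TRAVEL_MODES)
  if (length(bad) > 0L) stop("unknown travel mode: ", paste(bad, collapse = ", "))
  if (identical(sort(unique(modes)), "car")) "inactive" else "active"
}

#' @rdname code_commute_mode
#' @param mode_strings Character vector of `|`-separated mode selections;
#'   `NA`/empty entries give `NA`.
#' @export
code_commute_mode_vec <- function(mode_strings) {
  vapply(mode_strings, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    code_commute_mode(s)
  }, character(1), USE.NAMES = FALSE)
}

#' Four-category commute change between two assessments
#'
#' @param baseline,followup Commute class (`"inactive"`/`"active"`) at
#'   baseline and follow-up; vectorised.
#' @return Factor with levels stable_inactive, stable_active,
#'   inactive_to_active, active_to_inactive.
#' @export
code_commute_change <- function(baseline, followup) {
  if (any(is.na(baseline)) || any(is.na(followup))) {
    stop("commute class missing at one assessment")
  }
  ok <- c("inactive", "active")
  if (!all(baseline %in% ok) || !all(followup %in% ok)) {
    stop("commute class must be 'inactive' or 'active'")
  }
  out <- ifelse(baseline == "inactive",
                ifelse(followup == "inactive", "stable_inactive", "inactive_to_active"),
                ifelse(followup == "active", "stable_active", "active_to_inactive"))
  factor(out, levels = COMMUTE_CHANGE_LEVELS)
}

#' Weekly screen time from daily TV and computer hours
#'
#' TV and computer hours are summed to daily screen time, the sum truncated
#' at nine hours/day, and converted to minutes/week. A zero result flags the
#' record for exclusion downstream (screen time is the complete part).
#'
#' @param tv_hours_day,pc_hours_day Non-negative daily hours; vectorised.
#' @return Minutes/week, `min(tv + pc, 9) * 60 * 7`.
#' @examples
#' derive_screen_time(4, 2) # 2520
#' derive_screen_time(6, 6) # truncated: 3780
#' @export
derive_screen_time <- function(tv_hours_day, pc_hours_day) {
  if (any(tv_hours_day < 0, na.rm = TRUE) || any(pc_hours_day < 0, na.rm = TRUE)) {
    stop("negative daily hours")
  }
  pmin(tv_hours_day + pc_hours_day, 9) * 60 * 7
}

#' Minutes/week from an activity's frequency and duration categories
#'
#' Weekly frequency (occasions/week) times the midpoint duration of the
#' category. An absent response (participant did not undertake the
#' activity) codes to 0 minutes/week - a rounded zero handled later by
#' imputation.
#'
#' @param frequency_category,duration_category Category labels (vectorised);
#'   `NA` in either = no response.
#' @param maps A `category_maps` object.
#' @return Minutes/week.
#' @examples
#' maps <- default_category_maps()
#' code_activity_minutes("2-3 times a week", "15-30 minutes", maps) # 56.25
#' @export
code_activity_minutes <- function(frequency_category, duration_category,
                                  maps = default_category_maps()) {
  n <- max(length(frequency_category), length(duration_category))
  frequency_category <- rep_len(as.character(frequency_category), n)
  duration_category <- rep_len(as.character(duration_category), n)
  absent <- is.na(frequency_category) & is.na(duration_category)
  present <- !absent
  badf <- present & !(frequency_category %in% names(maps$frequency))
  if (any(badf)) {
    stop("unknown frequency category: ",
         paste(unique(frequency_category[badf]), collapse = ", "))
  }
  badd <- present & !(duration_category %in% names(maps$duration))
  if (any(badd)) {
    stop("unknown duration category: ",
         paste(unique(duration_category[badd]), collapse = ", "))
  }
  out <- numeric(n)
  out[present] <- maps$frequency[frequency_category[present]] *
    maps$duration[duration_category[present]]
  out
}

#' Elapsed years and season change between two assessment dates
#'
#' Seasons are meteorological quarters (DJF / MAM / JJA / SON).
#'
#' @param date0,date1 Baseline and follow-up dates (`Date` or parseable);
#'   vectorised. `date1` must be strictly after `date0`.
#' @return A tibble with `years_elapsed` (= days / 365.25) and
#'   `season_differs`.
#' @export
derive_followup_covariates <- function(date0, date1) {
  date0 <- as.Date(date0)
  date1 <- as.Date(date1)
  if (any(date1 <= date0)) stop("follow-up date not after baseline date")
  tibble::tibble(
    years_elapsed = as.numeric(date1 - date0) / 365.25,
    season_differs = meteorological_season(date0) != meteorological_season(date1)
  )
}

#' Build the three-part discretionary-time subcomposition
#'
#' Walking for pleasure stands alone; strenuous and other sports are
#' combined with light and heavy DIY into one sport/DIY part. The total is
#' the sum of the three parts; totals above 10080 minutes (24 h/day) flag
#' the record for exclusion.
#'
#' @param screen_min_wk,walking_min_wk,strenuous_min_wk,other_sport_min_wk,light_diy_min_wk,heavy_diy_min_wk
#'   Coded minutes/week (vectorised).
#' @return Tibble with `screen_min_wk`, `walking_min_wk`, `sportdiy_min_wk`,
#'   `total_min_wk` and `flag_over_24h`.
#' @export
build_subcomposition <- function(screen_min_wk, walking_min_wk,
                                 strenuous_min_wk = 0, other_sport_min_wk = 0,
                                 light_diy_min_wk = 0, heavy_diy_min_wk = 0) {
  sportdiy <- strenuous_min_wk + other_sport_min_wk +
    light_diy_min_wk + heavy_diy_min_wk
  total <- screen_min_wk + walking_min_wk + sportdiy
  tibble::tibble(
    screen_min_wk = screen_min_wk,
    walking_min_wk = walking_min_wk,
    sportdiy_min_wk = sportdiy,
    total_min_wk = total,
    flag_over_24h = total > 10080
  )
}

#' Derive analysis variables for a raw participant table
#'
#' Applies [code_commute_mode_vec()], [derive_screen_time()],
#' [code_activity_minutes()] and [build_subcomposition()] to a raw table
#' (see [generate_cross_sectional()] for the column schema) without yet
#' excluding anyone.
#'
#' @param raw Raw participant table.
#' @param maps `category_maps`.
#' @return Tibble of derived records (one per row of `raw`).
#' @export
derive_records <- function(raw, maps = default_category_maps()) {
  act <- lapply(ACTIVITIES, function(a) {
    code_activity_minutes(raw[[paste0(a, "_freq")]],
                          raw[[paste0(a, "_dur")]], maps)
  })
  names(act) <- ACTIVITIES
  sub <- build_subcomposition(
    screen_min_wk = derive_screen_time(raw$tv_hours_day, raw$pc_hours_day),
    walking_min_wk = act$walking_pleasure,
    strenuous_min_wk = act$strenuous_sport,
    other_sport_min_wk = act$other_sport,
    light_diy_min_wk = act$light_diy,
    heavy_diy_min_wk = act$heavy_diy
  )
  keep <- intersect(
    c("id", "assessment", "assessment_date", "employed", "commute_modes",
      "commute_freq", "commute_miles", "able_to_walk",
      TIER2_COVARIATES, TIER3_EXTRA),
    names(raw)
  )
  out <- tibble::as_tibble(raw[, keep])
  out$commute_class <- code_commute_mode_vec(raw$commute_modes)
  tibble::as_tibble(cbind(out, sub))
}

#' Apply the exclusion filters
#'
#' Drops, in order, records that are: (1) not employed or without a commute
#' mode; (2) assumed to work from home (commute frequency < 1/week or
#' distance 0 miles); (3) unable to walk; (4) reporting zero screen time
#' (the complete part must be positive); (5) reporting more than the
#' equivalent of 24 h/day of discretionary time; (6) incomplete on
#' exposure, outcome or any required covariate (complete-case filter, last,
#' mirroring the sample-flow ordering). Each dropped record is counted once
#' under the first applicable reason.
#'
#' @param records Derived records from [derive_records()].
#' @param required_covariates Covariates that must be non-missing; the
#'   sensitivity analysis passes this list without income / children.
#' @return `list(records = retained tibble, ledger = tibble(reason, n))`;
#'   ledger counts sum to `nrow(records) - nrow(retained)`.
#' @export
apply_exclusions <- function(records,
                             required_covariates = c(TIER2_COVARIATES, TIER3_EXTRA)) {
  required_covariates <- intersect(required_covariates, names(records))
  n0 <- nrow(records)
  reasons <- c("not_employed_or_no_commute", "works_from_home",
               "unable_to_walk", "zero_screen_time",
               "over_24h_discretionary", "incomplete_covariates")
  drop_reason <- rep(NA_character_, n0)

  mark <- function(cond, reason) {
    cond[is.na(cond)] <- FALSE
    idx <- cond & is.na(drop_reason)
    drop_reason[idx] <<- reason
  }
  no_mode <- is.na(records$commute_modes) | !nzchar(records$commute_modes)
  mark(!records$employed | no_mode, "not_employed_or_no_commute")
  mark(records$commute_freq < 1 | records$commute_miles == 0, "works_from_home")
  mark(!records$able_to_walk, "unable_to_walk")
  mark(records$screen_min_wk == 0, "zero_screen_time")
  mark(records$total_min_wk > 10080, "over_24h_discretionary")
  incomplete <- Reduce(`|`, lapply(records[required_covariates], is.na),
                       rep(FALSE, n0)) | is.na(records$commute_class)
  mark(incomplete, "incomplete_covariates")

  ledger <- tibble::tibble(
    reason = reasons,
    n = vapply(reasons, function(r) sum(drop_reason == r, na.rm = TRUE), integer(1))
  )
  list(records = records[is.na(drop_reason), , drop = FALSE], ledger = ledger)
}
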