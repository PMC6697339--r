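# Shared helpers: run the derive -> exclude -> impute -> transform chain on
# a raw table using only exported functions, and small fixture builders.

prep_analysis <- function(raw, dl = NULL, maps = default_category_maps()) {
  derived <- derive_records(raw, maps)
  ex <- apply_exclusions(derived)
  rec <- ex$records
  m <- as.matrix(rec[, paste0(DT_PARTS, "_min_wk")])
  colnames(m) <- DT_PARTS
  if (is.null(dl)) {
    dl <- c(walking = maps$detection_limit, sportdiy = 2 * maps$detection_limit)
  }
  imp <- replace_zeros(m, dl = dl)
  bases <- pivot_bases()
  rec$z1 <- ilr_transform(imp, bases$screen)[, 1]
  rec$z2 <- ilr_transform(imp, bases$screen)[, 2]
  rec$balance_screen <- rec$z1
  rec$balance_walking <- ilr_transform(imp, bases$walking)[, 1]
  rec$balance_sportdiy <- ilr_transform(imp, bases$sportdiy)[, 1]
  list(records = rec, raw_parts = m, imputed = imp, ledger = ex$ledger)
}

# Random strictly positive composition table on a realistic scale.
random_parts <- function(n, seed = 1) {
  set.seed(seed)
  matrix(exp(stats::rnorm(n * 3, mean = c(7, 3, 4), sd = 1)),
         ncol = 3, byrow = TRUE, dimnames = list(NULL, DT_PARTS))
}

# Minimal raw participant row for derive-level tests.
raw_row <- function(id = 1L, commute_modes = "car", commute_freq = 5,
                    commute_miles = 6, able_to_walk = TRUE, employed = TRUE,
                    tv = 3, pc = 1,
                    walking_freq = "2-3 times a week",
                    walking_dur = "15-30 minutes",
                    income = "31-52k", age = 50) {
  tibble::tibble(
    id = id, assessment = 0L, assessment_date = as.Date("2008-07-01"),
    employed = employed, commute_modes = commute_modes,
    commute_freq = commute_freq, commute_miles = commute_miles,
    able_to_walk = able_to_walk, tv_hours_day = tv, pc_hours_day = pc,
    walking_pleasure_freq = walking_freq, walking_pleasure_dur = walking_dur,
    strenuous_sport_freq = "once a week", strenuous_sport_dur = "30-60 minutes",
    other_sport_freq = NA_character_, other_sport_dur = NA_character_,
    light_diy_freq = NA_character_, light_diy_dur = NA_character_,
    heavy_diy_freq = NA_character_, heavy_diy_dur = NA_character_,
    age = age, sex = "female", ethnicity = "white", home_owner = "owner",
    car_owner = "yes", income = income, education = "degree",
    has_child = "yes", townsend = -1.5, bmi = 26.5,
    work_activity = "sitting", fracture = "no", vascular = "no",
    nonvascular = "no"
  )
}
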