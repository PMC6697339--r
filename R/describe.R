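# Descriptive reporting: composition descriptives (raw and imputed) and
# included-vs-excluded group comparisons.

#' Descriptive characteristics of the subcomposition
#'
#' Per part: arithmetic mean (SD) and median (IQR) on the raw table (zeros
#' included), geometric mean on the imputed table, and the compositional
#' mean as proportions and minutes/week (proportions of the mean total).
#'
#' @param raw Row-aligned raw part table (zeros allowed).
#' @param imputed Strictly positive imputed part table from
#'   [replace_zeros()].
#' @param total_scale Total used to express the compositional mean in
#'   minutes/week; defaults to the mean of the raw row totals.
#' @return Tibble, one row per part.
#' @export
describe_composition <- function(raw, imputed, total_scale = NULL) {
  parts <- colnames(raw) %||% DT_PARTS
  raw <- as_part_matrix(raw, parts)
  imputed <- as_part_matrix(imputed, parts)
  if (nrow(raw) != nrow(imputed)) {
    stop("raw and imputed tables are not row-aligned")
  }
  if (is.null(total_scale)) total_scale <- mean(rowSums(raw))
  cm <- compositional_mean(imputed, total_scale = total_scale, parts = parts)
  tibble::tibble(
    part = parts,
    mean = colMeans(raw),
    sd = apply(raw, 2L, stats::sd),
    median = apply(raw, 2L, stats::median),
    q25 = apply(raw, 2L, stats::quantile, probs = 0.25),
    q75 = apply(raw, 2L, stats::quantile, probs = 0.75),
    geometric_mean = cm$geometric_mean,
    comp_mean_prop = cm$proportion,
    comp_mean_min_wk = cm$minutes_wk
  )
}

#' Compare two groups covariate by covariate
#'
#' One-way ANOVA (F and p) for continuous covariates, chi-squared (no
#' continuity correction by default) for categorical ones - the standard
#' included-versus-excluded sample comparison.
#'
#' @param included,excluded Data frames sharing the covariate columns.
#' @param covariates Columns to compare; defaults to the shared tier
#'   covariates present in both.
#' @param correct Apply Yates' continuity correction in 2x2 chi-squared
#'   tests.
#' @return Tibble: covariate, test, statistic, p.value.
#' @export
compare_groups <- function(included, excluded, covariates = NULL,
                           correct = FALSE) {
  if (nrow(included) == 0L || nrow(excluded) == 0L) {
    stop("both groups must be non-empty")
  }
  covariates <- covariates %||%
    intersect(c(TIER2_COVARIATES, TIER3_EXTRA),
              intersect(names(included), names(excluded)))
  grp <- factor(rep(c("included", "excluded"),
                    c(nrow(included), nrow(excluded))))
  rows <- lapply(covariates, function(nm) {
    x <- c(included[[nm]], excluded[[nm]])
    ok <- !is.na(x)
    if (is.numeric(x)) {
      a <- stats::anova(stats::lm(x[ok] ~ grp[ok]))
      tibble::tibble(covariate = nm, test = "anova",
                     statistic = a[1, "F value"], p.value = a[1, "Pr(>F)"])
    } else {
      tab <- table(factor(x[ok]), grp[ok])
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      tibble::tibble(covariate = nm, test = "chisq",
                     statistic = unname(ct$statistic),
                     p.value = ct$p.value)
    }
  })
  do.call(rbind, rows)
}
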