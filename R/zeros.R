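# Rounded-zero replacement.
#
# Zeros in walking / sport-DIY arise from categorical reporting ("did not do
# the activity"), i.e. values below a detection limit rather than true
# zeros. They are replaced by small positive values so log-ratio methods
# apply. The algorithm works on additive log-ratios with respect to a
# complete (always positive) part - screen time - treating each zero as a
# left-censored observation at its part's detection limit.

#' Replace rounded zeros in a composition table
#'
#' Two methods are available:
#'
#' * `"lrEM"` (default): express each row in additive log-ratio (alr)
#'   coordinates with respect to the complete part; treat zeros as
#'   left-censored at `log(dl_j / complete_i)`; iteratively (EM) regress
#'   each censored alr column on the others and impute censored cells with
#'   their conditional expectation under the censoring bound,
#'   `mu - sigma * phi(a)/Phi(a)` with `a = (psi - mu)/sigma`; back-transform.
#'   Non-zero entries are returned unchanged.
#' * `"multiplicative"`: each zero becomes `frac * dl_j` and the non-zero
#'   parts of that row are shrunk multiplicatively so the row total is
#'   preserved.
#'
#' Both respect the rounded-zero model: every imputed value is strictly
#' below its part's detection limit.
#'
#' @param x Matrix/data frame of non-negative parts; zeros allowed only
#'   outside `complete_part`.
#' @param dl Detection limits: named vector (per part) or scalar. Defaults
#'   to the smallest positive observed value per part.
#' @param method `"lrEM"` or `"multiplicative"`.
#' @param complete_part Part guaranteed strictly positive (default
#'   `"screen"`); a zero there is an upstream exclusion-filter problem, not
#'   an imputation problem, and is an error.
#' @param frac Fraction of the detection limit used by the multiplicative
#'   method (default 0.65).
#' @param tol,maxit EM convergence tolerance on imputed alr values and
#'   iteration cap.
#' @return Matrix of the same shape, strictly positive, with attribute
#'   `"n_imputed"` (count of replaced cells).
#' @export
replace_zeros <- function(x, dl = NULL, method = c("lrEM", "multiplicative"),
                          complete_part = "screen", frac = 0.65,
                          tol = 1e-8, maxit = 100L) {
  method <- match.arg(method)
  parts <- colnames(x) %||% DT_PARTS
  m <- as_part_matrix(x, parts)
  if (!complete_part %in% parts) stop("unknown complete part: ", complete_part)
  if (any(m < 0) || any(!is.finite(m))) stop("parts must be finite and non-negative")
  if (any(m[, complete_part] <= 0)) {
    stop("zero values in the complete part ('", complete_part,
         "'); such records must be removed by the exclusion filter before imputation")
  }
  zero <- m == 0
  if (!any(zero)) {
    attr(m, "n_imputed") <- 0L
    return(m)
  }

  if (is.null(dl)) {
    dl <- apply(m, 2L, function(col) {
      pos <- col[col > 0]
      if (length(pos) == 0L) stop("a part is entirely zero; no detection limit inferable")
      min(pos)
    })
  } else if (length(dl) == 1L && is.null(names(dl))) {
    dl <- stats::setNames(rep(dl, length(parts)), parts)
  }
  if (!all(parts[colSums(zero) > 0] %in% names(dl))) {
    stop("detection limit missing for a part containing zeros")
  }
  full_dl <- stats::setNames(rep(NA_real_, length(parts)), parts)
  full_dl[names(dl)] <- dl
  for (p in parts[is.na(full_dl)]) full_dl[p] <- min(m[m[, p] > 0, p])
  dl <- full_dl

  out <- switch(method,
    lrEM = impute_lrem(m, zero, dl, complete_part, tol, maxit),
    multiplicative = impute_mult(m, zero, dl, frac)
  )
  attr(out, "n_imputed") <- sum(zero)
  out
}

# EM on alr coordinates w.r.t. the complete part, censored cells truncated
# above at psi = log(dl / complete).
impute_lrem <- function(m, zero, dl, complete_part, tol, maxit) {
  parts <- colnames(m)
  others <- setdiff(parts, complete_part)
  comp <- m[, complete_part]
  y <- log(sweep(m[, others, drop = FALSE], 1L, comp, "/"))
  psi <- log(outer(1 / comp, dl[others], "*"))     # row-specific bounds
  cens <- zero[, others, drop = FALSE]
  y[cens] <- psi[cens] - log(2)                     # dl/2 start

  cens_cols <- which(colSums(cens) > 0L)
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in cens_cols) {
      idx <- cens[, j]
      X <- cbind(1, y[, -j, drop = FALSE])
      fit <- stats::lm.fit(X, y[, j])
      s <- sqrt(sum(fit$residuals^2) / max(fit$df.residual, 1L))
      if (!is.finite(s) || s <= 0) s <- 1e-6
      mu <- drop(X[idx, , drop = FALSE] %*% fit$coefficients)
      a <- (psi[idx, j] - mu) / s
      # E[Y | Y < psi] for Y ~ N(mu, s^2); log-scale Mills ratio for stability
      ratio <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
      newval <- pmin(mu - s * ratio, psi[idx, j] - 1e-10)
      delta <- max(delta, max(abs(newval - y[idx, j])))
      y[idx, j] <- newval
    }
    if (delta < tol) break
  }

  out <- m
  for (j in seq_along(others)) {
    idx <- cens[, j]
    if (any(idx)) out[idx, others[j]] <- comp[idx] * exp(y[idx, j])
  }
  out
}

# Simple multiplicative replacement preserving row totals.
impute_mult <- function(m, zero, dl, frac) {
  out <- m
  repl <- sweep(matrix(0, nrow(m), ncol(m)), 2L, frac * dl, "+")
  out[zero] <- repl[zero]
  tot <- rowSums(m)
  added <- rowSums(repl * zero)
  shrink <- 1 - added / tot
  rows <- which(added > 0)
  for (i in rows) {
    nz <- !zero[i, ]
    out[i, nz] <- m[i, nz] * shrink[i]
  }
  out
}
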