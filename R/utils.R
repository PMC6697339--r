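# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean
#'
#' @param x Strictly positive numeric vector.
#' @param na.rm Drop `NA`s before averaging.
#' @return The geometric mean `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (any(x <= 0, na.rm = TRUE)) {
    stop("geometric mean requires strictly positive values")
  }
  exp(mean(log(x), na.rm = na.rm))
}

# Meteorological season (DJF / MAM / JJA / SON) from a Date.
meteorological_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
}

# Normal draws truncated to be > lower, by resampling.
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

# Coerce a data.frame/matrix/vector of parts to a numeric matrix with the
# given column order, failing loudly on absent parts.
as_part_matrix <- function(x, parts) {
  if (is.vector(x) && is.numeric(x)) {
    x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  }
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && all(parts %in% colnames(x))) {
    x <- x[, parts, drop = FALSE]
  } else if (ncol(x) == length(parts)) {
    colnames(x) <- parts
  } else {
    stop("expected parts ", paste(parts, collapse = ", "),
         " but got columns ", paste(colnames(x), collapse = ", "))
  }
  storage.mode(x) <- "double"
  x
}
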