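# Compositional core: closure, compositional means, sequential binary
# partitions, ilr transforms and pivot coordinate sets.
#
# A composition here is a vector of strictly positive parts carrying only
# relative information. The three-part discretionary-time composition used
# throughout the package is (screen, walking, sportdiy) in minutes/week, but
# the SBP/ilr machinery is written for any number of parts.

#' Part names of the discretionary-time subcomposition
#'
#' Screen time, walking for pleasure, and sport/DIY activities, in
#' minutes/week and in this order everywhere in the package.
#' @export
DT_PARTS <- c("screen", "walking", "sportdiy")

#' Close a composition to proportions
#'
#' Divides each part by the row total so parts sum to 1 (the closure
#' operation on the simplex).
#'
#' @param x Strictly positive numeric vector, or matrix/data frame with one
#'   composition per row.
#' @param parts Column names/order to use; defaults to the columns of `x`
#'   (or [DT_PARTS] when `x` is an unnamed length-3 vector).
#' @return A vector or matrix of proportions with rows summing to 1.
#' @examples
#' close_composition(c(1270, 18, 51))
#' @export
close_composition <- function(x, parts = NULL) {
  vec <- is.vector(x) && is.numeric(x)
  if (is.null(parts)) {
    parts <- if (vec) names(x) %||% paste0("part", seq_along(x)) else colnames(x)
    if (is.null(parts)) parts <- paste0("part", seq_len(ncol(as.matrix(x))))
  }
  m <- as_part_matrix(x, parts)
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("closure requires strictly positive, finite parts")
  }
  out <- m / rowSums(m)
  if (vec) out[1L, ] else out
}

#' Compositional mean
#'
#' The closed vector of per-part geometric means, optionally rescaled to
#' minutes/week by a total. With `total_scale` left `NULL` the arithmetic
#' mean of the row totals is used, matching the convention of reporting the
#' compositional mean "as proportions of the mean total".
#'
#' @param x Matrix/data frame of strictly positive compositions (rows =
#'   observations).
#' @param total_scale Total (e.g. mean total discretionary minutes/week) used
#'   to rescale the proportions; `NULL` for the mean of row sums.
#' @param parts Part columns, defaults to `colnames(x)`.
#' @return A tibble with one row per part: `geometric_mean`, `proportion`
#'   and `minutes_wk` (= proportion x total_scale).
#' @examples
#' compositional_mean(matrix(c(1270, 18, 51), 1), total_scale = 1724)
#' @export
compositional_mean <- function(x, total_scale = NULL, parts = NULL) {
  if (is.null(parts)) {
    parts <- colnames(x) %||% if (is.vector(x)) names(x) else NULL
  }
  if (is.null(parts)) parts <- paste0("part", seq_len(ncol(as.matrix(x))))
  m <- as_part_matrix(x, parts)
  if (any(m <= 0)) stop("compositional mean requires strictly positive parts")
  gm <- exp(colMeans(log(m)))
  prop <- gm / sum(gm)
  if (is.null(total_scale)) total_scale <- mean(rowSums(m))
  tibble::tibble(
    part = parts,
    geometric_mean = unname(gm),
    proportion = unname(prop),
    minutes_wk = unname(prop * total_scale)
  )
}

#' Sequential binary partition and its orthonormal contrast matrix
#'
#' A sequential binary partition (SBP) splits the parts into successively
#' smaller groups; each split contributes one balance (ilr coordinate). The
#' contrast matrix row for a split with `r` numerator and `s` denominator
#' parts carries `+sqrt(s / (r * (r + s)))` on the numerator parts and
#' `-sqrt(r / (s * (r + s)))` on the denominator parts, giving an
#' orthonormal basis of the (D-1)-dimensional ilr space.
#'
#' @param partition A list of `D - 1` splits, each `list(num = <labels>,
#'   den = <labels>)`. The first split must cover all parts; every later
#'   split must subdivide a group produced earlier.
#' @param parts Character vector of all part labels (column order of the
#'   composition matrix).
#' @return A `balance_basis` object: the partition, the parts, and the
#'   `(D-1) x D` contrast matrix `V`.
#' @examples
#' sbp_contrast_matrix(
#'   list(list(num = "screen", den = c("walking", "sportdiy")),
#'        list(num = "walking", den = "sportdiy")))
#' @export
sbp_contrast_matrix <- function(partition, parts = DT_PARTS) {
  D <- length(parts)
  if (!is.list(partition) || length(partition) != D - 1L) {
    stop("partition must be a list of ", D - 1L, " binary splits")
  }
  open_groups <- list(parts) # groups still eligible for splitting
  V <- matrix(0, nrow = D - 1L, ncol = D, dimnames = list(NULL, parts))
  for (k in seq_along(partition)) {
    sp <- partition[[k]]
    num <- sp$num
    den <- sp$den
    if (is.null(num) || is.null(den) || length(num) == 0L || length(den) == 0L) {
      stop("split ", k, " must have non-empty 'num' and 'den'")
    }
    grp <- sort(c(num, den))
    if (anyDuplicated(grp) > 0L) stop("split ", k, " reuses a part")
    hit <- which(vapply(open_groups, function(g) identical(sort(g), grp), logical(1)))
    if (length(hit) != 1L) {
      stop("split ", k, " (", paste(num, collapse = "+"), " | ",
           paste(den, collapse = "+"),
           ") does not subdivide a pending group: not a sequential binary partition")
    }
    open_groups <- open_groups[-hit]
    if (length(num) > 1L) open_groups <- c(open_groups, list(num))
    if (length(den) > 1L) open_groups <- c(open_groups, list(den))
    r <- length(num)
    s <- length(den)
    V[k, num] <- sqrt(s / (r * (r + s)))
    V[k, den] <- -sqrt(r / (s * (r + s)))
  }
  structure(list(partition = partition, parts = parts, V = V),
            class = "balance_basis")
}

#' @export
print.balance_basis <- function(x, ...) {
  cat("Balance basis over parts:", paste(x$parts, collapse = ", "), "\n")
  for (k in seq_along(x$partition)) {
    sp <- x$partition[[k]]
    cat(sprintf("  z%d: %s | %s\n", k,
                paste(sp$num, collapse = "+"), paste(sp$den, collapse = "+")))
  }
  invisible(x)
}

#' Default balance basis: screen time versus the rest
#'
#' First balance contrasts screen time with the geometric mean of walking
#' and sport/DIY (positive = relatively more screen time); second balance
#' contrasts walking with sport/DIY.
#' @return A `balance_basis`.
#' @export
default_basis <- function() {
  sbp_contrast_matrix(list(
    list(num = "screen", den = c("walking", "sportdiy")),
    list(num = "walking", den = "sportdiy")
  ))
}

#' Pivot coordinate bases
#'
#' One balance basis per part, each isolating that part in its first
#' balance (numerator = the isolated part, so a positive first coordinate
#' means relatively more of it). The three coordinate sets of the same
#' composition are related by orthogonal rotations, so multivariate model
#' fits are identical whichever set is used; the first coordinate of each
#' set isolates one part's dominance.
#'
#' @param parts Part labels.
#' @return Named list of `balance_basis` objects, one per part.
#' @export
pivot_bases <- function(parts = DT_PARTS) {
  out <- lapply(seq_along(parts), function(i) {
    rest <- parts[-i]
    splits <- list(list(num = parts[i], den = rest))
    while (length(rest) > 1L) {
      splits <- c(splits, list(list(num = rest[1L], den = rest[-1L])))
      rest <- rest[-1L]
    }
    sbp_contrast_matrix(splits, parts)
  })
  names(out) <- parts
  out
}

#' Isometric log-ratio transform
#'
#' Maps strictly positive compositions to `D - 1` real balance coordinates,
#' `z = log(x) %*% t(V)`. The transform is scale invariant: multiplying a
#' row by any positive constant leaves its coordinates unchanged, so closed
#' and unclosed compositions give the same balances.
#'
#' @param x Composition matrix/data frame (or single vector), strictly
#'   positive.
#' @param basis A `balance_basis`; default [default_basis()].
#' @return An `n x (D-1)` matrix of coordinates (columns `z1`, `z2`, ...)
#'   carrying the generating basis as attribute `"basis"`.
#' @examples
#' ilr_transform(c(screen = 1270, walking = 18, sportdiy = 51))
#' @export
ilr_transform <- function(x, basis = default_basis()) {
  stopifnot(inherits(basis, "balance_basis"))
  m <- as_part_matrix(x, basis$parts)
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("ilr transform requires strictly positive, finite parts")
  }
  z <- log(m) %*% t(basis$V)
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  attr(z, "basis") <- basis
  z
}

#' Inverse isometric log-ratio transform
#'
#' Recovers compositions from balance coordinates:
#' `close(exp(z %*% V)) * total_scale`. Together with [ilr_transform()] this
#' round-trips to the closed composition.
#'
#' @param z Coordinate matrix (or single coordinate vector).
#' @param basis The `balance_basis` that generated `z`. If `z` carries a
#'   basis tag it must agree with `basis`.
#' @param total_scale Scalar or per-row vector of totals; 1 gives
#'   proportions.
#' @return Matrix of compositions, columns named by the basis parts.
#' @export
ilr_inverse <- function(z, basis = default_basis(), total_scale = 1) {
  stopifnot(inherits(basis, "balance_basis"))
  tag <- attr(z, "basis")
  if (!is.null(tag) && !isTRUE(all.equal(tag$V, basis$V, tolerance = 1e-12))) {
    stop("coordinates were generated under a different balance basis")
  }
  if (is.vector(z) && is.numeric(z)) z <- matrix(z, nrow = 1L)
  z <- as.matrix(z)
  if (ncol(z) != nrow(basis$V)) {
    stop("expected ", nrow(basis$V), " coordinates, got ", ncol(z))
  }
  comp <- exp(z %*% basis$V)
  comp <- comp / rowSums(comp)
  comp * total_scale
}
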