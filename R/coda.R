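#' @title Compositional geometry for 24-h time-use data
#' @name coda
#' @description
#' The 24-h day is treated as a 4-part composition (sleep, SB, LPA, MVPA)
#' living on the simplex with total 24 h/day. These functions provide the
#' closure operation, pivot isometric log-ratio (ilr) coordinates and their
#' inverse, compositional means (part-wise geometric means re-scaled to the
#' total), confidence intervals for re-scaled geometric means, and the
#' paired test on first pivot coordinates used in descriptive tables.
NULL

#' Canonical behaviour order of the 4-part time-use composition
#'
#' Sleep, sedentary behaviour (SB), light physical activity (LPA) and
#' moderate-to-vigorous physical activity (MVPA), in the default pivot order.
#'
#' @export
timeuse_parts <- function() c("sleep", "sb", "lpa", "mvpa")

#' Close a positive vector to a fixed total
#'
#' Multiplies all parts by `total / sum(x)` so that the result sums to
#' `total`. This is the linear adjustment to 24 h/day applied to raw
#' behaviour durations: unaccounted (or double-counted) time is
#' proportionally redistributed over all parts.
#'
#' @param x numeric vector of strictly positive parts (hours).
#' @param total target total, default 24 (hours/day).
#' @return numeric vector of the same length and names summing to `total`.
#' @export
closure <- function(x, total = 24) {
  x <- as.numeric_parts(x)
  if (any(x <= 0)) stop("all parts must be strictly positive for closure")
  x * (total / sum(x))
}

# coerce to a plain numeric vector, keeping names, validating finiteness
as.numeric_parts <- function(x) {
  x <- unlist(x, use.names = TRUE)
  storage.mode(x) <- "double"
  if (length(x) < 2) stop("a composition needs at least 2 parts")
  if (any(!is.finite(x))) stop("non-finite part value")
  x
}

# orthonormal pivot ilr basis: D x (D-1) matrix V with z = t(V) %*% log(x)
pivot_basis <- function(D) {
  V <- matrix(0, D, D - 1)
  for (j in seq_len(D - 1)) {
    r <- D - j
    V[j, j] <- sqrt(r / (r + 1))
    V[(j + 1):D, j] <- -1 / sqrt(r * (r + 1))
  }
  V
}

#' Pivot ilr coordinates of a composition
#'
#' Maps a D-part positive composition to D-1 real coordinates using the
#' pivot ilr basis: the j-th coordinate contrasts part j against the
#' geometric mean of the subsequent parts,
#' \deqn{z_j = \sqrt{\frac{D-j}{D-j+1}} \,
#'       \ln\!\frac{x_j}{g(x_{j+1},\dots,x_D)}.}
#' The first coordinate carries all relative information about the first
#' part, which is why descriptive tests pivot each behaviour to the front.
#' The map is invariant to closure (only ratios enter) and is an isometry
#' between the Aitchison geometry and ordinary Euclidean space.
#'
#' @param x positive composition; if named, it is reordered by `part_order`.
#' @param part_order character permutation of `names(x)` giving the pivot
#'   sequence; ignored for unnamed input.
#' @return numeric vector of length `length(x) - 1`.
#' @seealso [inverse_pivot_ilr()]
#' @export
pivot_ilr <- function(x, part_order = names(x)) {
  x <- as.numeric_parts(x)
  if (!is.null(part_order) && !is.null(names(x))) {
    if (!setequal(part_order, names(x)))
      stop("part_order must be a permutation of the part names")
    x <- x[part_order]
  }
  if (any(x <= 0)) stop("pivot_ilr requires strictly positive parts")
  D <- length(x)
  as.vector(crossprod(pivot_basis(D), log(x)))
}

#' Inverse pivot ilr transform
#'
#' Reconstructs the composition with the given total from pivot ilr
#' coordinates; exact inverse of [pivot_ilr()].
#'
#' @param z numeric coordinate vector (length D-1).
#' @param total total of the reconstructed composition (default 24 h).
#' @param part_order optional character vector of D part names for the
#'   result, in pivot order.
#' @return positive composition of length `length(z) + 1` summing to `total`.
#' @export
inverse_pivot_ilr <- function(z, total = 24, part_order = NULL) {
  z <- as.vector(z)
  if (any(!is.finite(z))) stop("non-finite ilr coordinate")
  D <- length(z) + 1
  x <- exp(as.vector(pivot_basis(D) %*% z))
  x <- x * (total / sum(x))
  if (!is.null(part_order)) {
    if (length(part_order) != D) stop("part_order must have length(z) + 1 names")
    names(x) <- part_order
  }
  x
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between the clr (equivalently ilr) images; the
#' natural metric of the simplex.
#'
#' @param x,y positive compositions of equal length (same part order).
#' @return non-negative scalar.
#' @export
aitchison_dist <- function(x, y) {
  x <- as.numeric_parts(x); y <- as.numeric_parts(y)
  if (length(x) != length(y)) stop("compositions differ in length")
  clr <- function(v) log(v) - mean(log(v))
  sqrt(sum((clr(x) - clr(y))^2))
}

# validate a cohort of compositions given as matrix / data.frame,
# returning a numeric matrix with columns in `parts` order
cohort_matrix <- function(comps, parts = timeuse_parts()) {
  m <- as.matrix(as.data.frame(comps)[, parts, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) == 0) stop("empty cohort")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("cohort compositions must be finite and strictly positive")
  m
}

#' Compositional mean of a cohort
#'
#' Part-wise geometric means across participants, re-scaled (closed) to the
#' total. Equals the inverse ilr of the arithmetic mean of the ilr vectors:
#' the centre of the data in the Aitchison geometry.
#'
#' @param comps matrix or data.frame of compositions, one row per
#'   participant, with columns named by `parts`.
#' @param parts part names/order (default [timeuse_parts()]).
#' @param total closure total (default 24).
#' @return named composition summing to `total`.
#' @export
mean_composition <- function(comps, parts = timeuse_parts(), total = 24) {
  m <- cohort_matrix(comps, parts)
  g <- exp(colMeans(log(m)))
  closure(g, total)
}

#' Confidence interval for a re-scaled geometric mean duration
#'
#' A t-based interval for the mean of the log duration of one part across
#' participants, exponentiated and then multiplied by the same closure
#' factor used for the point estimate (the factor that re-scales the vector
#' of part-wise geometric means to sum to `total`). The interval therefore
#' brackets the part's entry in [mean_composition()].
#'
#' @param comps cohort of compositions (rows = participants).
#' @param part which part.
#' @param level confidence level (default 0.95).
#' @inheritParams mean_composition
#' @return named numeric: `estimate`, `lower`, `upper` (hours/day).
#' @export
rescaled_geomean_ci <- function(comps, part, level = 0.95,
                                parts = timeuse_parts(), total = 24) {
  m <- cohort_matrix(comps, parts)
  if (!part %in% parts) stop("unknown part: ", part)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 participants for a confidence interval")
  lx <- log(m[, part])
  g <- exp(colMeans(log(m)))
  k <- total / sum(g)                # closure factor of the point estimate
  mu <- mean(lx)
  se <- stats::sd(lx) / sqrt(n)
  if (se == 0) {
    est <- k * exp(mu)
    return(c(estimate = est, lower = est, upper = est))
  }
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  c(estimate = k * exp(mu),
    lower = k * exp(mu - tq * se),
    upper = k * exp(mu + tq * se))
}

#' Paired t-test on first pivot coordinates
#'
#' For each participant, the chosen behaviour is pivoted to the front and
#' its first pivot coordinate computed at both waves; a paired two-sided
#' t-test is run on the follow-up minus baseline differences. Because the
#' first pivot coordinate carries all relative information about the
#' pivoted part, this tests whether that behaviour changed relative to the
#' remaining behaviours.
#'
#' @param baseline,followup cohorts of compositions with identical row
#'   order (same participants).
#' @param part behaviour to pivot first.
#' @inheritParams mean_composition
#' @return list with `t`, `p`, `mean_diff` (mean change in the first pivot
#'   coordinate), `df`.
#' @export
paired_pivot_ttest <- function(baseline, followup, part,
                               parts = timeuse_parts()) {
  b <- cohort_matrix(baseline, parts)
  f <- cohort_matrix(followup, parts)
  if (nrow(b) != nrow(f)) stop("mismatched participant sets between waves")
  if (nrow(b) < 2) stop("need at least 2 participants")
  ord <- c(part, setdiff(parts, part))
  first_pivot <- function(m) {
    D <- length(ord)
    sqrt((D - 1) / D) *
      (log(m[, ord[1]]) - rowMeans(log(m[, ord[-1], drop = FALSE])))
  }
  d <- first_pivot(f) - first_pivot(b)
  if (stats::sd(d) < 1e-12) {
    if (abs(mean(d)) < 1e-12)
      return(list(t = 0, p = 1, mean_diff = 0, df = length(d) - 1))
    stop("zero variance in paired differences with a non-zero mean change")
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = mean(d), df = unname(tt$parameter))
}
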