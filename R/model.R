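#' @title Longitudinal compositional regression and isotemporal substitution
#' @name model
#' @description
#' Fits the follow-up level of an inflammatory marker on the change in
#' pivot ilr coordinates of the 24-h time-use composition
#' (follow-up minus baseline), adjusting for the baseline ilr coordinates,
#' the baseline marker level, sex, age, maternal education, zBMI and its
#' change, pubertal stage and accelerometer wear time at both waves.
#' Unstandardised coefficients feed the compositional
#' isotemporal-substitution model: the predicted marker change for a
#' one-to-one reallocation of time is a linear contrast of the
#' ilr-change coefficients, with a t-based 95% confidence interval.
NULL

# required cohort columns besides the marker pair
composition_cols <- function(parts)
  c(paste0(parts, "_baseline"), paste0(parts, "_followup"))

covariate_cols <- function()
  c("sex", "age", "maternal_education", "zbmi", "zbmi_change",
    "pubertal_stage", "wear_baseline_h", "wear_followup_h")

# 0/1 dummy columns for an integer-coded factor. Reference = first level;
# levels absent from the data contribute no column, and if the reference
# level itself is absent the first present level becomes the reference
# (otherwise the dummies would sum to the intercept).
dummy_cols <- function(x, levels, prefix) {
  x <- factor(x, levels = levels)
  if (anyNA(x)) stop("invalid level in ", prefix)
  present <- levels[levels %in% x]
  if (length(present) < 2)
    stop("covariate '", prefix, "' is constant in the analysed rows")
  if (present[1] != levels[1])
    message("build_design: reference level for '", prefix,
            "' shifted to ", present[1], " (level ", levels[1],
            " absent)")
  dropped <- setdiff(setdiff(levels, present), levels[1])
  if (length(dropped))
    message("build_design: no rows in '", prefix, "' categor",
            if (length(dropped) > 1) "ies " else "y ",
            paste(dropped, collapse = ", "), "; column(s) omitted")
  m <- sapply(present[-1], function(l) as.numeric(x == l))
  colnames(m) <- paste0(prefix, present[-1])
  m
}

#' Build the regression design for one marker
#'
#' Columns: intercept; 3 ilr-change columns (`dilr*`, follow-up minus
#' baseline pivot ilr coordinates); 3 baseline ilr columns (`bilr*`);
#' baseline marker level; sex indicator; age; 4 maternal-education
#' indicators (reference: level 1, no formal education); zBMI; change in
#' zBMI; 4 pubertal-stage indicators (reference: stage 1); baseline and
#' follow-up wear time (hours). Outcome: follow-up marker level. Rows with
#' any missing value are dropped (complete-case) and their identifiers
#' recorded. Indicator columns for categories absent from the analysed
#' rows are dropped with a message (an empty category carries no
#' information), and if a reference level is absent the first present
#' level becomes the reference; otherwise the design would be rank
#' deficient.
#'
#' @param cohort data.frame with per-part composition columns
#'   `<part>_baseline` / `<part>_followup` (hours, strictly positive),
#'   `<marker>_baseline` / `<marker>_followup`, and covariates `sex`
#'   (0/1), `age` (years), `maternal_education` (integer 1-5), `zbmi`,
#'   `zbmi_change`, `pubertal_stage` (integer 1-5), `wear_baseline_h`,
#'   `wear_followup_h`.
#' @param marker marker name, e.g. `"c3"`.
#' @param part_order pivot order of the composition parts.
#' @return list with design matrix `X`, outcome `y`, `labels`,
#'   `part_order`, `dilr_idx` (positions of the ilr-change columns) and
#'   `dropped` (identifiers of incomplete rows).
#' @export
build_design <- function(cohort, marker, part_order = timeuse_parts()) {
  mcols <- paste0(marker, c("_baseline", "_followup"))
  need <- c(composition_cols(part_order), mcols, covariate_cols())
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  ids <- if ("participant_id" %in% names(cohort)) cohort$participant_id
         else seq_len(nrow(cohort))
  cc <- stats::complete.cases(cohort[, need])
  dropped <- ids[!cc]
  if (length(dropped))
    message("build_design: dropped ", length(dropped),
            " incomplete row(s): ", paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  d <- cohort[cc, , drop = FALSE]
  if (!nrow(d)) stop("no complete rows")

  bmat <- cohort_matrix(d[, paste0(part_order, "_baseline")] |>
                          stats::setNames(part_order), part_order)
  fmat <- cohort_matrix(d[, paste0(part_order, "_followup")] |>
                          stats::setNames(part_order), part_order)
  bilr <- t(apply(bmat, 1, pivot_ilr, part_order = part_order))
  filr <- t(apply(fmat, 1, pivot_ilr, part_order = part_order))
  dilr <- filr - bilr
  ncoord <- ncol(bilr)
  colnames(dilr) <- paste0("dilr", seq_len(ncoord))
  colnames(bilr) <- paste0("bilr", seq_len(ncoord))

  edu <- dummy_cols(d$maternal_education, 1:5, "edu")
  pub <- dummy_cols(d$pubertal_stage, 1:5, "pub")
  X <- cbind(
    `(Intercept)` = 1,
    dilr, bilr,
    marker_baseline = d[[mcols[1]]],
    sex = as.numeric(d$sex),
    age = d$age,
    edu,
    zbmi = d$zbmi,
    zbmi_change = d$zbmi_change,
    pub,
    wear_baseline_h = d$wear_baseline_h,
    wear_followup_h = d$wear_followup_h
  )
  list(X = X, y = d[[mcols[2]]], labels = colnames(X),
       part_order = part_order,
       dilr_idx = which(colnames(X) %in% colnames(dilr)),
       dropped = dropped)
}

# Huber psi and weights
huber_w <- function(u, k) pmin(1, k / pmax(abs(u), .Machine$double.eps))

#' Fit the marker regression
#'
#' `method = "ols"`: least squares with the classical covariance
#' \eqn{\hat\sigma^2 (X'X)^{-1}}. `method = "robust"`: Huber M-estimation
#' (tuning constant `tuning`, default 1.345 for 95% Gaussian efficiency)
#' solved by iteratively reweighted least squares, with the scale
#' re-estimated each iteration as the normalised median absolute residual
#' (MAD about zero), iterated until the relative change of the fitted
#' values falls below `tol`. The coefficient covariance is the standard
#' M-estimator sandwich
#' \eqn{\hat s^2 \; \frac{\sum \psi(u_i)^2/(n-p)}{(\overline{\psi'(u_i)})^2}
#'      (X'X)^{-1}}.
#' Degrees of freedom are `n - p` for both methods. A perfect
#' (zero-residual) fit short-circuits with a zero covariance.
#'
#' @param design list from [build_design()] (or any list with `X`, `y`,
#'   `labels`, `part_order`, `dilr_idx`).
#' @param method `"robust"` (default) or `"ols"`.
#' @param tuning Huber tuning constant (default 1.345).
#' @param tol relative convergence tolerance for IRLS (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 200).
#' @return object of class `timeuse_fit`: `coefficients`, `vcov`, `df`,
#'   `scale`, `method`, `labels`, `part_order`, `dilr_idx`, `n`.
#' @export
fit_marker_model <- function(design, method = c("robust", "ols"),
                             tuning = 1.345, tol = 1e-8, max_iter = 200) {
  method <- match.arg(method)
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more rows than design columns")
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is rank deficient")
  beta <- qr.coef(qx, y)
  res <- y - as.vector(X %*% beta)
  yscale <- stats::median(abs(y)) + 1

  if (method == "ols") {
    sigma2 <- sum(res^2) / (n - p)
    V <- sigma2 * chol2inv(qr.R(qx))
    scale <- sqrt(sigma2)
  } else {
    fitted_old <- as.vector(X %*% beta)
    converged <- FALSE
    s <- 0
    for (it in seq_len(max_iter)) {
      s <- stats::median(abs(res)) / 0.6745
      if (s < 1e-10 * yscale) { converged <- TRUE; break }  # perfect fit
      w <- huber_w(res / s, tuning)
      fit_w <- stats::lm.wfit(X, y, w)
      beta <- fit_w$coefficients
      fitted_new <- y - fit_w$residuals
      res <- fit_w$residuals
      rel <- sqrt(sum((fitted_new - fitted_old)^2) /
                    max(sum(fitted_old^2), yscale^2))
      fitted_old <- fitted_new
      if (rel < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop("IRLS did not converge in ", max_iter, " iterations")
    if (s < 1e-10 * yscale) {
      V <- matrix(0, p, p)
      scale <- 0
    } else {
      u <- res / s
      psi <- pmax(-tuning, pmin(tuning, u))
      psip <- as.numeric(abs(u) <= tuning)
      V <- s^2 * (sum(psi^2) / (n - p)) / mean(psip)^2 *
        chol2inv(chol(crossprod(X)))
      scale <- s
    }
  }
  dimnames(V) <- list(design$labels, design$labels)
  structure(
    list(coefficients = stats::setNames(as.vector(beta), design$labels),
         vcov = V, df = n - p, scale = scale, method = method,
         labels = design$labels, part_order = design$part_order,
         dilr_idx = design$dilr_idx, n = n),
    class = "timeuse_fit"
  )
}

#' @export
print.timeuse_fit <- function(x, ...) {
  cat(sprintf("<timeuse_fit> %s fit, n = %d, df = %d, scale = %.4g\n",
              x$method, x$n, x$df, x$scale))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Isotemporal-substitution estimate for one reallocation
#'
#' Predicted change in the marker for transferring `minutes`/day from one
#' behaviour to another, starting from `base` (typically the mean baseline
#' composition): the contrast vector is zero except in the ilr-change
#' positions, where it equals
#' `pivot_ilr(reallocate(base, ...)) - pivot_ilr(base)`. The estimate is
#' `c'beta` with a `level` t-interval `c'beta +/- t qnorm * sqrt(c'Vc)`;
#' it is flagged significant iff the interval excludes zero.
#'
#' @param fit a [fit_marker_model()] result.
#' @param base named composition in hours.
#' @param from,to,minutes the reallocation (see [reallocate()]).
#' @param level confidence level (default 0.95).
#' @return one-row data.frame: `from`, `to`, `minutes`, `delta`, `se`,
#'   `ci_low`, `ci_high`, `significant`.
#' @export
estimate_substitution <- function(fit, base, from, to, minutes,
                                  level = 0.95) {
  stopifnot(inherits(fit, "timeuse_fit"))
  realloc <- reallocate(base, from, to, minutes)
  dz <- pivot_ilr(realloc, fit$part_order) - pivot_ilr(base, fit$part_order)
  cvec <- numeric(length(fit$coefficients))
  cvec[fit$dilr_idx] <- dz
  delta <- sum(cvec * fit$coefficients)
  se <- sqrt(max(0, as.vector(cvec %*% fit$vcov %*% cvec)))
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  lo <- delta - tq * se
  hi <- delta + tq * se
  data.frame(from = from, to = to, minutes = minutes, delta = delta,
             se = se, ci_low = lo, ci_high = hi,
             significant = lo > 0 | hi < 0)
}

#' Full substitution table
#'
#' All feasible ordered behaviour pairs at each duration, starting from
#' `base`; infeasible cells are skipped with a warning (by
#' [substitution_grid()] semantics).
#'
#' @inheritParams estimate_substitution
#' @param durations durations in minutes/day (default `c(10, 30, 60)`).
#' @return data.frame of [estimate_substitution()] rows.
#' @export
substitution_table <- function(fit, base, durations = c(10, 30, 60),
                               level = 0.95) {
  base <- as.numeric_parts(base)
  parts <- names(base)
  rows <- list()
  for (m in durations) {
    for (from in parts) for (to in setdiff(parts, from)) {
      if (base[[from]] <= m / 60) {
        warning(sprintf("skipping infeasible reallocation %s -> %s, %g min",
                        from, to, m), call. = FALSE)
        next
      }
      rows[[length(rows) + 1]] <-
        estimate_substitution(fit, base, from, to, m, level = level)
    }
  }
  do.call(rbind, rows)
}
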