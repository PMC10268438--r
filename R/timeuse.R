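#' @title Assembly of the 24-h time-use composition
#' @name timeuse
#' @description
#' Combines self-reported sleep with accelerometer-derived SB/LPA/MVPA
#' durations and closes the 4-part vector to 24 h/day. Sleep comes
#' entirely from self-report (devices are removed overnight), so it is
#' never subtracted from device wear time; discrepancies between the raw
#' total and 24 h are proportionally redistributed over all four parts by
#' the closure.
NULL

# "HH:MM" (or "HH:MM:SS") clock string -> fractional hours in [0, 24)
parse_clock <- function(x) {
  p <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (!length(p) %in% c(2, 3) || anyNA(suppressWarnings(as.numeric(p))))
    stop("invalid clock time: ", x)
  v <- as.numeric(p)
  h <- v[1] + v[2] / 60 + if (length(v) == 3) v[3] / 3600 else 0
  if (v[1] < 0 || v[1] > 23 || v[2] < 0 || v[2] > 59 || h < 0 || h >= 24)
    stop("invalid clock time: ", x)
  h
}

#' Self-reported sleep duration from bed and wake times
#'
#' Difference between wake-up time and bedtime in hours. Clock times carry
#' no dates: when the wake time is at or before the bedtime the interval
#' is taken to wrap midnight. Equal times are rejected (0 h and 24 h are
#' indistinguishable).
#'
#' @param bedtime,waketime clock times as `"HH:MM"` or `"HH:MM:SS"` strings.
#' @return sleep duration in hours, in (0, 24).
#' @export
sleep_duration <- function(bedtime, waketime) {
  b <- parse_clock(bedtime)
  w <- parse_clock(waketime)
  if (b == w) stop("bedtime equals waketime: sleep duration is ambiguous")
  d <- w - b
  if (d <= 0) d <- d + 24
  d
}

#' Replace zero durations before log-ratio analysis
#'
#' Log-ratios require strictly positive parts. Zero parts are set to
#' `delta` (in the input's own units); the positive parts are shrunk by a
#' common multiplicative factor so the vector total is preserved exactly.
#' With no zeros the input is returned unchanged.
#'
#' @param raw named or unnamed numeric vector of raw durations (any common
#'   unit).
#' @param delta replacement value for a zero part, in the same unit
#'   (default 1, i.e. 1 minute for minute-scale input).
#' @return vector of the same length, strictly positive, same total.
#' @export
replace_zeros <- function(raw, delta = 1) {
  raw <- as.numeric_parts(raw)
  if (any(raw < 0)) stop("negative duration")
  z <- raw == 0
  if (!any(z)) return(raw)
  if (all(z)) stop("all parts are zero")
  total <- sum(raw)
  need <- delta * sum(z)
  if (need >= total) stop("zero-replacement delta too large for the total")
  raw[!z] <- raw[!z] * (total - need) / total
  raw[z] <- delta
  raw
}

#' Build the closed 4-part time-use composition
#'
#' Takes self-reported sleep (hours) and accelerometer-derived SB, LPA and
#' MVPA (minutes/day), replaces zeros (see [replace_zeros()], applied on
#' the minute scale with `delta_min`), and linearly adjusts all four parts
#' to sum to 24 h: each part is multiplied by `24 / (raw total)`, i.e.
#' unaccounted time is proportionally redistributed to all four
#' behaviours.
#'
#' @param sleep_h sleep duration, hours/day.
#' @param sb_min,lpa_min,mvpa_min behaviour durations, minutes/day.
#' @param delta_min zero-replacement value in minutes (default 1).
#' @param total closure total in hours (default 24).
#' @return named composition `c(sleep, sb, lpa, mvpa)` in hours, summing
#'   to `total`.
#' @export
build_composition <- function(sleep_h, sb_min, lpa_min, mvpa_min,
                              delta_min = 1, total = 24) {
  raw_min <- c(sleep = sleep_h * 60, sb = sb_min, lpa = lpa_min,
               mvpa = mvpa_min)
  if (any(!is.finite(raw_min)) || any(raw_min < 0))
    stop("durations must be finite and non-negative")
  raw_min <- replace_zeros(raw_min, delta = delta_min)
  closure(raw_min / 60, total = total)
}
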