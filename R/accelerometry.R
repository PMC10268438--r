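#' @title Accelerometer count processing
#' @name accelerometry
#' @description
#' Turns raw vertical-axis activity-count series into per-participant
#' average daily minutes of sedentary behaviour (SB), light physical
#' activity (LPA) and moderate-to-vigorous physical activity (MVPA):
#' epoch reintegration, non-wear detection (60-min zero-count rule with a
#' 2-min allowance under 100 cpm), cut-point classification
#' (0-99 / 100-1999 / >=2000 counts per minute, scaled to the working
#' epoch length), per-calendar-day summaries and valid-day filtering
#' (>= 3 days with >= 10 wear hours, including a weekend day).
NULL

#' Create an epoch count series
#'
#' Container for one participant-wave of accelerometer data: a sequence of
#' non-negative vertical-axis counts at a fixed epoch length starting at a
#' known time.
#'
#' @param counts integer vector of non-negative counts per epoch.
#' @param epoch_s epoch length in seconds; must divide 60.
#' @param start_time `POSIXct` timestamp of the first epoch's start.
#' @param participant_id,wave optional identifiers (`wave` is `"baseline"`
#'   or `"followup"` in cohort use).
#' @return object of class `epoch_series`.
#' @export
epoch_series <- function(counts, epoch_s, start_time,
                         participant_id = NA_character_,
                         wave = NA_character_) {
  counts <- as.numeric(counts)
  if (length(counts) < 1) stop("counts must have length >= 1")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  epoch_s <- as.integer(epoch_s)
  if (is.na(epoch_s) || epoch_s < 1 || 60L %% epoch_s != 0L)
    stop("epoch_s must be a positive integer dividing 60")
  if (!inherits(start_time, "POSIXct")) stop("start_time must be POSIXct")
  structure(
    list(participant_id = participant_id, wave = wave,
         start_time = start_time, epoch_s = epoch_s, counts = counts),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %s/%s: %d epochs of %d s from %s\n",
              x$participant_id, x$wave, length(x$counts), x$epoch_s,
              format(x$start_time)))
  invisible(x)
}

#' Reintegrate a count series to a longer epoch
#'
#' Sums counts over consecutive blocks to produce a series at
#' `target_epoch_s`. Total counts are conserved; a trailing partial block
#' is dropped (with a message). Upsampling is impossible.
#'
#' @param series an [epoch_series()].
#' @param target_epoch_s target epoch length (integer multiple of the
#'   series epoch, dividing 60).
#' @return an `epoch_series` at the target epoch length.
#' @export
reintegrate <- function(series, target_epoch_s) {
  stopifnot(inherits(series, "epoch_series"))
  target_epoch_s <- as.integer(target_epoch_s)
  if (target_epoch_s < series$epoch_s)
    stop("cannot upsample: target epoch is shorter than the series epoch")
  if (target_epoch_s %% series$epoch_s != 0L)
    stop("target epoch must be an integer multiple of the series epoch")
  if (60L %% target_epoch_s != 0L) stop("target epoch must divide 60")
  k <- target_epoch_s %/% series$epoch_s
  if (k == 1L) return(series)
  n <- length(series$counts)
  n_full <- n %/% k
  if (n_full == 0L) stop("series shorter than one target epoch")
  dropped <- n - n_full * k
  if (dropped > 0)
    message("reintegrate: dropped trailing partial block of ", dropped,
            " epoch(s)")
  agg <- colSums(matrix(series$counts[seq_len(n_full * k)], nrow = k))
  epoch_series(agg, target_epoch_s, series$start_time,
               series$participant_id, series$wave)
}

# per-minute count totals over complete minutes (trailing partial minute
# excluded); used by the non-wear rule, which is stated in minutes
minute_totals <- function(series) {
  epm <- 60L %/% series$epoch_s
  n_min <- length(series$counts) %/% epm
  if (n_min == 0L) return(numeric(0))
  colSums(matrix(series$counts[seq_len(n_min * epm)], nrow = epm))
}

#' Detect accelerometer non-wear time
#'
#' An epoch is non-wear iff its minute lies inside some window of at least
#' `window_min` consecutive minutes in which every minute has zero counts,
#' except for at most `allowance_max_min` minutes with a per-minute total
#' strictly between 0 and `allowance_cpm`. Any minute at or above
#' `allowance_cpm`, or a further sub-threshold non-zero minute, terminates
#' the window. All qualifying windows are unioned. Classification is done
#' on per-minute totals; a trailing partial minute is never non-wear.
#'
#' The scan keeps, for each start minute, the farthest end such that the
#' window remains admissible (a two-pointer sweep, linear time). Because
#' admissibility is inherited by sub-windows, marking each maximal
#' admissible window of length >= `window_min` reproduces the union over
#' all qualifying windows.
#'
#' @param series an [epoch_series()].
#' @param window_min minimum window length in minutes (default 60).
#' @param allowance_max_min maximum number of tolerated non-zero minutes
#'   (default 2).
#' @param allowance_cpm upper bound (exclusive) for a tolerated minute's
#'   count total (default 100).
#' @return logical wear mask aligned with the series (`TRUE` = worn).
#' @export
detect_nonwear <- function(series, window_min = 60, allowance_max_min = 2,
                           allowance_cpm = 100) {
  stopifnot(inherits(series, "epoch_series"))
  epm <- 60L %/% series$epoch_s
  tot <- minute_totals(series)
  n_min <- length(tot)
  mask <- rep(TRUE, length(series$counts))
  if (n_min == 0L) return(mask)
  # minute classes: 0 zero, 1 allowance-eligible, 2 active (ends any window)
  cls <- ifelse(tot == 0, 0L, ifelse(tot < allowance_cpm, 1L, 2L))
  nonwear_min <- rep(FALSE, n_min)
  j <- 0L; nz <- 0L
  for (i in seq_len(n_min)) {
    if (j < i - 1L) { j <- i - 1L; nz <- 0L }
    while (j < n_min &&
           cls[j + 1L] != 2L &&
           !(cls[j + 1L] == 1L && nz >= allowance_max_min)) {
      j <- j + 1L
      if (cls[j] == 1L) nz <- nz + 1L
    }
    if (j - i + 1L >= window_min) nonwear_min[i:j] <- TRUE
    if (j >= i && cls[i] == 1L) nz <- nz - 1L
  }
  if (any(nonwear_min)) {
    bad <- rep(nonwear_min, each = epm)
    mask[seq_along(bad)] <- !bad
  }
  mask
}

#' Intensity cut-points in counts per minute
#'
#' Closed per-minute bins: SB `[0, sb_max_cpm]`, LPA
#' `[sb_max_cpm + 1, lpa_max_cpm]`, MVPA `[lpa_max_cpm + 1, Inf)`.
#' Defaults are the vertical-axis youth cut-points 0-99 / 100-1999 /
#' >= 2000 cpm.
#'
#' @param sb_max_cpm upper SB bound (default 99).
#' @param lpa_max_cpm upper LPA bound (default 1999).
#' @return object of class `cut_points` with the MVPA lower bound implied.
#' @export
cut_points <- function(sb_max_cpm = 99, lpa_max_cpm = 1999) {
  if (sb_max_cpm < 0 || lpa_max_cpm <= sb_max_cpm)
    stop("need 0 <= sb_max_cpm < lpa_max_cpm")
  structure(list(sb_max_cpm = sb_max_cpm, lpa_max_cpm = lpa_max_cpm,
                 mvpa_min_cpm = lpa_max_cpm + 1),
            class = "cut_points")
}

#' Classify epochs by intensity
#'
#' Worn epochs are labelled by comparing the epoch count against the
#' cut-points scaled proportionally to the epoch length
#' (`cpm * epoch_s / 60`): with `f = epoch_s / 60` the bins are
#' `[0, 100 f)` for SB, `[100 f, 2000 f)` for LPA and `[2000 f, Inf)` for
#' MVPA at the default cut-points. At 60-s epochs this reproduces the
#' per-minute bins exactly; at 10-s epochs the SB/LPA boundary is 100/6.
#' Non-worn epochs are labelled `NONWEAR` regardless of count.
#'
#' @param series an [epoch_series()].
#' @param mask logical wear mask from [detect_nonwear()].
#' @param cuts a [cut_points()] object.
#' @return factor of per-epoch labels with levels SB, LPA, MVPA, NONWEAR.
#' @export
classify_epochs <- function(series, mask, cuts = cut_points()) {
  stopifnot(inherits(series, "epoch_series"), inherits(cuts, "cut_points"))
  if (length(mask) != length(series$counts))
    stop("wear mask is not aligned with the series")
  f <- series$epoch_s / 60
  lpa_lo <- (cuts$sb_max_cpm + 1) * f
  mvpa_lo <- cuts$mvpa_min_cpm * f
  lab <- ifelse(series$counts < lpa_lo, "SB",
                ifelse(series$counts < mvpa_lo, "LPA", "MVPA"))
  lab[!mask] <- "NONWEAR"
  factor(lab, levels = c("SB", "LPA", "MVPA", "NONWEAR"))
}

#' Summarise a labelled series by calendar day
#'
#' One row per calendar date touched by the series. Wear hours are worn
#' epochs times the epoch length; behaviour minutes count labelled epochs.
#' Days split at midnight in the series' own time zone; weekend means
#' Saturday or Sunday.
#'
#' @param series an [epoch_series()].
#' @param labels factor from [classify_epochs()].
#' @param mask logical wear mask.
#' @return data.frame with columns `date`, `is_weekend`, `wear_h`,
#'   `sb_min`, `lpa_min`, `mvpa_min`.
#' @export
summarize_days <- function(series, labels, mask) {
  stopifnot(inherits(series, "epoch_series"))
  n <- length(series$counts)
  if (length(labels) != n || length(mask) != n)
    stop("labels/mask not aligned with the series")
  tz <- attr(series$start_time, "tzone")
  if (is.null(tz) || identical(tz, "")) tz <- "UTC"
  times <- series$start_time + (seq_len(n) - 1) * series$epoch_s
  dates <- as.Date(times, tz = tz)
  ud <- sort(unique(dates))
  # accumulate exact integer seconds first, then divide: whole-minute
  # durations come out exactly representable
  out <- lapply(ud, function(d) {
    idx <- dates == d
    data.frame(
      date = d,
      is_weekend = format(d, "%u") %in% c("6", "7"),
      wear_h = (sum(mask[idx]) * series$epoch_s) / 3600,
      sb_min = (sum(labels[idx] == "SB") * series$epoch_s) / 60,
      lpa_min = (sum(labels[idx] == "LPA") * series$epoch_s) / 60,
      mvpa_min = (sum(labels[idx] == "MVPA") * series$epoch_s) / 60
    )
  })
  do.call(rbind, out)
}

#' Valid-day filter and participant-level averaging
#'
#' Discards days with fewer wear hours than `min_wear_h`; the participant
#' is retained iff at least `min_days` days remain, of which at least
#' `min_weekend_days` fall on a weekend. Means are unweighted averages over
#' the retained days. Rejection is returned as a value, not an error.
#'
#' @param days data.frame of daily summaries from [summarize_days()] for
#'   one participant-wave.
#' @param min_wear_h minimum wear hours for a valid day (default 10).
#' @param min_days minimum number of valid days (default 3).
#' @param min_weekend_days minimum number of valid weekend days (default 1).
#' @param participant_id,wave identifiers carried into the result.
#' @return list with `accepted` (logical); if accepted, `n_valid_days`,
#'   `mean_wear_h`, `mean_sb_min`, `mean_lpa_min`, `mean_mvpa_min`;
#'   otherwise `reason`.
#' @export
filter_valid <- function(days, min_wear_h = 10, min_days = 3,
                         min_weekend_days = 1,
                         participant_id = NA_character_,
                         wave = NA_character_) {
  keep <- days[days$wear_h >= min_wear_h, , drop = FALSE]
  reject <- function(reason)
    list(accepted = FALSE, participant_id = participant_id, wave = wave,
         reason = reason)
  if (nrow(keep) < min_days)
    return(reject(sprintf("only %d day(s) with >= %g wear hours",
                          nrow(keep), min_wear_h)))
  if (sum(keep$is_weekend) < min_weekend_days)
    return(reject(sprintf("only %d valid weekend day(s)",
                          sum(keep$is_weekend))))
  list(accepted = TRUE, participant_id = participant_id, wave = wave,
       n_valid_days = nrow(keep),
       mean_wear_h = mean(keep$wear_h),
       mean_sb_min = mean(keep$sb_min),
       mean_lpa_min = mean(keep$lpa_min),
       mean_mvpa_min = mean(keep$mvpa_min))
}
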