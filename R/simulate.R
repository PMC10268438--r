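#' @title Synthetic cohorts and count series with known ground truth
#' @name synthetic_data
#' @description
#' Generators that emulate the statistical structure assumed by the
#' analysis so that every stage is testable without any external data:
#' logistic-normal 4-part compositions (multivariate normal in pivot ilr
#' space) centred on the published descriptive means, follow-up change
#' drawn in ilr space, marker outcomes generated as the regression design
#' times known coefficients plus (optionally contaminated) Gaussian noise,
#' and per-day accelerometer count schedules with planted non-wear blocks
#' and intensity bouts.
NULL

# default true coefficient vector, aligned with build_design() labels.
# ilr-change effects are sized so 60-min reallocation effects are of the
# order of a few marker units (complement-factor scale); illustrative, not
# an empirical estimate.
default_true_beta <- function() {
  c(`(Intercept)` = 30,
    dilr1 = 25, dilr2 = -18, dilr3 = 6,
    bilr1 = 5, bilr2 = -3, bilr3 = 2,
    marker_baseline = 0.5,
    sex = 2, age = 0.8,
    edu2 = 0.5, edu3 = 1, edu4 = 1.5, edu5 = 2,
    zbmi = 3, zbmi_change = 4,
    pub2 = 0.5, pub3 = 1, pub4 = 1.5, pub5 = 2,
    wear_baseline_h = 0.3, wear_followup_h = -0.2)
}

#' Simulation configuration
#'
#' Defaults mirror the motivating cohort: n = 296; compositional centre
#' and mean follow-up change equal to the published re-scaled geometric
#' means ([reference_timeuse_means()]); between-participant ilr dispersion
#' calibrated to the published descriptive confidence intervals; covariate
#' marginals (sex ratio, age, maternal education, pubertal stage, zBMI,
#' wear time, baseline marker level) matching the published sample
#' description. `beta` holds the generating coefficients in design-column
#' order; `noise_sd` is the residual SD of the marker (marker units);
#' `contamination_frac` of residuals have their SD inflated by
#' `contamination_scale` (symmetric variance inflation, no mean shift).
#'
#' @param n number of participants.
#' @param marker marker name used for the outcome columns.
#' @param baseline_ilr_mean,baseline_ilr_cov mean vector and covariance of
#'   baseline pivot ilr coordinates.
#' @param change_ilr_mean,change_ilr_cov mean and covariance of the ilr
#'   change (follow-up minus baseline).
#' @param beta named true coefficient vector (see [build_design()] labels).
#' @param noise_sd residual SD, marker units.
#' @param contamination_frac fraction of observations with inflated noise.
#' @param contamination_scale noise SD multiplier for contaminated rows.
#' @param sex_p probability of `sex = 1`.
#' @param age_mean,age_sd age distribution (years).
#' @param edu_p,pub_p category probabilities for maternal education and
#'   pubertal stage (5 each, reference level first).
#' @param zbmi_mean,zbmi_sd,dzbmi_sd zBMI level and change distributions.
#' @param marker_baseline_mean,marker_baseline_sd baseline marker level.
#' @param wear_baseline,wear_followup `c(mean, sd)` of wear time (h/day).
#' @param wear_from_composition if `TRUE`, wear time is set to 24 minus
#'   sleep at each wave (device removed only overnight) instead of being
#'   drawn independently; used when counts consistent with the
#'   compositions are also generated.
#' @param part_order pivot order.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    n = 296,
    marker = "c3",
    baseline_ilr_mean = pivot_ilr(reference_composition("baseline")),
    baseline_ilr_cov = diag(c(0.12, 0.18, 0.30)^2),
    change_ilr_mean = pivot_ilr(reference_composition("followup")) -
      pivot_ilr(reference_composition("baseline")),
    change_ilr_cov = diag(c(0.10, 0.15, 0.25)^2),
    beta = default_true_beta(),
    noise_sd = 20,
    contamination_frac = 0,
    contamination_scale = 5,
    sex_p = 0.49,
    age_mean = 12.8, age_sd = 2.4,
    edu_p = c(4, 53, 52, 93, 94) / 296,
    pub_p = c(11, 79, 100, 77, 29) / 296,
    zbmi_mean = 0.62, zbmi_sd = 1.09, dzbmi_sd = 0.5,
    marker_baseline_mean = 89.35, marker_baseline_sd = 27.82,
    wear_baseline = c(14.43, 1.05),
    wear_followup = c(14.32, 1.22),
    wear_from_composition = FALSE,
    part_order = timeuse_parts()) {
  stopifnot(n >= length(beta) + 2,
            length(baseline_ilr_mean) == 3, length(change_ilr_mean) == 3,
            contamination_frac >= 0, contamination_frac < 1,
            abs(sum(edu_p) - 1) < 1e-8, abs(sum(pub_p) - 1) < 1e-8)
  check_cov <- function(S) {
    if (!isTRUE(all.equal(S, t(S))) || any(eigen(S, TRUE)$values < -1e-12))
      stop("covariance must be symmetric positive semi-definite")
  }
  check_cov(baseline_ilr_cov); check_cov(change_ilr_cov)
  structure(as.list(environment()), class = "simulation_config")
}

# multivariate normal draws via Cholesky (semi-definite tolerated)
rmvn <- function(n, mu, S) {
  d <- length(mu)
  if (all(S == 0)) return(matrix(mu, n, d, byrow = TRUE))
  L <- chol(S + diag(1e-12, d))
  matrix(mu, n, d, byrow = TRUE) + matrix(stats::rnorm(n * d), n, d) %*% L
}

#' Simulate a cohort with known ground truth
#'
#' Baseline compositions are inverse-ilr images of multivariate normal
#' draws (logistic-normal law on the simplex); follow-up ilr = baseline
#' ilr + an independent change draw. Covariates are drawn from the config
#' marginals, and the follow-up marker equals the regression design times
#' the true coefficients plus Gaussian noise, with a `contamination_frac`
#' of rows having their noise SD multiplied by `contamination_scale`.
#' Fully reproducible from `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `cohort` (data.frame in [build_design()] schema) and
#'   `truth` (class `truth_record`: generating `beta`, the population mean
#'   baseline composition `base`, and the config).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n <- config$n
  po <- config$part_order

  bilr <- rmvn(n, config$baseline_ilr_mean, config$baseline_ilr_cov)
  filr <- bilr + rmvn(n, config$change_ilr_mean, config$change_ilr_cov)
  bcomp <- t(apply(bilr, 1, inverse_pivot_ilr, total = 24, part_order = po))
  fcomp <- t(apply(filr, 1, inverse_pivot_ilr, total = 24, part_order = po))

  cohort <- data.frame(participant_id = sprintf("P%03d", seq_len(n)))
  cohort[paste0(po, "_baseline")] <- as.data.frame(bcomp)
  cohort[paste0(po, "_followup")] <- as.data.frame(fcomp)
  cohort$sex <- stats::rbinom(n, 1, config$sex_p)
  cohort$age <- stats::rnorm(n, config$age_mean, config$age_sd)
  cohort$maternal_education <- sample(1:5, n, TRUE, config$edu_p)
  cohort$zbmi <- stats::rnorm(n, config$zbmi_mean, config$zbmi_sd)
  cohort$zbmi_change <- stats::rnorm(n, 0, config$dzbmi_sd)
  cohort$pubertal_stage <- sample(1:5, n, TRUE, config$pub_p)
  if (config$wear_from_composition) {
    cohort$wear_baseline_h <- 24 - bcomp[, "sleep"]
    cohort$wear_followup_h <- 24 - fcomp[, "sleep"]
  } else {
    cohort$wear_baseline_h <-
      stats::rnorm(n, config$wear_baseline[1], config$wear_baseline[2])
    cohort$wear_followup_h <-
      stats::rnorm(n, config$wear_followup[1], config$wear_followup[2])
  }
  cohort[[paste0(config$marker, "_baseline")]] <-
    stats::rnorm(n, config$marker_baseline_mean, config$marker_baseline_sd)
  cohort[[paste0(config$marker, "_followup")]] <- 0  # placeholder

  des <- build_design(cohort, config$marker, po)
  if (!all(des$labels %in% names(config$beta)))
    stop("config beta is missing coefficients for: ",
         paste(setdiff(des$labels, names(config$beta)), collapse = ", "))
  mu <- as.vector(des$X %*% config$beta[des$labels])
  noise <- stats::rnorm(n, 0, config$noise_sd)
  if (config$contamination_frac > 0) {
    idx <- sample(n, round(config$contamination_frac * n))
    noise[idx] <- noise[idx] * config$contamination_scale
  }
  cohort[[paste0(config$marker, "_followup")]] <- mu + noise

  truth <- structure(
    list(beta = config$beta,
         base = inverse_pivot_ilr(config$baseline_ilr_mean, 24, po),
         config = config),
    class = "truth_record")
  list(cohort = cohort, truth = truth)
}

#' True substitution effect implied by the generating coefficients
#'
#' The noise-free change in the marker for one reallocation: the ilr-change
#' contrast at `base` dotted with the generating ilr-change coefficients.
#' Zero at zero minutes by construction.
#'
#' @param truth `truth_record` from [simulate_cohort()].
#' @param from,to,minutes the reallocation.
#' @param base starting composition (default: the generator's population
#'   mean baseline composition).
#' @return scalar effect in marker units.
#' @export
true_substitution_effect <- function(truth, from, to, minutes,
                                     base = truth$base) {
  stopifnot(inherits(truth, "truth_record"))
  po <- truth$config$part_order
  dz <- pivot_ilr(reallocate(base, from, to, minutes), po) -
    pivot_ilr(base, po)
  sum(truth$beta[paste0("dilr", seq_along(dz))] * dz)
}

#' Simulate an accelerometer count series from a block schedule
#'
#' Counts are drawn per epoch strictly inside the scaled cut-point bins:
#' non-wear epochs are zero (with up to 2 planted "allowance" minutes per
#' non-wear block, each a single epoch with a 1-99 count total), SB epochs
#' lie in `[1, 100 f)`, LPA in `[100 f, 2000 f)` and MVPA in
#' `[2000 f, mvpa_max_cpm f]`, `f = epoch_s / 60`. The returned ground
#' truth is the schedule itself (planted allowance minutes count as
#' non-wear, since the detection rule absorbs them).
#'
#' Note an identifiability constraint: a pure-SB minute always totals
#' under 100 cpm, so SB minutes bordering a non-wear block can be absorbed
#' by the allowance rule. Schedules meant to be exactly recoverable must
#' therefore border non-wear blocks with LPA or MVPA
#' (see [random_day_schedule()]).
#'
#' @param schedule data.frame with columns `behaviour` (one of `nonwear`,
#'   `sb`, `lpa`, `mvpa`) and `minutes` (positive integers); blocks tile
#'   the day in order, total at most 1440.
#' @param epoch_s epoch length in seconds (default 10).
#' @param start_time start of the series (default a Monday midnight, UTC).
#' @param cuts intensity [cut_points()].
#' @param mvpa_max_cpm upper bound for simulated MVPA counts (default 6000).
#' @param plant_allowance plant 0-2 sub-threshold minutes per non-wear
#'   block (default `TRUE`).
#' @param participant_id,wave identifiers for the series.
#' @return list with `series` (an [epoch_series()]) and `truth`
#'   (data.frame: `nonwear_min`, `sb_min`, `lpa_min`, `mvpa_min`,
#'   `wear_min`).
#' @export
simulate_counts <- function(schedule, epoch_s = 10,
                            start_time = as.POSIXct("2012-03-05 00:00:00",
                                                    tz = "UTC"),
                            cuts = cut_points(), mvpa_max_cpm = 6000,
                            plant_allowance = TRUE,
                            participant_id = NA_character_,
                            wave = NA_character_) {
  stopifnot(is.data.frame(schedule),
            all(c("behaviour", "minutes") %in% names(schedule)))
  beh <- as.character(schedule$behaviour)
  mins <- as.integer(schedule$minutes)
  if (!all(beh %in% c("nonwear", "sb", "lpa", "mvpa")))
    stop("unknown behaviour in schedule")
  if (any(mins < 1) || sum(mins) > 1440)
    stop("schedule blocks must be >= 1 min and tile at most one day")
  epm <- 60L %/% as.integer(epoch_s)
  f <- epoch_s / 60
  sb_hi <- ceiling((cuts$sb_max_cpm + 1) * f) - 1
  lpa_lo <- sb_hi + 1
  lpa_hi <- ceiling(cuts$mvpa_min_cpm * f) - 1
  mvpa_lo <- lpa_hi + 1
  mvpa_hi <- max(mvpa_lo + 1, floor(mvpa_max_cpm * f))

  counts <- integer(0)
  for (i in seq_along(beh)) {
    ne <- mins[i] * epm
    block <- switch(beh[i],
      nonwear = {
        x <- integer(ne)
        if (plant_allowance && mins[i] >= 3) {
          k <- sample(0:2, 1)
          if (k > 0) {
            which_min <- sample(seq_len(mins[i]), k)
            x[(which_min - 1) * epm + 1] <- sample(1:99, k, replace = TRUE)
          }
        }
        x
      },
      sb = sample(1:sb_hi, ne, replace = TRUE),
      lpa = sample(lpa_lo:lpa_hi, ne, replace = TRUE),
      mvpa = sample(mvpa_lo:mvpa_hi, ne, replace = TRUE))
    counts <- c(counts, block)
  }
  series <- epoch_series(counts, epoch_s, start_time, participant_id, wave)
  truth <- data.frame(
    nonwear_min = sum(mins[beh == "nonwear"]),
    sb_min = sum(mins[beh == "sb"]),
    lpa_min = sum(mins[beh == "lpa"]),
    mvpa_min = sum(mins[beh == "mvpa"]))
  truth$wear_min <- sum(mins) - truth$nonwear_min
  list(series = series, truth = truth)
}

#' Random one-day block schedule
#'
#' A plausible day: a long overnight non-wear block (device removed for
#' sleep), an optional daytime non-wear block of 60-150 min, and waking
#' time filled with random SB/LPA/MVPA bouts. Every non-wear block is
#' bordered by LPA so the planted schedule is exactly recoverable by the
#' non-wear rule (see [simulate_counts()]).
#'
#' @param p_daytime_nonwear probability of a daytime non-wear block
#'   (default 0.5).
#' @return data.frame `behaviour`, `minutes` tiling 1440 min.
#' @export
random_day_schedule <- function(p_daytime_nonwear = 0.5) {
  fill_segment <- function(total) {
    blocks <- list()
    left <- total
    while (left > 0) {
      len <- min(left, sample(10:90, 1))
      if (left - len < 5) len <- left
      blocks[[length(blocks) + 1]] <-
        data.frame(behaviour = sample(c("sb", "lpa", "mvpa"), 1,
                                      prob = c(0.55, 0.3, 0.15)),
                   minutes = len)
      left <- left - len
    }
    do.call(rbind, blocks)
  }
  night <- sample(420:560, 1)
  day_nw <- if (stats::runif(1) < p_daytime_nonwear) sample(60:150, 1) else 0
  buf1 <- sample(10:30, 1)
  sched <- data.frame(behaviour = c("nonwear", "lpa"),
                      minutes = c(night, buf1))
  wake <- 1440 - night - buf1
  if (day_nw > 0) {
    buf2 <- sample(10:30, 1); buf3 <- sample(10:30, 1)
    wake <- wake - day_nw - buf2 - buf3
    cut <- sample(seq(50, wake - 50), 1)
    sched <- rbind(sched,
                   fill_segment(cut),
                   data.frame(behaviour = c("lpa", "nonwear", "lpa"),
                              minutes = c(buf2, day_nw, buf3)),
                   fill_segment(wake - cut))
  } else {
    sched <- rbind(sched, fill_segment(wake))
  }
  rownames(sched) <- NULL
  sched
}
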