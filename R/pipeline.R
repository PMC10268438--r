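#' @title End-to-end analysis pipeline
#' @name pipeline
#' @description
#' Orchestrates the stages: accelerometer count files -> per-participant
#' activity -> 24-h compositions -> descriptive table -> per-marker robust
#' compositional fits -> isotemporal-substitution tables, with a
#' machine-readable run manifest. All randomness flows from the single
#' configuration seed (the analysis itself is deterministic); identical
#' configuration and inputs give bit-identical CSV outputs.
NULL

#' Read a count series from a delimited text file
#'
#' Expects header columns `timestamp,counts`; the epoch length is inferred
#' from the first two timestamps unless given.
#'
#' @param path CSV file path.
#' @param participant_id,wave identifiers (default: parsed from the file
#'   name `<participant>_<wave>.csv`).
#' @param epoch_s epoch length in seconds; `NULL` to infer.
#' @param tz time zone of the timestamps (default UTC).
#' @return an [epoch_series()].
#' @export
read_epoch_series <- function(path, participant_id = NULL, wave = NULL,
                              epoch_s = NULL, tz = "UTC") {
  if (is.null(participant_id) || is.null(wave)) {
    bn <- sub("\\.csv$", "", basename(path))
    wave0 <- sub("^.*_", "", bn)
    if (is.null(wave)) wave <- wave0
    if (is.null(participant_id)) participant_id <- sub("_[^_]*$", "", bn)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "counts") %in% names(d)))
    stop("count file must have columns timestamp,counts: ", path)
  ts <- as.POSIXct(d$timestamp, tz = tz)
  if (is.null(epoch_s)) {
    if (nrow(d) < 2) stop("cannot infer epoch length from one row: ", path)
    epoch_s <- as.integer(round(as.numeric(difftime(ts[2], ts[1],
                                                    units = "secs"))))
  }
  epoch_series(d$counts, epoch_s, ts[1], participant_id, wave)
}

#' Process a directory of count files into participant activity
#'
#' Applies reintegration (optional), non-wear detection, cut-point
#' classification, daily summaries and the valid-day filter to every
#' `*_<wave>.csv` file in `counts_dir`.
#'
#' @param counts_dir directory of count CSV files.
#' @param cuts intensity [cut_points()].
#' @param target_epoch_s reintegrate to this epoch length first (`NULL`
#'   to process at the native epoch).
#' @param min_wear_h,min_days,min_weekend_days valid-day rules (see
#'   [filter_valid()]).
#' @param tz time zone of the timestamps.
#' @return list with `activity` (data.frame of accepted participant-waves)
#'   and `rejections` (data.frame with reasons).
#' @export
process_accel <- function(counts_dir, cuts = cut_points(),
                          target_epoch_s = NULL, min_wear_h = 10,
                          min_days = 3, min_weekend_days = 1, tz = "UTC") {
  files <- sort(list.files(counts_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no count files found in ", counts_dir)
  acc <- list(); rej <- list()
  for (f in files) {
    s <- read_epoch_series(f, tz = tz)
    if (!is.null(target_epoch_s) && target_epoch_s != s$epoch_s)
      s <- reintegrate(s, target_epoch_s)
    mask <- detect_nonwear(s)
    labels <- classify_epochs(s, mask, cuts)
    days <- summarize_days(s, labels, mask)
    r <- filter_valid(days, min_wear_h, min_days, min_weekend_days,
                      participant_id = s$participant_id, wave = s$wave)
    if (r$accepted) acc[[length(acc) + 1]] <- as.data.frame(r)
    else rej[[length(rej) + 1]] <- as.data.frame(r)
  }
  list(
    activity = if (length(acc)) do.call(rbind, acc) else data.frame(),
    rejections = if (length(rej)) do.call(rbind, rej) else data.frame()
  )
}

#' Assemble closed compositions from activity and sleep reports
#'
#' Joins accelerometer-derived behaviour durations with self-reported
#' bed/wake times, computes sleep duration, and closes the 4-part vector
#' to 24 h/day.
#'
#' @param activity data.frame from [process_accel()]`$activity`.
#' @param sleep data.frame with columns `participant_id`, `wave`,
#'   `bedtime`, `waketime`.
#' @param delta_min zero-replacement minutes (see [build_composition()]).
#' @return data.frame `participant_id`, `wave`, `sleep`, `sb`, `lpa`,
#'   `mvpa` (closed hours/day) and `mean_wear_h`.
#' @export
assemble_timeuse <- function(activity, sleep, delta_min = 1) {
  d <- merge(activity, sleep, by = c("participant_id", "wave"))
  if (!nrow(d)) stop("no participant-waves with both activity and sleep data")
  comp <- t(mapply(function(b, w, sb, lpa, mvpa)
    build_composition(sleep_duration(b, w), sb, lpa, mvpa,
                      delta_min = delta_min),
    d$bedtime, d$waketime, d$mean_sb_min, d$mean_lpa_min, d$mean_mvpa_min))
  out <- data.frame(participant_id = d$participant_id, wave = d$wave)
  out[timeuse_parts()] <- as.data.frame(comp)
  out$mean_wear_h <- d$mean_wear_h
  out[order(out$participant_id, out$wave), , drop = FALSE]
}

#' Descriptive table of behaviours and markers across waves
#'
#' Behaviour rows: re-scaled geometric means with t-based confidence
#' intervals at each wave, the follow-up minus baseline change, and the
#' p-value of the paired t-test on the behaviour's first pivot coordinate.
#' Marker rows: arithmetic means and SDs with an ordinary paired t-test on
#' the raw values.
#'
#' @param baseline,followup cohorts of compositions (same participants,
#'   same row order).
#' @param markers_baseline,markers_followup optional data.frames of marker
#'   levels (same rows, one column per marker).
#' @param level confidence level for the behaviour intervals.
#' @return data.frame with columns `variable`, `type`, `baseline`,
#'   `baseline_low`, `baseline_high`, `followup`, `followup_low`,
#'   `followup_high`, `change`, `p`.
#' @export
descriptive_table <- function(baseline, followup,
                              markers_baseline = NULL,
                              markers_followup = NULL, level = 0.95) {
  parts <- timeuse_parts()
  rows <- lapply(parts, function(p) {
    cb <- rescaled_geomean_ci(baseline, p, level)
    cf <- rescaled_geomean_ci(followup, p, level)
    tt <- paired_pivot_ttest(baseline, followup, p)
    data.frame(variable = p, type = "behaviour_h",
               baseline = cb[["estimate"]], baseline_low = cb[["lower"]],
               baseline_high = cb[["upper"]],
               followup = cf[["estimate"]], followup_low = cf[["lower"]],
               followup_high = cf[["upper"]],
               change = cf[["estimate"]] - cb[["estimate"]], p = tt$p)
  })
  if (!is.null(markers_baseline)) {
    rows <- c(rows, lapply(names(markers_baseline), function(m) {
      b <- markers_baseline[[m]]; f <- markers_followup[[m]]
      tt <- stats::t.test(f, b, paired = TRUE)
      data.frame(variable = m, type = "marker",
                 baseline = mean(b), baseline_low = NA,
                 baseline_high = NA,
                 followup = mean(f), followup_low = NA, followup_high = NA,
                 change = mean(f - b), p = tt$p.value)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis
#'
#' Executes count processing, composition assembly, the descriptive table
#' and one robust compositional fit plus substitution table per marker,
#' writing CSV outputs and a JSON manifest to `out_dir`. The substitution
#' starting point is the mean baseline composition of the analysed
#' participants.
#'
#' @param config list with entries `counts_dir`, `sleep_csv`,
#'   `cohort_csv`, `out_dir`, `markers` (character vector), and optional
#'   `method` ("robust"/"ols"), `durations`, `part_order`, `min_wear_h`,
#'   `min_days`, `min_weekend_days`, `target_epoch_s`, `delta_min`,
#'   `seed`, `tz`.
#' @return invisibly, a list with the in-memory stage outputs and the
#'   manifest.
#' @export
run_all <- function(config) {
  need <- c("counts_dir", "sleep_csv", "cohort_csv", "out_dir", "markers")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  cfg <- utils::modifyList(
    list(method = "robust", durations = c(10, 30, 60),
         part_order = timeuse_parts(), min_wear_h = 10, min_days = 3,
         min_weekend_days = 1, target_epoch_s = NULL, delta_min = 1,
         seed = 1L, tz = "UTC"),
    config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, name)
    utils::write.csv(d, file.path(cfg$out_dir, name), row.names = FALSE)

  pa <- run_stage("process-accel", process_accel(
    cfg$counts_dir, target_epoch_s = cfg$target_epoch_s,
    min_wear_h = cfg$min_wear_h, min_days = cfg$min_days,
    min_weekend_days = cfg$min_weekend_days, tz = cfg$tz))
  wcsv(pa$activity, "participant_activity.csv")
  wcsv(pa$rejections, "rejections.csv")

  sleep <- run_stage("assemble",
                     utils::read.csv(cfg$sleep_csv, colClasses = "character"))
  comps <- run_stage("assemble",
                     assemble_timeuse(pa$activity, sleep, cfg$delta_min))
  wcsv(comps, "compositions.csv")

  cov <- run_stage("fit", utils::read.csv(cfg$cohort_csv))
  b <- comps[comps$wave == "baseline", ]
  f <- comps[comps$wave == "followup", ]
  both <- intersect(b$participant_id, f$participant_id)
  if (!length(both)) stop("pipeline stage 'fit' failed: no participant ",
                          "with both waves")
  b <- b[match(both, b$participant_id), ]
  f <- f[match(both, f$participant_id), ]

  model_cohort <- run_stage("fit", {
    mc <- data.frame(participant_id = both)
    mc[paste0(timeuse_parts(), "_baseline")] <- b[timeuse_parts()]
    mc[paste0(timeuse_parts(), "_followup")] <- f[timeuse_parts()]
    mc$wear_baseline_h <- b$mean_wear_h
    mc$wear_followup_h <- f$mean_wear_h
    merge(mc, cov, by = "participant_id", sort = TRUE)
  })

  desc <- run_stage("descriptive", {
    mb <- paste0(cfg$markers, "_baseline")
    mf <- paste0(cfg$markers, "_followup")
    miss <- setdiff(c(mb, mf), names(model_cohort))
    if (length(miss))
      stop("missing marker column(s): ", paste(miss, collapse = ", "))
    descriptive_table(
      b[timeuse_parts()], f[timeuse_parts()],
      stats::setNames(model_cohort[mb], cfg$markers),
      stats::setNames(model_cohort[mf], cfg$markers))
  })
  wcsv(desc, "descriptive_table.csv")

  base <- mean_composition(b[timeuse_parts()])
  fits <- list(); subs <- list()
  for (m in cfg$markers) {
    fit <- run_stage(paste0("fit (", m, ")"), {
      des <- build_design(model_cohort, m, cfg$part_order)
      fit_marker_model(des, method = cfg$method)
    })
    tab <- run_stage(paste0("substitute (", m, ")"), {
      tt <- substitution_table(fit, base, cfg$durations)
      cbind(marker = m, tt)
    })
    wcsv(tab, paste0("substitutions_", m, ".csv"))
    fits[[m]] <- fit; subs[[m]] <- tab
  }

  manifest <- list(
    package = "tuscoda",
    version = as.character(utils::packageVersion("tuscoda")),
    seed = cfg$seed,
    method = cfg$method,
    durations = cfg$durations,
    part_order = cfg$part_order,
    markers = cfg$markers,
    n_analysed = length(both),
    inputs = list(counts_dir = cfg$counts_dir, sleep_csv = cfg$sleep_csv,
                  cohort_csv = cfg$cohort_csv),
    valid_day_rules = list(min_wear_h = cfg$min_wear_h,
                           min_days = cfg$min_days,
                           min_weekend_days = cfg$min_weekend_days))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(activity = pa, compositions = comps, descriptive = desc,
                 fits = fits, substitutions = subs, manifest = manifest))
}

#' Write a complete synthetic study bundle to disk
#'
#' Simulates a cohort ([simulate_cohort()] with wear tied to the
#' compositions), realises each participant-wave as `days` consecutive
#' days of accelerometer counts consistent with that participant's
#' composition (overnight device removal as non-wear, behaviours as
#' daytime blocks bordered by LPA), and writes the count files, the sleep
#' report CSV, the covariate/marker CSV and a truth JSON. Bed/wake reports
#' are jittered by up to `sleep_jitter_min` minutes against device
#' non-wear so the 24-h closure is exercised.
#'
#' @param dir output directory (created).
#' @param n participants.
#' @param seed integer seed.
#' @param days days of recording per wave (default 4, Friday-Monday, so a
#'   weekend is always included).
#' @param epoch_s epoch length for the count files (default 60).
#' @param config base [simulation_config()] (its `n` and
#'   `wear_from_composition` are overridden).
#' @param sleep_jitter_min maximum absolute discrepancy between reported
#'   sleep and device non-wear, minutes.
#' @return invisibly, the simulated cohort and truth record.
#' @export
simulate_study_bundle <- function(dir, n = 36, seed = 1, days = 4,
                                  epoch_s = 60,
                                  config = simulation_config(),
                                  sleep_jitter_min = 15) {
  config$n <- n
  config$wear_from_composition <- TRUE
  sim <- simulate_cohort(config, seed = seed)
  cohort <- sim$cohort
  dir.create(file.path(dir, "counts"), showWarnings = FALSE,
             recursive = TRUE)
  # Friday starts so that days 2-3 are the weekend
  wave_start <- c(baseline = as.POSIXct("2011-10-07 00:00:00", tz = "UTC"),
                  followup = as.POSIXct("2013-10-04 00:00:00", tz = "UTC"))
  sleep_rows <- list()
  for (i in seq_len(n)) {
    for (w in c("baseline", "followup")) {
      comp <- stats::setNames(
        as.numeric(cohort[i, paste0(timeuse_parts(), "_", w)]),
        timeuse_parts())
      sb <- round(comp[["sb"]] * 60)
      lpa <- max(round(comp[["lpa"]] * 60), 12)
      mvpa <- max(round(comp[["mvpa"]] * 60), 1)
      night <- 1440 - sb - lpa - mvpa
      sched <- data.frame(
        behaviour = c("nonwear", "lpa", "sb", "lpa", "mvpa"),
        minutes = c(night, 10, sb, lpa - 10, mvpa))
      counts <- integer(0)
      for (d in seq_len(days))
        counts <- c(counts,
                    simulate_counts(sched, epoch_s,
                                    plant_allowance = FALSE)$series$counts)
      s <- epoch_series(counts, epoch_s, wave_start[[w]],
                        cohort$participant_id[i], w)
      ts <- format(s$start_time + (seq_along(counts) - 1) * epoch_s,
                   "%Y-%m-%d %H:%M:%S", tz = "UTC")
      utils::write.csv(
        data.frame(timestamp = ts, counts = counts),
        file.path(dir, "counts",
                  paste0(cohort$participant_id[i], "_", w, ".csv")),
        row.names = FALSE)
      reported <- night + sample(-sleep_jitter_min:sleep_jitter_min, 1)
      bed_min <- 1440 - (reported %/% 2)
      wake_min <- reported - (reported %/% 2)
      fmt <- function(m) sprintf("%02d:%02d", (m %/% 60) %% 24, m %% 60)
      sleep_rows[[length(sleep_rows) + 1]] <- data.frame(
        participant_id = cohort$participant_id[i], wave = w,
        bedtime = fmt(bed_min), waketime = fmt(wake_min))
    }
  }
  utils::write.csv(do.call(rbind, sleep_rows),
                   file.path(dir, "sleep.csv"), row.names = FALSE)
  cov_cols <- c("participant_id", "sex", "age", "maternal_education",
                "zbmi", "zbmi_change", "pubertal_stage",
                paste0(config$marker, c("_baseline", "_followup")))
  utils::write.csv(cohort[cov_cols], file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, n = n, marker = config$marker,
         beta = as.list(sim$truth$beta),
         base = as.list(sim$truth$base)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
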