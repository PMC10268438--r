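# shared fixtures and independent oracles, built in code

mk_series <- function(counts, epoch_s = 60,
                      start = "2012-03-05 00:00:00", tz = "UTC")
  epoch_series(counts, epoch_s, as.POSIXct(start, tz = tz))

# Brute-force non-wear oracle on per-minute totals: mark the union of all
# admissible windows of exactly `window_min` minutes (no minute >= cpm,
# at most `allow` minutes with a non-zero total below cpm). Any admissible
# window longer than `window_min` is covered by its length-`window_min`
# sub-windows (admissibility is inherited by sub-windows), so this union
# equals the union over all windows of length >= `window_min`.
oracle_nonwear_minutes <- function(tot, window_min = 60, allow = 2,
                                   cpm = 100) {
  n <- length(tot)
  covered <- rep(FALSE, n)
  if (n < window_min) return(covered)
  nz <- cumsum(tot > 0 & tot < cpm)
  ac <- cumsum(tot >= cpm)
  nz0 <- c(0, nz); ac0 <- c(0, ac)
  starts <- seq_len(n - window_min + 1)
  ends <- starts + window_min - 1
  ok <- (ac[ends] - ac0[starts]) == 0 & (nz[ends] - nz0[starts]) <= allow
  for (s in starts[ok]) covered[s:(s + window_min - 1)] <- TRUE
  covered
}

# expected wear mask for a series, via the minute-level oracle
oracle_wear_mask <- function(series) {
  epm <- 60L %/% series$epoch_s
  n <- length(series$counts)
  n_min <- n %/% epm
  tot <- if (n_min > 0)
    colSums(matrix(series$counts[seq_len(n_min * epm)], nrow = epm))
  else numeric(0)
  mask <- rep(TRUE, n)
  if (n_min > 0) {
    nonwear <- oracle_nonwear_minutes(tot)
    mask[seq_len(n_min * epm)] <- rep(!nonwear, each = epm)
  }
  mask
}

# random count series alternating zero / sub-threshold / active minute
# runs, with totals spread over the epochs of each minute
random_count_series <- function(epoch_s, max_minutes = 1440) {
  epm <- 60L %/% epoch_s
  tot <- integer(0)
  while (length(tot) < max_minutes) {
    state <- sample(c("zero", "low", "high"), 1, prob = c(0.5, 0.25, 0.25))
    len <- sample(1:120, 1)
    run <- switch(state,
                  zero = integer(len),
                  low = sample(1:99, len, replace = TRUE),
                  high = sample(100:3000, len, replace = TRUE))
    tot <- c(tot, run)
  }
  tot <- tot[seq_len(min(length(tot), max_minutes))]
  counts <- unlist(lapply(tot, function(m) {
    x <- integer(epm)
    x[sample(epm, 1)] <- m
    x
  }))
  # occasionally a trailing partial minute
  if (stats::runif(1) < 0.3)
    counts <- c(counts, sample(0:200, sample(1:(epm), 1), replace = TRUE))
  mk_series(counts, epoch_s)
}

# run the full count-processing chain on one series
process_series <- function(series, cuts = cut_points()) {
  mask <- detect_nonwear(series)
  labels <- classify_epochs(series, mask, cuts)
  list(mask = mask, labels = labels,
       days = summarize_days(series, labels, mask))
}

# all 12 ordered behaviour pairs
behaviour_pairs <- function() {
  g <- expand.grid(from = timeuse_parts(), to = timeuse_parts(),
                   stringsAsFactors = FALSE)
  g[g$from != g$to, ]
}

# random strictly positive composition closed to 24 h
random_composition <- function() {
  x <- stats::rlnorm(4, log(c(9, 10.5, 3, 1)), 0.4)
  stats::setNames(closure(x, 24), timeuse_parts())
}
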