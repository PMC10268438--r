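test_that("reintegration sums blocks, conserves counts and drops partial tails", {
  s <- mk_series(1:10, epoch_s = 1)
  out <- reintegrate(s, 10)
  expect_equal(out$counts, 55)
  expect_equal(out$epoch_s, 10L)

  s10 <- mk_series(c(5, 7, 9), epoch_s = 10)
  expect_identical(reintegrate(s10, 10), s10)

  set.seed(1)
  s1 <- mk_series(sample(0:50, 600, replace = TRUE), epoch_s = 1)
  expect_equal(sum(reintegrate(s1, 10)$counts), sum(s1$counts))

  s_tail <- mk_series(c(rep(1, 26)), epoch_s = 2)
  expect_message(out <- reintegrate(s_tail, 10), "partial")
  expect_equal(length(out$counts), 5)
  expect_equal(sum(out$counts), 25)

  expect_error(reintegrate(s10, 5), "upsample")
  expect_error(reintegrate(mk_series(1:20, 4), 10), "multiple")
})

test_that("non-wear rule: 60 zero minutes flag, shorter runs and 3 interruptions do not", {
  # 60 min of zeros, nothing else
  s <- mk_series(rep(0, 60))
  expect_true(all(!detect_nonwear(s)))

  # 59 zero minutes bounded by active minutes stay worn
  s <- mk_series(c(500, rep(0, 59), 500))
  expect_true(all(detect_nonwear(s)))

  # 60-min zero block bounded by active minutes: 2 sub-threshold minutes
  # are tolerated, a third keeps the block worn
  block2 <- rep(0, 60); block2[c(15, 40)] <- 50
  s2 <- mk_series(c(500, block2, 500))
  expect_equal(detect_nonwear(s2), c(TRUE, rep(FALSE, 60), TRUE))
  block3 <- block2; block3[25] <- 50
  s3 <- mk_series(c(500, block3, 500))
  expect_true(all(detect_nonwear(s3)))

  # a minute at >= 100 cpm always terminates the window: two 59-min zero
  # runs separated by an active minute stay worn
  blockA <- rep(0, 119); blockA[60] <- 100
  sA <- mk_series(c(500, blockA, 500))
  expect_true(all(detect_nonwear(sA)))
})

test_that("non-wear detection matches the brute-force window oracle", {
  set.seed(42)
  for (epoch_s in c(10, 60)) {
    for (r in 1:20) {
      s <- random_count_series(epoch_s)
      expect_identical(detect_nonwear(s), oracle_wear_mask(s))
    }
  }
})

test_that("wear plus non-wear epochs always partition the series", {
  set.seed(7)
  for (r in 1:10) {
    s <- random_count_series(60)
    mask <- detect_nonwear(s)
    expect_equal(sum(mask) + sum(!mask), length(s$counts))
  }
})

test_that("cut-points classify at per-minute bounds and scale to shorter epochs", {
  s60 <- mk_series(c(0, 99, 100, 1999, 2000), epoch_s = 60)
  lab <- classify_epochs(s60, rep(TRUE, 5))
  expect_equal(as.character(lab), c("SB", "SB", "LPA", "LPA", "MVPA"))

  # 10-s epochs: SB/LPA boundary at 100/6
  s10 <- mk_series(c(16, 17, 333, 334), epoch_s = 10)
  expect_equal(as.character(classify_epochs(s10, rep(TRUE, 4))),
               c("SB", "LPA", "LPA", "MVPA"))

  # non-wear overrides any count
  lab2 <- classify_epochs(s60, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(as.character(lab2), c("SB", "NONWEAR", "LPA", "NONWEAR",
                                     "MVPA"))
  expect_error(classify_epochs(s60, rep(TRUE, 3)), "aligned")
})

test_that("worn epochs are partitioned into exactly one intensity each", {
  set.seed(9)
  s <- random_count_series(10)
  mask <- detect_nonwear(s)
  lab <- classify_epochs(s, mask)
  expect_equal(sum(lab %in% c("SB", "LPA", "MVPA")), sum(mask))
  expect_equal(sum(lab == "NONWEAR"), sum(!mask))
})

test_that("daily summaries count labelled epochs and split at midnight", {
  # 12 h fully worn below the scaled SB bound at 10-s epochs
  s <- mk_series(rep(10, 12 * 360), epoch_s = 10)
  d <- summarize_days(s, classify_epochs(s, rep(TRUE, 12 * 360)),
                      rep(TRUE, 12 * 360))
  expect_equal(nrow(d), 1)
  expect_equal(d$wear_h, 12)
  expect_equal(d$sb_min, 720)
  expect_equal(d$lpa_min, 0)
  expect_equal(d$mvpa_min, 0)

  # two hours spanning midnight -> one row per date, split at 00:00
  s2 <- mk_series(rep(150, 120), epoch_s = 60,
                  start = "2012-03-05 23:00:00")
  d2 <- summarize_days(s2, classify_epochs(s2, rep(TRUE, 120)),
                       rep(TRUE, 120))
  expect_equal(nrow(d2), 2)
  expect_equal(d2$date, as.Date(c("2012-03-05", "2012-03-06")))
  expect_equal(d2$lpa_min, c(60, 60))
  expect_equal(d2$is_weekend, c(FALSE, FALSE))

  # random labelled day agrees with a per-label counting oracle
  set.seed(3)
  s3 <- random_count_series(60, max_minutes = 600)
  p <- process_series(s3)
  d3 <- p$days
  expect_equal(sum(d3$sb_min), sum(p$labels == "SB"))
  expect_equal(sum(d3$lpa_min), sum(p$labels == "LPA"))
  expect_equal(sum(d3$mvpa_min), sum(p$labels == "MVPA"))
  expect_equal(sum(d3$wear_h) * 60, sum(p$mask))
})

test_that("valid-day filter enforces wear hours, day count and a weekend day", {
  day <- function(date, wear, sb = 600, lpa = 120, mvpa = 60)
    data.frame(date = as.Date(date), is_weekend = format(as.Date(date),
                                                         "%u") %in% c("6", "7"),
               wear_h = wear, sb_min = sb, lpa_min = lpa, mvpa_min = mvpa)

  # 4 weekdays with ample wear but no weekend day
  wk <- do.call(rbind, lapply(sprintf("2012-03-0%d", 5:8), day, wear = 11))
  r <- filter_valid(wk)
  expect_false(r$accepted)
  expect_match(r$reason, "weekend")

  # only 2 valid days
  r2 <- filter_valid(wk[1:2, ])
  expect_false(r2$accepted)
  expect_match(r2$reason, "day")

  # Sat + 2 weekdays, unweighted mean
  ok <- rbind(day("2012-03-10", 11, sb = 600),
              day("2012-03-05", 11, sb = 620),
              day("2012-03-06", 11, sb = 640))
  r3 <- filter_valid(ok)
  expect_true(r3$accepted)
  expect_equal(r3$n_valid_days, 3)
  expect_equal(r3$mean_sb_min, 620)

  # low-wear days are discarded before counting
  r4 <- filter_valid(rbind(ok, day("2012-03-07", 5)))
  expect_equal(r4$n_valid_days, 3)

  # monotone: adding a valid day never flips acceptance to rejection
  set.seed(4)
  for (i in 1:20) {
    base_days <- rbind(day("2012-03-10", runif(1, 10, 16)),
                       day("2012-03-05", runif(1, 10, 16)),
                       day("2012-03-06", runif(1, 10, 16)))
    extra <- day(sample(c("2012-03-07", "2012-03-11"), 1), runif(1, 10, 16))
    expect_true(filter_valid(rbind(base_days, extra))$accepted)
  }
})
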