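test_that("pivot ilr matches its defining formula and maps equal parts to zero", {
  expect_equal(pivot_ilr(c(6, 6, 6, 6)), c(0, 0, 0), tolerance = 1e-12)

  # 2-part closed form: single coordinate is ln(x/y)/sqrt(2)
  expect_equal(pivot_ilr(c(3, 7)), log(3 / 7) / sqrt(2), tolerance = 1e-12)

  # direct per-coordinate formula as an independent check at D = 4
  set.seed(1)
  x <- random_composition()
  gm <- function(v) exp(mean(log(v)))
  expected <- c(sqrt(3 / 4) * log(x[[1]] / gm(x[2:4])),
                sqrt(2 / 3) * log(x[[2]] / gm(x[3:4])),
                sqrt(1 / 2) * log(x[[3]] / x[[4]]))
  expect_equal(pivot_ilr(x), expected, tolerance = 1e-12)

  expect_error(pivot_ilr(c(1, 0, 2, 3)), "positive")
})

test_that("inverse pivot ilr round-trips and respects the total", {
  expect_equal(inverse_pivot_ilr(c(0, 0, 0)), rep(6, 4), tolerance = 1e-12)

  set.seed(2)
  for (i in 1:100) {
    x <- random_composition()
    back <- inverse_pivot_ilr(pivot_ilr(x), part_order = names(x))
    expect_lt(max(abs(back - x)), 1e-10)
    z <- stats::rnorm(3)
    expect_lt(max(abs(pivot_ilr(inverse_pivot_ilr(z)) - z)), 1e-10)
    # total-1 inverse then closure equals total-24 inverse
    expect_equal(closure(inverse_pivot_ilr(z, total = 1), 24),
                 inverse_pivot_ilr(z, total = 24), tolerance = 1e-12)
  }
})

test_that("pivot ilr is an isometry for the Aitchison distance", {
  set.seed(3)
  for (i in 1:50) {
    x <- random_composition(); y <- random_composition()
    d_ilr <- sqrt(sum((pivot_ilr(x) - pivot_ilr(y))^2))
    expect_lt(abs(d_ilr - aitchison_dist(x, y)), 1e-9)
  }
})

test_that("compositional mean is the closed geometric mean and the ilr-space mean", {
  one <- random_composition()
  cohort <- do.call(rbind, replicate(5, as.data.frame(as.list(one)),
                                     simplify = FALSE))
  expect_equal(mean_composition(cohort), one, tolerance = 1e-12)

  # two participants: geometric mean of sleep 8 and 2 is 4 before closure
  a <- c(sleep = 8, sb = 10, lpa = 3, mvpa = 1)
  b <- c(sleep = 2, sb = 10, lpa = 3, mvpa = 1)
  expect_equal(mean_composition(rbind(a, b)),
               closure(c(sleep = 4, sb = 10, lpa = 3, mvpa = 1)),
               tolerance = 1e-12)

  set.seed(4)
  m <- t(replicate(40, random_composition()))
  colnames(m) <- timeuse_parts()
  ilr_mean <- colMeans(t(apply(m, 1, pivot_ilr, part_order = timeuse_parts())))
  expect_equal(mean_composition(m),
               inverse_pivot_ilr(ilr_mean, part_order = timeuse_parts()),
               tolerance = 1e-10)
  expect_equal(sum(mean_composition(m)), 24, tolerance = 1e-9)

  # permutation equivariance
  perm <- c("lpa", "sleep", "mvpa", "sb")
  expect_equal(mean_composition(m[, perm], parts = perm),
               mean_composition(m)[perm], tolerance = 1e-12)
})

test_that("re-scaled geometric mean intervals collapse, nest and calibrate", {
  one <- random_composition()
  cohort <- do.call(rbind, replicate(4, as.data.frame(as.list(one)),
                                     simplify = FALSE))
  ci <- rescaled_geomean_ci(cohort, "sleep")
  expect_equal(ci[["lower"]], ci[["estimate"]])
  expect_equal(ci[["upper"]], ci[["estimate"]])

  set.seed(5)
  m <- t(replicate(30, random_composition()))
  colnames(m) <- timeuse_parts()
  ci95 <- rescaled_geomean_ci(m, "lpa", 0.95)
  ci99 <- rescaled_geomean_ci(m, "lpa", 0.99)
  expect_lt(ci99[["lower"]], ci95[["lower"]])
  expect_gt(ci99[["upper"]], ci95[["upper"]])

  # Monte-Carlo calibration against independent lognormal durations:
  # the interval for the re-scaled geometric mean is nominal for minor
  # parts and conservative for the dominant part (the closure factor
  # co-moves with its geometric mean), so coverage must be >= ~95%
  # throughout and never degenerate.
  mu <- log(c(9.1, 10.9, 2.9, 1.05)); sdl <- c(0.10, 0.13, 0.25, 0.38)
  truth <- 24 / sum(exp(mu)) * exp(mu)
  set.seed(6)
  hit <- matrix(NA, 300, 4)
  for (r in seq_len(nrow(hit))) {
    sim <- sapply(1:4, function(j) stats::rlnorm(1000, mu[j], sdl[j]))
    colnames(sim) <- timeuse_parts()
    for (j in 1:4) {
      ci <- rescaled_geomean_ci(sim, timeuse_parts()[j])
      hit[r, j] <- ci[["lower"]] <= truth[j] && truth[j] <= ci[["upper"]]
    }
  }
  expect_true(all(colMeans(hit) >= 0.92))
  expect_true(all(colMeans(hit) <= 1))
})

test_that("paired first-pivot test is null at identity and flags zero variance", {
  set.seed(7)
  m <- t(replicate(20, random_composition()))
  colnames(m) <- timeuse_parts()
  r <- paired_pivot_ttest(m, m, "sleep")
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # common Aitchison perturbation -> constant differences, zero variance
  pert <- closure(m * rep(c(1.2, 0.9, 1, 1), each = nrow(m)))
  colnames(pert) <- timeuse_parts()
  expect_error(paired_pivot_ttest(m, pert, "sleep"), "variance")
})

test_that("paired first-pivot test holds its type-I error under the null", {
  set.seed(8)
  n <- 50
  p_vals <- replicate(800, {
    b <- t(replicate(n, random_composition()))
    colnames(b) <- timeuse_parts()
    # independent re-draw of the same law: no systematic change
    f <- t(replicate(n, random_composition()))
    colnames(f) <- timeuse_parts()
    paired_pivot_ttest(b, f, "sb")$p
  })
  expect_gt(mean(p_vals < 0.05), 0.03)
  expect_lt(mean(p_vals < 0.05), 0.07)
})
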