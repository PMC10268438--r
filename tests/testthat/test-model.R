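test_that("regression design has the documented covariate structure", {
  sim <- simulate_cohort(simulation_config(), seed = 1)
  des <- build_design(sim$cohort, "c3")
  expect_equal(ncol(des$X), 22)
  expect_equal(des$labels[1:7],
               c("(Intercept)", "dilr1", "dilr2", "dilr3",
                 "bilr1", "bilr2", "bilr3"))
  expect_true(all(c("marker_baseline", "sex", "age", "zbmi", "zbmi_change",
                    "wear_baseline_h", "wear_followup_h") %in% des$labels))
  expect_equal(sum(grepl("^edu", des$labels)), 4)
  expect_equal(sum(grepl("^pub", des$labels)), 4)
  expect_equal(nrow(des$X), 296)

  # identical waves -> all ilr-change columns vanish
  cfg0 <- simulation_config(change_ilr_mean = rep(0, 3),
                            change_ilr_cov = matrix(0, 3, 3))
  des0 <- build_design(simulate_cohort(cfg0, seed = 2)$cohort, "c3")
  expect_true(all(abs(des0$X[, des0$dilr_idx]) < 1e-12))

  # missing columns are reported by name
  expect_error(build_design(sim$cohort, "crp"), "crp_baseline")
})

test_that("noise-free outcomes are recovered exactly by both estimators", {
  cfg <- simulation_config(noise_sd = 0)
  sim <- simulate_cohort(cfg, seed = 3)
  des <- build_design(sim$cohort, "c3")
  truth <- sim$truth$beta[des$labels]
  for (method in c("ols", "robust")) {
    fit <- fit_marker_model(des, method)
    expect_lt(max(abs(fit$coefficients - truth)), 1e-8)
  }
})

test_that("ordinary least squares agrees with stats::lm", {
  sim <- simulate_cohort(simulation_config(n = 120), seed = 4)
  des <- build_design(sim$cohort, "c3")
  fit <- fit_marker_model(des, "ols")
  ref <- stats::lm(des$y ~ des$X - 1)
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-10)
  expect_equal(unname(fit$vcov), unname(stats::vcov(ref)),
               tolerance = 1e-8)
  expect_equal(fit$df, ref$df.residual)
})

test_that("Huber IRLS agrees with an independent M-estimation routine", {
  skip_if_not_installed("MASS")
  sim <- simulate_cohort(simulation_config(contamination_frac = 0.1),
                         seed = 5)
  des <- build_design(sim$cohort, "c3")
  fit <- fit_marker_model(des, "robust")
  ref <- MASS::rlm(des$X, des$y, psi = MASS::psi.huber,
                   scale.est = "MAD", acc = 1e-10, maxit = 200)
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-5)
  expect_equal(fit$scale, ref$s, tolerance = 1e-3)
})

test_that("robust estimation resists gross outliers better than OLS", {
  cfg <- simulation_config(contamination_frac = 0.1,
                           contamination_scale = 5)
  dn <- c("dilr1", "dilr2", "dilr3")
  err <- sapply(1:30, function(r) {
    sim <- simulate_cohort(cfg, seed = 100 + r)
    des <- build_design(sim$cohort, "c3")
    bt <- sim$truth$beta[dn]
    c(robust = sum((fit_marker_model(des, "robust")$coefficients[dn] - bt)^2),
      ols = sum((fit_marker_model(des, "ols")$coefficients[dn] - bt)^2))
  })
  expect_lt(sqrt(mean(err["robust", ])), sqrt(mean(err["ols", ])))
})

test_that("substitution estimates are unbiased for the generating effects", {
  cfg <- simulation_config()
  est <- tru <- numeric(100)
  for (r in 1:100) {
    sim <- simulate_cohort(cfg, seed = 200 + r)
    fit <- fit_marker_model(build_design(sim$cohort, "c3"))
    est[r] <- estimate_substitution(fit, sim$truth$base,
                                    "sb", "sleep", 60)$delta
    tru[r] <- true_substitution_effect(sim$truth, "sb", "sleep", 60)
  }
  mc_se <- stats::sd(est - tru) / sqrt(length(est))
  expect_lt(abs(mean(est - tru)), 4 * mc_se + 1e-12)
})

test_that("substitution estimates obey the path-reversal identity", {
  sim <- simulate_cohort(simulation_config(), seed = 6)
  fit <- fit_marker_model(build_design(sim$cohort, "c3"))
  base <- sim$truth$base
  for (k in seq_len(nrow(behaviour_pairs()))) {
    p <- behaviour_pairs()[k, ]
    fwd <- estimate_substitution(fit, base, p$from, p$to, 30)
    moved <- reallocate(base, p$from, p$to, 30)
    rev <- estimate_substitution(fit, moved, p$to, p$from, 30)
    expect_lt(abs(fwd$delta + rev$delta), 1e-9)
  }
})

test_that("effects are nonlinear in duration and intervals widen with it", {
  sim <- simulate_cohort(simulation_config(), seed = 7)
  fit <- fit_marker_model(build_design(sim$cohort, "c3"))
  base <- sim$truth$base
  for (k in seq_len(nrow(behaviour_pairs()))) {
    p <- behaviour_pairs()[k, ]
    e10 <- estimate_substitution(fit, base, p$from, p$to, 10)
    e30 <- estimate_substitution(fit, base, p$from, p$to, 30)
    e60 <- estimate_substitution(fit, base, p$from, p$to, 60)
    # log-ratio contrasts are not proportional to minutes
    expect_gt(abs(e60$delta - 6 * e10$delta), 1e-6)
    w <- c(e10$ci_high - e10$ci_low, e30$ci_high - e30$ci_low,
           e60$ci_high - e60$ci_low)
    expect_true(all(diff(w) > 0))
  }
})

test_that("the substitution table covers the feasible grid with consistent flags", {
  sim <- simulate_cohort(simulation_config(), seed = 8)
  fit <- fit_marker_model(build_design(sim$cohort, "c3"))
  tab <- substitution_table(fit, sim$truth$base)
  expect_equal(nrow(tab), 36)
  expect_true(all(tab$ci_low <= tab$delta & tab$delta <= tab$ci_high))
  expect_equal(tab$significant, tab$ci_low > 0 | tab$ci_high < 0)

  # short MVPA makes 60-min reallocations out of it infeasible
  base2 <- c(sleep = 9.2, sb = 11, lpa = 2.97, mvpa = 50 / 60)
  w <- capture_warnings(tab2 <- substitution_table(fit, base2,
                                                   durations = 60))
  expect_length(w, 3)
  expect_match(w, "infeasible", all = TRUE)
  expect_equal(nrow(tab2), 9)
})
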