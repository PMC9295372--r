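test_that("trapezoidal AUC matches hand values and the summation oracle", {
  sched <- sampling_schedule()
  expect_equal(auc_0t(sched, rep(1, length(sched))), 12)
  expect_equal(auc_0t(c(0, 1, 2), c(0, 10, 0)), 10)
  conc <- 100 * exp(-0.5 * sched)
  expect_equal(auc_0t(sched, conc), trapezoid_oracle(sched, conc),
               tolerance = 1e-12)
  expect_error(auc_0t(c(0), c(1)), "at least 2")
  expect_error(auc_0t(c(0, 2, 1), c(1, 1, 1)), "increasing")
})

test_that("AUC is additive over interior grid points", {
  set.seed(1)
  for (rep in 1:5) {
    t <- sort(runif(12, 0, 12))
    y <- runif(12, 1, 100) # strictly positive: last measurable = last point
    k <- sample(2:11, 1)
    expect_equal(auc_0t(t[1:k], y[1:k]) + auc_0t(t[k:12], y[k:12]),
                 auc_0t(t, y))
  }
})

test_that("AUC and lambda_z transform correctly under a time rescale", {
  t <- sampling_schedule()
  y <- simulate_concentration(base_params(), t)
  expect_equal(auc_0t(t * 60, y), 60 * auc_0t(t, y))
  lz_h <- fit_lambda_z(t, y)
  lz_min <- fit_lambda_z(t * 60, y)
  expect_equal(lz_min$lambda_z, lz_h$lambda_z / 60)
})

test_that("lambda_z recovers an exact mono-exponential tail", {
  t <- c(0, 1, 2, 4, 6, 8, 10, 12)
  y <- c(0, 30, 50 * exp(-0.6 * 2), 50 * exp(-0.6 * 4), 50 * exp(-0.6 * 6),
         50 * exp(-0.6 * 8), 50 * exp(-0.6 * 10), 50 * exp(-0.6 * 12))
  # peak at t = 1; everything after decays at exactly 0.6/h
  fit <- fit_lambda_z(t, y)
  expect_equal(fit$lambda_z, 0.6, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
  expect_equal(fit$n_points, length(t) - 2) # all post-peak points
})

test_that("permissive two-point mode applies the two-point formula", {
  t <- c(0, 2, 8, 10)
  y <- c(0, 20, 10, 5)
  strict <- fit_lambda_z(t, y)
  expect_true(is.na(strict$lambda_z)) # needs 3 points after Tmax
  loose <- fit_lambda_z(t, y, min_points = 2)
  expect_equal(loose$lambda_z, log(2) / 2)
  expect_equal(loose$n_points, 2L)
})

test_that("AUC extrapolation composes correctly", {
  expect_equal(auc_0inf(100, 10, 0.5), 120)
  expect_equal(auc_0inf(100, 1e-9, 0.5), 100, tolerance = 1e-8)
  expect_true(is.na(auc_0inf(100, 10, NA_real_)))
  # closed-form profile: AUC0-inf within 2% of D / CL
  p <- base_params()
  t <- sampling_schedule()
  res <- nca_per_subject(t, simulate_concentration(p, t))
  expect_lt(abs(res$auc_0inf - p$dose / p$cl) / (p$dose / p$cl), 0.02)
})

test_that("Cmax/Tmax follow the earliest-maximum rule", {
  r <- nca_per_subject(c(0, 1, 2, 3), c(0, 1, 5, 3))
  expect_equal(r$cmax, 5)
  expect_equal(r$tmax, 2)
  tie <- nca_per_subject(c(0, 2, 4), c(0, 5, 5))
  expect_equal(tie$tmax, 2)
  flagged <- nca_per_subject(c(0, 1, 2), c(0, 0, 0))
  expect_true(all(is.na(flagged)))
})

test_that("recovered lambda_z approaches ke as the grid extends and refines", {
  p <- base_params()
  ke <- p$cl / p$v
  err <- vapply(list(seq(0, 12, by = 1), seq(0, 18, by = 0.5),
                     seq(0, 24, by = 0.25)), function(t) {
    abs(fit_lambda_z(t, simulate_concentration(p, t))$lambda_z - ke) / ke
  }, numeric(1))
  expect_true(all(diff(err) < 0)) # monotone improvement
  expect_lt(err[3], 0.01)
})

test_that("per-subject NCA on a default cohort matches the study scale", {
  coh <- simulate_cohort(100, seed = 31)
  nca <- nca_table(coh$concentrations)
  expect_identical(names(nca)[1], "subject_id")
  expect_true(all(nca$auc_0inf >= nca$auc_0t, na.rm = TRUE))
  expect_equal(nca$t_half, log(2) / nca$lambda_z)
  # cohort mean terminal half-life within 25% of the reference 1.25 h
  expect_lt(abs(mean(nca$t_half, na.rm = TRUE) - 1.25) / 1.25, 0.25)
  # median Tmax in the reference band
  expect_true(median(nca$tmax, na.rm = TRUE) >= 3.5 &&
                median(nca$tmax, na.rm = TRUE) <= 5.5)
})
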