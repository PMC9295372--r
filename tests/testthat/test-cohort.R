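test_that("a fixed seed reproduces the cohort bit for bit", {
  a <- simulate_cohort(15, seed = 7)
  b <- simulate_cohort(15, seed = 7)
  expect_identical(a, b)
  c2 <- simulate_cohort(15, seed = 8)
  expect_false(identical(a$concentrations, c2$concentrations))
})

test_that("covariate sampling follows the per-gender truncated normals", {
  spec <- covariate_spec()
  cov <- sample_covariates(1000, spec, seed = 3)
  # male fraction close to its expectation
  expect_lt(abs(mean(cov$gender == 0) - 23 / 47), 3 * sqrt(0.5^2 / 1000))
  # bounds respected, per gender
  for (i in seq_len(nrow(spec))) {
    v <- cov[[spec$variable[i]]]
    m <- cov$gender == 0
    expect_true(all(v[m] >= spec$min_male[i] & v[m] <= spec$max_male[i]))
    expect_true(all(v[!m] >= spec$min_female[i] & v[!m] <= spec$max_female[i]))
  }
  # male hemoglobin runs higher than female, as specified
  expect_gt(mean(cov$hemoglobin[cov$gender == 0]),
            mean(cov$hemoglobin[cov$gender == 1]))
  # per-gender sample means near the analytic truncated-normal mean
  n_m <- sum(cov$gender == 0)
  i_age <- which(spec$variable == "age")
  mu <- spec$mean_male[i_age]; sg <- spec$sd_male[i_age]
  a <- (spec$min_male[i_age] - mu) / sg
  b <- (spec$max_male[i_age] - mu) / sg
  trunc_mean <- mu + sg * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(cov$age[cov$gender == 0]) - trunc_mean),
            4 * sg / sqrt(n_m))
  # age-group label consistent with the 26-year cut
  expect_identical(cov$age_group == "low", cov$age <= 26)
})

test_that("degenerate SD = 0 spec collapses draws to the clipped mean", {
  spec <- covariate_spec()
  spec$sd_male[] <- 0
  spec$sd_female[] <- 0
  spec$mean_male[spec$variable == "age"] <- 50 # above max 42 -> clipped
  cov <- sample_covariates(20, spec, seed = 1)
  expect_true(all(cov$age[cov$gender == 0] == 42))
  expect_true(all(cov$bmi[cov$gender == 1] ==
                    spec$mean_female[spec$variable == "bmi"]))
})

test_that("invalid cohort arguments are rejected", {
  expect_error(sample_covariates(1), "at least 2")
  bad <- covariate_spec()
  bad$sd_male[1] <- -1
  expect_error(covariate_spec(bad), "SD")
  expect_error(covariate_spec(male_fraction = 1.5), "male_fraction")
  expect_error(pk_model_spec(cl = -1))
  expect_error(pk_model_spec(ka = 0.55, cl = 16500, v = 30000), "degenerate")
})

test_that("zero covariate effects and variability yield base PK parameters", {
  spec <- pk_model_spec(omega_cl = 0, omega_v = 0, omega_ka = 0,
                        theta_age_cl = 0, theta_gender_cl = 0,
                        theta_crea_cl = 0, theta_bmi_v = 0)
  cov <- sample_covariates(10, seed = 1)
  par <- pk_parameters(cov, spec, seed = 2)
  expect_equal(par$cl, rep(spec$cl, 10))
  expect_equal(par$v, rep(spec$v, 10))
  expect_equal(par$ka, rep(spec$ka, 10))
})

test_that("covariate effects point the group contrasts the designed way", {
  cov <- sample_covariates(1000, seed = 5)
  par <- pk_parameters(cov, pk_model_spec(), seed = 6)
  # high age -> higher clearance -> lower exposure (AUCinf = D / CL)
  auc <- par$dose / par$cl
  expect_gt(mean(auc[cov$age_group == "low"]), mean(auc[cov$age_group == "high"]))
  # males (code 0) reach higher peaks than females on average
  cmax <- vapply(seq_len(nrow(par)), function(i)
    max(simulate_concentration(par[i, ], sampling_schedule())), numeric(1))
  expect_gt(mean(cmax[cov$gender == 0]), mean(cmax[cov$gender == 1]))
})

test_that("the closed-form profile matches its analytic properties", {
  p <- base_params()
  ke <- p$cl / p$v
  expect_equal(simulate_concentration(p, c(0, 1, p$tlag)), c(0, 0, 0))
  # peak location within one step of the analytic optimum
  tgrid <- seq(0, 12, by = 0.001)
  conc <- simulate_concentration(p, tgrid)
  t_star <- p$tlag + log(p$ka / ke) / (p$ka - ke)
  expect_lt(abs(tgrid[which.max(conc)] - t_star), 0.002)
  # unimodal after the lag
  after <- conc[tgrid > p$tlag]
  expect_lte(sum(diff(sign(diff(after))) != 0), 1)
  # dense trapezoid to quasi-infinity recovers D / CL within 1%
  tlong <- seq(0, 200, by = 0.01)
  auc <- trapezoid_oracle(tlong, simulate_concentration(p, tlong))
  expect_lt(abs(auc - p$dose / p$cl) / (p$dose / p$cl), 0.01)
  # dose linearity
  p2 <- p; p2$dose <- 2 * p$dose
  expect_equal(simulate_concentration(p2, tgrid), 2 * conc)
  # degenerate ka = ke errors
  pd <- p; pd$ka <- ke
  expect_error(simulate_concentration(pd, tgrid), "degenerate")
})

test_that("assay noise and LLOQ censoring behave as configured", {
  p <- base_params()
  times <- sampling_schedule()
  conc <- simulate_concentration(p, times)
  clean <- apply_noise_and_lloq(times, conc, 0, 0, 0, seed = 1)
  expect_equal(clean$conc_ng_ml, conc)
  expect_false(any(clean$bloq))
  allq <- apply_noise_and_lloq(times, conc, 0, 0, Inf, seed = 1)
  expect_true(all(allq$bloq[times > 0]))
  expect_false(allq$bloq[1])
  # proportional residuals have the configured SD (Monte Carlo)
  many <- rep(100, 1e4)
  obs <- apply_noise_and_lloq(seq_along(many), many, 0.1, 0, 0, seed = 2)
  expect_lt(abs(sd(obs$conc_ng_ml / many - 1) - 0.1), 0.005)
  # predose concentration is exactly zero, always
  noisy <- apply_noise_and_lloq(times, conc, 0.2, 5, 0, seed = 3)
  expect_identical(noisy$conc_ng_ml[1], 0)
})

test_that("the feature table has the declared schema and drops BLOQ rows", {
  pk0 <- pk_model_spec(lloq = 0, prop_sd = 0, add_sd = 0)
  coh <- simulate_cohort(47, pk_spec = pk0, seed = 9)
  feats <- assemble_feature_table(coh$covariates, coh$concentrations)
  expect_equal(nrow(feats), 47 * 15) # all postdose rows kept
  expect_identical(names(feats), c("subject_id", feature_schema(), "conc"))
  # flag three points of one subject below LLOQ -> it contributes 12 rows
  conc <- coh$concentrations
  pick <- which(conc$subject_id == 1 & conc$time_h > 0)[1:3]
  conc$bloq[pick] <- TRUE
  feats2 <- assemble_feature_table(coh$covariates, conc)
  expect_equal(sum(feats2$subject_id == 1), 12)
  # orphan profiles are reported by id
  bad <- conc
  bad$subject_id[1] <- 999
  expect_error(assemble_feature_table(coh$covariates, bad), "999")
})

test_that("cohort files round-trip through their readers", {
  coh <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  cov2 <- read_covariates(file.path(dir, "covariates.csv"))
  con2 <- read_concentrations(file.path(dir, "concentrations.csv"))
  expect_equal(cov2$age, coh$covariates$age)
  expect_identical(cov2$age_group, coh$covariates$age_group)
  expect_equal(con2$conc_ng_ml, coh$concentrations$conc_ng_ml)
  expect_identical(con2$bloq, coh$concentrations$bloq)
})

test_that("a default 200-subject cohort lands inside the calibration bands", {
  coh <- simulate_cohort(200, seed = 20)
  nca <- nca_table(coh$concentrations)
  expect_lt(abs(mean(nca$cmax, na.rm = TRUE) - 379) / 379, 0.40)
  med_tmax <- median(nca$tmax, na.rm = TRUE)
  expect_gte(med_tmax, 3.5)
  expect_lte(med_tmax, 5.5)
})
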