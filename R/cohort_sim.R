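# Synthetic cohort simulation: covariates, individual PK parameters,
# noise-free profiles, assay noise / LLOQ censoring.

# truncated-normal draws by rejection; exact for the stated bounds
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(clamp(mean, lo, hi), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Sample subject covariates from a cohort specification
#'
#' Gender is assigned Bernoulli(male fraction); each covariate is drawn from
#' a per-gender normal truncated to the spec's \[min, max\]. Covariates are
#' drawn independently given gender (the reference cohort reports only
#' marginal summaries). The age-group label splits at 26 years
#' (low: age <= 26), the reference cohort's median-age rule.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param spec a [covariate_spec()].
#' @param seed optional integer; when given, draws are reproducible.
#' @return data.frame with `id`, `gender` (male = 0, female = 1), the ten
#'   covariates, and `age_group` (factor low/high).
#' @examples
#' head(sample_covariates(5, seed = 1))
#' @export
sample_covariates <- function(n_subjects, spec = covariate_spec(), seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop("`n_subjects` must be at least 2", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  if (!is.null(seed)) set.seed(seed)
  male <- runif(n_subjects) < attr(spec, "male_fraction")
  out <- data.frame(id = seq_len(n_subjects),
                    gender = ifelse(male, 0L, 1L))
  for (i in seq_len(nrow(spec))) {
    v <- numeric(n_subjects)
    if (any(male)) {
      v[male] <- rtrunc_norm(sum(male), spec$mean_male[i], spec$sd_male[i],
                             spec$min_male[i], spec$max_male[i])
    }
    if (any(!male)) {
      v[!male] <- rtrunc_norm(sum(!male), spec$mean_female[i], spec$sd_female[i],
                              spec$min_female[i], spec$max_female[i])
    }
    out[[spec$variable[i]]] <- v
  }
  out$age_group <- factor(ifelse(out$age <= 26, "low", "high"),
                          levels = c("low", "high"))
  out
}

#' Individual PK parameters for simulated subjects
#'
#' Applies the covariate model of [pk_model_spec()] plus log-normal
#' between-subject variability:
#' `CL_i = CL * exp(th_age (age - ref)) * exp(th_gender gender) *
#' exp(th_crea (crea - ref)) * exp(eta_CL)`, and analogously
#' `V_i = V * exp(th_bmi (bmi - ref)) * exp(eta_V)`,
#' `ka_i = ka * exp(eta_ka)`. If an individual's ka collides with its
#' ke = CL/V (relative gap below 1e-8), ka is nudged by a relative 1e-6
#' with a warning so the closed-form profile stays defined.
#'
#' @param subjects data.frame from [sample_covariates()].
#' @param spec a [pk_model_spec()].
#' @param seed optional integer seed for the variability draws.
#' @return data.frame with `id`, `cl`, `v`, `ka`, `tlag`, `dose`.
#' @export
pk_parameters <- function(subjects, spec = pk_model_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(subjects)
  eta_cl <- rnorm(n, 0, spec$omega_cl)
  eta_v <- rnorm(n, 0, spec$omega_v)
  eta_ka <- rnorm(n, 0, spec$omega_ka)
  cl <- spec$cl *
    exp(spec$theta_age_cl * (subjects$age - spec$ref_age)) *
    exp(spec$theta_gender_cl * subjects$gender) *
    exp(spec$theta_crea_cl * (subjects$creatinine - spec$ref_crea)) *
    exp(eta_cl)
  v <- spec$v * exp(spec$theta_bmi_v * (subjects$bmi - spec$ref_bmi)) * exp(eta_v)
  ka <- spec$ka * exp(eta_ka)
  ke <- cl / v
  bad <- abs(ka - ke) < 1e-8 * pmax(ka, ke)
  if (any(bad)) {
    warning(sum(bad), " subject(s) had ka == ke; ka perturbed by 1e-6 relative")
    ka[bad] <- ka[bad] * (1 + 1e-6)
  }
  data.frame(id = subjects$id, cl = cl, v = v, ka = ka,
             tlag = spec$tlag, dose = spec$dose)
}

#' Noise-free concentration-time profile
#'
#' One-compartment model with first-order absorption and absolute lag:
#' C(t) = 0 for t <= tlag, otherwise
#' C(t) = D ka / (V (ka - ke)) (exp(-ke t') - exp(-ka t')), t' = t - tlag,
#' ke = CL/V. Concentrations are in the units of dose/V (ng/mL for the
#' defaults).
#'
#' @param params list or one-row data.frame with `dose`, `cl`, `v`, `ka`, `tlag`.
#' @param times sampling times in hours (>= 0).
#' @return numeric vector of concentrations.
#' @examples
#' p <- list(dose = 2e7, cl = 16500, v = 30000, ka = 1.2, tlag = 3)
#' simulate_concentration(p, sampling_schedule())
#' @export
simulate_concentration <- function(params, times) {
  if (any(times < 0)) stop("`times` must be >= 0", call. = FALSE)
  ke <- params$cl / params$v
  ka <- params$ka
  if (abs(ka - ke) < 1e-12 * max(ka, ke)) {
    stop("ka equals ke: one-compartment closed form is degenerate", call. = FALSE)
  }
  tt <- pmax(times - params$tlag, 0)
  conc <- params$dose * ka / (params$v * (ka - ke)) * (exp(-ke * tt) - exp(-ka * tt))
  conc[times <= params$tlag] <- 0
  pmax(conc, 0)
}

#' Apply assay noise and LLOQ censoring to a profile
#'
#' Observed concentration is C (1 + eps_p) + eps_a, floored at zero, applied
#' only where the true concentration is positive (predose stays exactly 0).
#' Postdose values below the LLOQ are flagged and set to 0 (flag-and-drop
#' for modelling; zeros for NCA).
#'
#' @param times,conc the noise-free profile.
#' @param prop_sd,add_sd proportional and additive error SDs (>= 0).
#' @param lloq lower limit of quantification (ng/mL).
#' @param seed optional integer seed.
#' @return data.frame `time_h`, `conc_ng_ml`, `bloq` (logical).
#' @export
apply_noise_and_lloq <- function(times, conc, prop_sd = 0, add_sd = 0,
                                 lloq = 0, seed = NULL) {
  if (prop_sd < 0 || add_sd < 0) stop("error SDs must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- conc
  pos <- conc > 0
  if (any(pos)) {
    obs[pos] <- conc[pos] * (1 + rnorm(sum(pos), 0, prop_sd)) +
      rnorm(sum(pos), 0, add_sd)
  }
  obs <- pmax(obs, 0)
  bloq <- times > 0 & obs < lloq
  obs[bloq] <- 0
  data.frame(time_h = times, conc_ng_ml = obs, bloq = bloq)
}

#' Simulate a complete virtual cohort
#'
#' Draws covariates, individual PK parameters, noise-free profiles on the
#' sampling schedule, then assay noise and LLOQ censoring. A fixed seed
#' yields a bit-identical cohort.
#'
#' @param n_subjects cohort size.
#' @param cov_spec a [covariate_spec()].
#' @param pk_spec a [pk_model_spec()].
#' @param times sampling schedule (hours, first element 0 = predose).
#' @param seed integer seed governing every draw.
#' @return list with `covariates` (one row per subject), `params`
#'   (individual PK parameters) and `concentrations` (long format:
#'   `subject_id`, `time_h`, `conc_ng_ml`, `bloq`).
#' @examples
#' coh <- simulate_cohort(5, seed = 42)
#' head(coh$concentrations)
#' @export
simulate_cohort <- function(n_subjects = 47,
                            cov_spec = covariate_spec(),
                            pk_spec = pk_model_spec(),
                            times = sampling_schedule(),
                            seed = 1) {
  assert_increasing(times)
  set.seed(seed)
  covariates <- sample_covariates(n_subjects, cov_spec)
  params <- pk_parameters(covariates, pk_spec)
  profiles <- lapply(seq_len(n_subjects), function(i) {
    cf <- simulate_concentration(params[i, ], times)
    prof <- apply_noise_and_lloq(times, cf, pk_spec$prop_sd, pk_spec$add_sd,
                                 pk_spec$lloq)
    cbind(subject_id = covariates$id[i], prof)
  })
  concentrations <- do.call(rbind, profiles)
  rownames(concentrations) <- NULL
  list(covariates = covariates, params = params, concentrations = concentrations)
}
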