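#' Covariate distribution specification for the synthetic cohort
#'
#' Per-variable, per-gender truncated-normal parameters (mean, SD, min, max)
#' for the ten demographic/laboratory covariates, plus the male fraction.
#' The default is calibrated to the published characteristics of a cohort of
#' 47 healthy Chinese adults in a single-dose omeprazole study: age (years),
#' body mass index (kg/m^2), hemoglobin (g/L), red blood cells (10^12/L),
#' white blood cells (10^9/L), platelets (10^9/L), ALT (U/L), AST (U/L),
#' blood urea nitrogen (mmol/L), serum creatinine (umol/L).
#'
#' @param table optional replacement data.frame with columns
#'   `variable`, `mean_male`, `sd_male`, `min_male`, `max_male`,
#'   `mean_female`, `sd_female`, `min_female`, `max_female`.
#' @param male_fraction probability that a sampled subject is male;
#'   default 23/47 as in the reference cohort.
#' @return A `covariate_spec` data.frame (with `male_fraction` attribute).
#' @export
covariate_spec <- function(table = NULL, male_fraction = 23 / 47) {
  if (is.null(table)) {
    table <- data.frame(
      variable    = c("age", "bmi", "hemoglobin", "rbc", "wbc",
                      "platelets", "alt", "ast", "bun", "creatinine"),
      mean_male   = c(27.6, 22.1, 153, 4.98, 6.00, 216, 19.0, 17.5, 4.60, 72.3),
      sd_male     = c(6.13, 1.89, 7.78, 0.28, 1.17, 49.3, 3.38, 7.25, 0.94, 8.66),
      min_male    = c(21.0, 19.2, 139, 4.36, 4.40, 114, 14.0, 8.00, 3.10, 54.0),
      max_male    = c(42.0, 25.2, 172, 5.43, 8.80, 307, 26.0, 38.0, 7.00, 89.0),
      mean_female = c(29.2, 21.4, 130, 4.43, 5.70, 231, 18.6, 11.9, 3.69, 52.5),
      sd_female   = c(6.95, 1.68, 9.04, 0.37, 1.32, 57.4, 3.46, 5.50, 0.99, 5.80),
      min_female  = c(20.0, 19.3, 117, 3.77, 4.20, 142, 13.0, 6.00, 1.30, 41.0),
      max_female  = c(42.0, 25.3, 149, 5.52, 9.10, 361, 28.0, 28.0, 5.80, 61.0),
      stringsAsFactors = FALSE
    )
  }
  needed <- c("variable", "mean_male", "sd_male", "min_male", "max_male",
              "mean_female", "sd_female", "min_female", "max_female")
  if (!all(needed %in% names(table))) {
    stop("covariate spec table is missing columns: ",
         paste(setdiff(needed, names(table)), collapse = ", "), call. = FALSE)
  }
  if (any(table$sd_male < 0) || any(table$sd_female < 0)) {
    stop("covariate SDs must be >= 0", call. = FALSE)
  }
  if (any(table$min_male >= table$max_male) ||
      any(table$min_female >= table$max_female)) {
    stop("each covariate needs min < max", call. = FALSE)
  }
  if (male_fraction < 0 || male_fraction > 1) {
    stop("`male_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(table, male_fraction = male_fraction, class = c("covariate_spec", "data.frame"))
}

#' Structural and stochastic model specification for simulated profiles
#'
#' One-compartment, first-order absorption with an absolute lag time,
#' emulating the delayed absorption of an enteric-coated tablet taken under
#' fed conditions. Between-subject variability is log-normal on CL/F, V/F
#' and ka; covariates act multiplicatively (exp of a linear term) on CL/F
#' (age, gender, serum creatinine) and V/F (body mass index).
#'
#' Defaults are calibrated so that a default cohort lands near the published
#' reference summaries ([omeprazole_reference()]): base CL/F 16.5 L/h and
#' V/F 30 L give ke ~ 0.55/h (terminal half-life ~ 1.26 h) and, with
#' ka = 1.2/h and tlag = 3 h, an analytic Tmax of ~ 4.2 h and peak
#' concentration ~ 345 ng/mL for a 20 mg dose. The positive age and gender
#' coefficients on CL/F make the high-age and female groups the lower
#' exposure groups; the negative BMI coefficient on V/F makes higher BMI
#' raise concentrations.
#'
#' @param dose dose in ng (default 20 mg).
#' @param cl,v,ka,tlag base apparent clearance (mL/h), volume (mL),
#'   absorption rate (1/h) and absorption lag (h).
#' @param omega_cl,omega_v,omega_ka log-normal between-subject SDs.
#' @param theta_age_cl,theta_gender_cl,theta_crea_cl multiplicative covariate
#'   effects on CL/F (per year, female vs male, per umol/L).
#' @param theta_bmi_v multiplicative BMI effect on V/F (per kg/m^2).
#' @param ref_age,ref_crea,ref_bmi centering constants (reference-cohort means).
#' @param prop_sd,add_sd residual error components (proportional; additive in
#'   ng/mL).
#' @param lloq lower limit of quantification (ng/mL).
#' @return A validated `pk_model_spec` list.
#' @export
pk_model_spec <- function(dose = 2e7,
                          cl = 16500, v = 30000, ka = 1.2, tlag = 3,
                          omega_cl = 0.3, omega_v = 0.15, omega_ka = 0.25,
                          theta_age_cl = 0.08, theta_gender_cl = 0.6,
                          theta_crea_cl = 0.01, theta_bmi_v = -0.25,
                          ref_age = 28.6, ref_crea = 61.9, ref_bmi = 21.75,
                          prop_sd = 0.10, add_sd = 1, lloq = 2) {
  spec <- list(dose = dose, cl = cl, v = v, ka = ka, tlag = tlag,
               omega_cl = omega_cl, omega_v = omega_v, omega_ka = omega_ka,
               theta_age_cl = theta_age_cl, theta_gender_cl = theta_gender_cl,
               theta_crea_cl = theta_crea_cl, theta_bmi_v = theta_bmi_v,
               ref_age = ref_age, ref_crea = ref_crea, ref_bmi = ref_bmi,
               prop_sd = prop_sd, add_sd = add_sd, lloq = lloq)
  if (any(unlist(spec[c("dose", "cl", "v", "ka")]) <= 0)) {
    stop("dose, cl, v and ka must all be > 0", call. = FALSE)
  }
  if (tlag < 0 || lloq < 0 || prop_sd < 0 || add_sd < 0 ||
      omega_cl < 0 || omega_v < 0 || omega_ka < 0) {
    stop("tlag, lloq, error SDs and omegas must be >= 0", call. = FALSE)
  }
  if (abs(ka - cl / v) < 1e-12 * ka) {
    stop("degenerate model: ka equals ke = cl/v", call. = FALSE)
  }
  structure(spec, class = "pk_model_spec")
}

#' Blood sampling schedule (hours post dose)
#'
#' Predose (0 h) plus 15 postdose samples: 0.5--5 h every 30 min, then
#' 6, 7, 8, 10, 12 h — the rich schedule of the reference study design.
#' @return Numeric vector of 16 times in hours.
#' @export
sampling_schedule <- function() {
  c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5, 6, 7, 8, 10, 12)
}
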