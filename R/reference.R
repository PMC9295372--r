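#' Published reference summaries for a 20 mg omeprazole enteric-coated tablet study
#'
#' Summary statistics reported for a single-dose pharmacokinetic study of
#' 20 mg omeprazole enteric-coated tablets in 47 healthy Chinese adults
#' (23 male / 24 female; median-age split at 26 years into a low-age group,
#' n = 24, and a high-age group, n = 23). These printed group summaries are
#' the calibration targets of [pk_model_spec()] and the inputs to the
#' percent-change and contribution-rate arithmetic that the package
#' recomputes; the underlying subject-level data are not public.
#'
#' @return A list with components:
#' \describe{
#'   \item{group_means}{data.frame of group mean (and SD) Cmax (ng/mL),
#'     AUC0-t and AUC0-inf (ng h/mL) and terminal half-life (h) for the
#'     all-subjects, male, female, low-age and high-age groups, plus the
#'     group median Tmax (h).}
#'   \item{eigenvalues}{the 12 printed eigenvalues of the correlation matrix
#'     of the study's 12 standardized input variables (10 laboratory and
#'     demographic covariates, gender code, sampling time).}
#'   \item{n_subjects, n_male, n_low_age}{cohort sizes.}
#' }
#' @examples
#' ref <- omeprazole_reference()
#' # exposure reduction in the high-age group, recomputed from group means
#' percent_change(ref$group_means["auc_0t", "low_age"],
#'                ref$group_means["auc_0t", "high_age"])
#' @export
omeprazole_reference <- function() {
  groups <- c("all", "male", "female", "low_age", "high_age")
  means <- rbind(
    auc_0t  = c(980, 1067, 715, 1262, 496),
    auc_0inf = c(1063, 1144, 782, 1393, 506),
    cmax    = c(379, 425, 283, 435, 266),
    tmax    = c(4.50, 4.00, 4.50, 4.50, 4.50), # medians
    t_half  = c(1.25, 1.27, 1.14, 1.44, 0.97)
  )
  sds <- rbind(
    auc_0t  = c(1121, 1232, 1000, 1410, 486),
    auc_0inf = c(1264, 1384, 1138, 1598, 499),
    cmax    = c(297, 341, 234, 330, 234),
    tmax    = c(NA, NA, NA, NA, NA),
    t_half  = c(0.64, 0.71, 0.59, 0.81, 0.27)
  )
  colnames(means) <- colnames(sds) <- groups
  list(
    group_means = as.data.frame(means),
    group_sds = as.data.frame(sds),
    eigenvalues = c(3.693, 2.252, 1.220, 1.184, 1.000, 0.869,
                    0.659, 0.354, 0.281, 0.242, 0.155, 0.090),
    n_subjects = 47L,
    n_male = 23L,
    n_low_age = 24L
  )
}
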