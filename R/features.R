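# Modelling feature table and cohort file I/O.

#' Declared 12-variable input schema of the concentration model
#'
#' Ten demographic/laboratory covariates, the gender code (male = 0,
#' female = 1) and the sampling time in hours, in the fixed order used by
#' every downstream stage (PCA, network, MIV).
#' @return character vector of length 12.
#' @export
feature_schema <- function() {
  c("age", "bmi", "hemoglobin", "rbc", "wbc", "platelets",
    "alt", "ast", "bun", "creatinine", "gender", "time_h")
}

#' Assemble the subject-by-timepoint modelling table
#'
#' One row per (subject, postdose timepoint) pairing the subject's 12 input
#' variables with the observed concentration as target. Rows flagged below
#' the LLOQ are excluded; the predose sample never enters.
#'
#' @param subjects covariate table from [sample_covariates()].
#' @param profiles long concentration table (`subject_id`, `time_h`,
#'   `conc_ng_ml`, `bloq`).
#' @return data.frame with `subject_id`, the [feature_schema()] columns, and
#'   `conc`.
#' @export
assemble_feature_table <- function(subjects, profiles) {
  m <- match(profiles$subject_id, subjects$id)
  if (anyNA(m)) {
    orphan <- unique(profiles$subject_id[is.na(m)])
    stop("profiles reference unknown subject id(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  keep <- profiles$time_h > 0 & !profiles$bloq
  m <- m[keep]
  covs <- setdiff(feature_schema(), "time_h")
  out <- data.frame(subject_id = profiles$subject_id[keep])
  for (v in covs) out[[v]] <- subjects[[v]][m]
  out$time_h <- profiles$time_h[keep]
  out$conc <- profiles$conc_ng_ml[keep]
  rownames(out) <- NULL
  out
}

#' Write / read cohort tables
#'
#' `write_cohort()` writes `covariates.csv` (one row per subject) and
#' `concentrations.csv` (long format) into `dir`; the readers re-parse them
#' into the shapes the rest of the package expects.
#'
#' @param cohort list as returned by [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `write_cohort()` the directory, invisibly; the readers a
#'   data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  write.csv(cohort$concentrations, file.path(dir, "concentrations.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param path a CSV file written by `write_cohort()`.
#' @export
read_covariates <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$age_group <- factor(x$age_group, levels = c("low", "high"))
  x
}

#' @rdname write_cohort
#' @export
read_concentrations <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$bloq <- as.logical(x$bloq)
  x
}
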