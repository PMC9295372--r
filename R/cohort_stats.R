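# Group summaries and age/gender comparisons of the NCA parameters.

#' Pooled-variance Student's t-test
#'
#' Classic two-sample Student's t with pooled variance,
#' df = nA + nB - 2, two-sided p. When the pooled variance is zero the test
#' degenerates: equal means give t = 0, p = 1; unequal means are an error.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @examples
#' students_t(c(1, 2, 3), c(2, 3, 4))
#' @export
students_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2", call. = FALSE)
  df <- na + nb - 2
  s2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  if (s2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    stop("zero pooled variance with unequal means: degenerate comparison",
         call. = FALSE)
  }
  tt <- (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Percent change of a comparison group relative to a reference group
#'
#' 100 (ref - cmp) / ref: positive when the comparison group is lower.
#'
#' @param ref_mean,cmp_mean group means; `ref_mean` must be non-zero.
#' @return percent change (full precision; round for reporting).
#' @examples
#' percent_change(435, 266) # peak-concentration reduction, high- vs low-age
#' @export
percent_change <- function(ref_mean, cmp_mean) {
  if (any(ref_mean == 0)) stop("reference mean must be non-zero", call. = FALSE)
  100 * (ref_mean - cmp_mean) / ref_mean
}

#' @rdname summarize_groups
#' @param m,s,lo,hi,digits mean / SD / range values and decimal digits for the
#'   formatting helpers.
#' @export
format_mean_sd <- function(m, s, digits = 3) {
  paste0(signif(m, digits), " ± ", signif(s, digits))
}

#' @rdname summarize_groups
#' @export
format_median_range <- function(m, lo, hi, digits = 2) {
  sprintf("%.*f(%.*f,%.*f)", digits, m, digits, lo, digits, hi)
}

nca_parameters <- c("auc_0t", "auc_0inf", "cmax", "tmax", "t_half")

group_index <- function(covariates) {
  list(all = rep(TRUE, nrow(covariates)),
       male = covariates$gender == 0,
       female = covariates$gender == 1,
       low_age = covariates$age_group == "low",
       high_age = covariates$age_group == "high")
}

#' Group summaries of the NCA parameters
#'
#' Mean and SD (plus median and range) of each PK parameter for the
#' all-subjects, male, female, low-age and high-age groups. With
#' `format = TRUE` a wide character table is returned: `mean ± SD` for
#' AUCs, Cmax and t1/2, `median(min,max)` for Tmax.
#'
#' @param nca per-subject table from [nca_table()].
#' @param covariates subject table carrying `gender` and `age_group`.
#' @param format return formatted strings instead of the long numeric table.
#' @return long numeric data.frame (`parameter`, `group`, `n`, `mean`, `sd`,
#'   `median`, `min`, `max`) or, when formatted, a 5 x 5 character table.
#' @export
summarize_groups <- function(nca, covariates, format = FALSE) {
  merged <- merge(nca, covariates[, c("id", "gender", "age_group")],
                  by.x = "subject_id", by.y = "id")
  groups <- group_index(merged)
  rows <- list()
  for (p in nca_parameters) {
    for (g in names(groups)) {
      v <- merged[[p]][groups[[g]]]
      v <- v[!is.na(v)]
      if (!length(v)) stop("empty group: ", g, call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, group = g, n = length(v),
        mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
        median = median(v), min = min(v), max = max(v))
    }
  }
  long <- do.call(rbind, rows)
  if (!format) return(long)
  wide <- matrix("", nrow = length(nca_parameters), ncol = length(groups),
                 dimnames = list(nca_parameters, names(groups)))
  for (i in seq_len(nrow(long))) {
    r <- long[i, ]
    wide[r$parameter, r$group] <- if (r$parameter == "tmax") {
      format_median_range(r$median, r$min, r$max)
    } else {
      format_mean_sd(r$mean, r$sd)
    }
  }
  as.data.frame(wide)
}

#' Age and gender comparisons of the NCA parameters
#'
#' Pooled Student's t-test of each parameter between the low- vs high-age
#' groups and the male vs female groups (reference groups: low-age, male),
#' with the percent change of the comparison group.
#'
#' @inheritParams summarize_groups
#' @return data.frame: `parameter`, `comparison`, `t`, `df`, `p`,
#'   `pct_change`.
#' @export
group_tests <- function(nca, covariates) {
  merged <- merge(nca, covariates[, c("id", "gender", "age_group")],
                  by.x = "subject_id", by.y = "id")
  comps <- list(
    age = list(ref = merged$age_group == "low", cmp = merged$age_group == "high"),
    gender = list(ref = merged$gender == 0, cmp = merged$gender == 1))
  rows <- list()
  for (p in nca_parameters) {
    for (cn in names(comps)) {
      a <- merged[[p]][comps[[cn]]$ref]
      b <- merged[[p]][comps[[cn]]$cmp]
      tt <- students_t(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, comparison = cn, t = tt$t, df = tt$df, p = tt$p,
        pct_change = percent_change(mean(a, na.rm = TRUE), mean(b, na.rm = TRUE)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
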