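# Noncompartmental analysis: linear trapezoidal AUC, best-adjusted-R^2
# terminal slope, extrapolated AUC, per-subject parameter table.

#' Area under the curve to the last measurable concentration
#'
#' Linear trapezoidal rule over the observed profile. Zeros (predose,
#' below-LLOQ) enter as zero concentrations, so trailing censored samples
#' beyond the first return to zero contribute no area and the integral
#' effectively stops one interval after the last measurable concentration.
#'
#' @param times increasing sampling times.
#' @param conc concentrations (below-LLOQ already set to 0).
#' @return AUC0-t, or `NA` if no measurable concentration exists.
#' @examples
#' auc_0t(c(0, 1, 2), c(0, 10, 0)) # 10
#' @export
auc_0t <- function(times, conc) {
  if (length(times) < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(times) != length(conc)) stop("length mismatch", call. = FALSE)
  assert_increasing(times)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (!any(conc > 0)) return(NA_real_)
  trapz(times, conc)
}

# closed-form simple linear regression of log-concentration on time
loglin_fit <- function(t, ly) {
  n <- length(t)
  mt <- mean(t); my <- mean(ly)
  sxx <- sum((t - mt)^2)
  slope <- sum((t - mt) * (ly - my)) / sxx
  sst <- sum((ly - my)^2)
  sse <- sum((ly - my - slope * (t - mt))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  adj <- if (n > 2 && !is.na(r2)) 1 - (1 - r2) * (n - 1) / (n - 2) else NA_real_
  list(slope = slope, r2 = r2, adj_r2 = adj)
}

#' Terminal elimination rate constant by log-linear regression
#'
#' Candidate point sets are the last 3..m measurable concentrations strictly
#' after Tmax; each gets an unweighted log-linear least-squares fit, and the
#' set with the highest adjusted R^2 wins, with near-ties (within 1e-4)
#' resolved in favour of the larger set — the de-facto standard automatic
#' rule. The
#' slope must be negative (lambda_z > 0) for a candidate to be valid. With
#' `min_points = 2` a two-point fallback is allowed when no 3-point set
#' exists (its adjusted R^2 is undefined and it is never preferred over a
#' valid >= 3-point set).
#'
#' @param times,conc the profile (zeros treated as unmeasurable).
#' @param min_points minimum points in the regression (3, or 2 in
#'   permissive mode).
#' @return list with `lambda_z` (1/h, `NA` when no valid fit), `n_points`,
#'   `adj_r2`.
#' @export
fit_lambda_z <- function(times, conc, min_points = 3) {
  assert_increasing(times)
  flagged <- list(lambda_z = NA_real_, n_points = NA_integer_, adj_r2 = NA_real_)
  if (!any(conc > 0)) return(flagged)
  imax <- which.max(conc)
  elig <- which(conc > 0 & seq_along(conc) > imax)
  m <- length(elig)
  ks <- if (m >= 3) 3:m else integer(0)
  if (!length(ks) && min_points <= 2 && m >= 2) ks <- 2L
  cand <- list()
  for (k in ks) {
    idx <- elig[(m - k + 1L):m]
    fit <- loglin_fit(times[idx], log(conc[idx]))
    lambda <- -fit$slope
    if (!is.finite(lambda) || lambda <= 0) next
    cand[[length(cand) + 1L]] <-
      list(lambda_z = lambda, n_points = k,
           adj_r2 = fit$adj_r2, score = if (k == 2L) -Inf else fit$adj_r2)
  }
  if (!length(cand)) return(flagged)
  scores <- vapply(cand, `[[`, numeric(1), "score")
  if (all(!is.finite(scores))) { # only the two-point fallback survived
    pick <- cand[[length(cand)]]
  } else {
    near <- which(scores >= max(scores) - 1e-4)
    pick <- cand[[near[which.max(vapply(cand[near], `[[`, integer(1),
                                        "n_points"))]]]
  }
  pick[c("lambda_z", "n_points", "adj_r2")]
}

#' Extrapolate AUC to infinity
#'
#' AUC0-inf = AUC0-t + Clast / lambda_z; `NA` when lambda_z is missing or
#' non-positive.
#'
#' @param auc0t AUC to the last measurable concentration.
#' @param clast last measurable concentration (> 0).
#' @param lambda_z terminal rate constant (1/h).
#' @return AUC0-inf (vectorized).
#' @export
auc_0inf <- function(auc0t, clast, lambda_z) {
  out <- auc0t + clast / lambda_z
  out[is.na(lambda_z) | lambda_z <= 0] <- NA_real_
  out
}

#' Noncompartmental parameters for one subject
#'
#' Cmax is the maximum observed concentration and Tmax the earliest time
#' attaining it; AUC0-t, the terminal slope and AUC0-inf compose
#' [auc_0t()], [fit_lambda_z()] and [auc_0inf()]; t1/2 = ln 2 / lambda_z.
#' An all-zero profile yields a flagged (all-`NA`) row.
#'
#' @param times,conc the observed profile.
#' @param min_points passed to [fit_lambda_z()].
#' @return one-row data.frame: `cmax`, `tmax`, `auc_0t`, `auc_0inf`,
#'   `lambda_z`, `t_half`, `lz_n_points`, `lz_adj_r2`, `auc_extrap_pct`.
#' @export
nca_per_subject <- function(times, conc, min_points = 3) {
  assert_increasing(times)
  if (all(conc == 0)) {
    return(data.frame(cmax = NA_real_, tmax = NA_real_, auc_0t = NA_real_,
                      auc_0inf = NA_real_, lambda_z = NA_real_,
                      t_half = NA_real_, lz_n_points = NA_integer_,
                      lz_adj_r2 = NA_real_, auc_extrap_pct = NA_real_))
  }
  cmax <- max(conc)
  tmax <- times[which.max(conc)] # earliest on ties
  auc <- auc_0t(times, conc)
  lz <- fit_lambda_z(times, conc, min_points = min_points)
  clast <- conc[max(which(conc > 0))]
  aucinf <- auc_0inf(auc, clast, lz$lambda_z)
  data.frame(
    cmax = cmax, tmax = tmax, auc_0t = auc, auc_0inf = aucinf,
    lambda_z = lz$lambda_z,
    t_half = ifelse(is.na(lz$lambda_z), NA_real_, log(2) / lz$lambda_z),
    lz_n_points = lz$n_points, lz_adj_r2 = lz$adj_r2,
    auc_extrap_pct = ifelse(is.na(aucinf), NA_real_,
                            100 * (aucinf - auc) / aucinf)
  )
}

#' NCA for every subject of a long concentration table
#'
#' @param concentrations long table (`subject_id`, `time_h`, `conc_ng_ml`).
#' @param min_points passed to [fit_lambda_z()].
#' @return data.frame, one row per subject, `subject_id` plus the
#'   [nca_per_subject()] columns.
#' @export
nca_table <- function(concentrations, min_points = 3) {
  ids <- unique(concentrations$subject_id)
  rows <- lapply(ids, function(id) {
    sub <- concentrations[concentrations$subject_id == id, ]
    sub <- sub[order(sub$time_h), ]
    cbind(subject_id = id,
          nca_per_subject(sub$time_h, sub$conc_ng_ml, min_points = min_points))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
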