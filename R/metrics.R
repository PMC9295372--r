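# Evaluation metrics and predicted-vs-measured paired test.

#' Regression evaluation metrics
#'
#' Pearson R, coefficient of determination R^2 = 1 - SS_res / SS_tot, mean
#' absolute error and root mean squared error, all in the units of the
#' inputs (original concentration units in the pipeline).
#'
#' @param y_true,y_pred equal-length numeric vectors (n >= 2); `y_true`
#'   must not be constant (R is undefined).
#' @return list with `r`, `r2`, `mae`, `rmse`.
#' @export
metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    stop("need two equal-length vectors with n >= 2", call. = FALSE)
  }
  if (sd(y_true) == 0) {
    stop("`y_true` is constant: correlation undefined", call. = FALSE)
  }
  res <- y_true - y_pred
  list(r = cor(y_true, y_pred),
       r2 = 1 - sum(res^2) / sum((y_true - mean(y_true))^2),
       mae = mean(abs(res)),
       rmse = sqrt(mean(res^2)))
}

#' Paired-samples t-test of predicted vs measured values
#'
#' Classic paired t on the differences: t = mean(d) / (sd(d) / sqrt(n)),
#' df = n - 1, two-sided p. Identical vectors give t = 0, p = 1;
#' zero-variance non-zero differences are an error.
#'
#' @param predicted,measured equal-length numeric vectors (n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
paired_t <- function(predicted, measured) {
  if (length(predicted) != length(measured) || length(predicted) < 2) {
    stop("need two equal-length vectors with n >= 2", call. = FALSE)
  }
  d <- predicted - measured
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1))
    stop("zero-variance non-zero differences: degenerate paired test",
         call. = FALSE)
  }
  tt <- mean(d) / (s / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1))
}
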