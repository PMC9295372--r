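# Mean impact value: covariate importance over the full prediction
# function (raw covariates -> standardize -> PCA scores -> network).

#' Perturb one raw input variable up and down
#'
#' Returns two copies of the feature table with the variable multiplied by
#' (1 + factor) and (1 - factor) on the raw (pre-standardization) scale;
#' every other column is untouched. The binary gender code and the sampling
#' time are perturbed multiplicatively like any other variable, mirroring
#' the uniform MIV procedure.
#'
#' @param table feature table.
#' @param variable column name to perturb.
#' @param factor perturbation fraction in \[0, 1); default 0.1.
#' @return list with `up` and `down` tables.
#' @export
perturb_variable <- function(table, variable, factor = 0.1) {
  if (!variable %in% names(table)) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  if (factor < 0 || factor >= 1) stop("`factor` must lie in [0, 1)", call. = FALSE)
  up <- table; down <- table
  up[[variable]] <- table[[variable]] * (1 + factor)
  down[[variable]] <- table[[variable]] * (1 - factor)
  list(up = up, down = down)
}

#' Mean impact value of one variable
#'
#' MIV = mean over rows of prediction(+10%) - prediction(-10%), with
#' predictions in original concentration units. A positive MIV means the
#' variable raises the predicted concentration.
#'
#' @param model fitted model passed to `predict_fn`.
#' @param table feature table (raw scale).
#' @param variable column to perturb.
#' @param factor perturbation fraction.
#' @param predict_fn `function(model, table) -> predictions`; defaults to
#'   [predict()].
#' @return the MIV (ng/mL for the concentration model).
#' @export
compute_miv <- function(model, table, variable, factor = 0.1,
                        predict_fn = predict) {
  pert <- perturb_variable(table, variable, factor)
  mean(predict_fn(model, pert$up) - predict_fn(model, pert$down))
}

#' Restart-stabilized mean impact values
#'
#' Finite-perturbation importance of a single trained network is sensitive
#' to the (random) weight initialization: independent restarts of the same
#' fit can disagree substantially on weakly influential variables. This
#' procedure trains `restarts` networks on the same feature table
#' (identical split, independent initial weights), computes [miv_table()]
#' for each, and reports the per-variable median MIV with ranks recomputed
#' from the medians — the package's recommended way to read covariate
#' importance off the pipeline.
#'
#' @param features table from [assemble_feature_table()].
#' @param restarts number of independently initialized fits.
#' @param seed base seed; restart r uses initial-weight seed
#'   `seed + 100 + r` with a common split seed `seed`.
#' @param ... passed to [fit_conc_model()] (e.g. `optimizer`, `hidden`).
#' @return data.frame as [miv_table()], medians across restarts.
#' @export
stable_miv <- function(features, restarts = 5, seed = 1, ...) {
  mivs <- sapply(seq_len(restarts), function(r) {
    fit <- fit_conc_model(features, split_seed = seed,
                          init_seed = seed + 100 + r,
                          opt_seed = seed + 200 + r, ...)
    miv_table(fit$model, features)$miv
  })
  med <- apply(mivs, 1L, median)
  vars <- feature_schema()
  ord <- order(-abs(med), seq_along(med))
  rank <- integer(length(med))
  rank[ord] <- seq_along(med)
  data.frame(variable = vars, miv = med, sign = sign(med), rank = rank,
             row.names = NULL)
}

#' Mean impact values for all 12 input variables
#'
#' One MIV per schema variable, ranked by absolute value (rank 1 = most
#' influential); ties break in schema order.
#'
#' @inheritParams compute_miv
#' @return data.frame: `variable`, `miv`, `sign`, `rank`.
#' @export
miv_table <- function(model, table, factor = 0.1, predict_fn = predict) {
  vars <- if (!is.null(model$schema)) model$schema else feature_schema()
  miv <- vapply(vars, function(v)
    compute_miv(model, table, v, factor, predict_fn), numeric(1))
  ord <- order(-abs(miv), seq_along(miv))
  rank <- integer(length(miv))
  rank[ord] <- seq_along(miv)
  data.frame(variable = vars, miv = unname(miv), sign = sign(unname(miv)),
             rank = rank, row.names = NULL)
}
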