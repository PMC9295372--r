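# The end-to-end covariates -> concentration model: stored PCA transform,
# range normalizers and network weights, with fitting and serialization.

new_conc_model <- function(pca, x_norm, y_norm, topology, weights,
                           schema = feature_schema()) {
  structure(list(pca = pca, x_norm = x_norm, y_norm = y_norm,
                 topology = topology, weights = weights, schema = schema),
            class = "conc_model")
}

#' Predict concentrations from raw covariates
#'
#' Routes a raw feature table through the stored standardization constants,
#' PCA projection (k selected components), \[-1, 1\] range normalization
#' and the network, then de-normalizes the output back to concentration
#' units.
#'
#' @param object a fitted `conc_model`.
#' @param newdata data.frame containing the [feature_schema()] columns.
#' @param ... unused.
#' @return numeric vector of predicted concentrations (ng/mL).
#' @export
predict.conc_model <- function(object, newdata, ...) {
  scores <- predict(object$pca, newdata[, object$schema, drop = FALSE])
  xn <- range_normalize(scores, object$x_norm)
  yn <- net_forward(object$weights, xn)
  as.numeric(range_denormalize(matrix(yn), object$y_norm))
}

#' Fit the concentration model on a feature table
#'
#' The full modelling stage: random 70/15/15 row split; PCA and both range
#' normalizers fitted on the training rows only (validation and test rows
#' touch no fitting step); optional metaheuristic search for the initial
#' weights (fitness = training MSE of the decoded untrained network);
#' Levenberg-Marquardt training with validation early stopping; evaluation
#' (R, R^2, MAE, RMSE in original units per split) and a paired t-test of
#' predicted vs measured concentrations on the held-out test rows.
#'
#' @param features table from [assemble_feature_table()].
#' @param hidden hidden layer size(s); default 13.
#' @param pca_threshold accumulated-contribution threshold (percent).
#' @param split_ratios train/validation/test fractions.
#' @param optimizer one of `"pso"`, `"woa"`, `"ga"`, `"none"` (random
#'   initial weights).
#' @param opt_config optional config list for the chosen optimizer
#'   (defaults: [pso_config()], [woa_config()], [ga_config()]).
#' @param control a [lm_control()].
#' @param split_seed,init_seed,opt_seed seeds for the row split, the random
#'   initial weights, and the optimizer.
#' @return list with `model` (a `conc_model`), `report` (training report
#'   plus per-split R), `evaluation` (per-split metrics data.frame),
#'   `paired` (test-split paired t), `trace` (optimizer trace or NULL),
#'   `split`, `init_fitness` (training MSE of the initial weights) and
#'   `optimizer`.
#' @export
fit_conc_model <- function(features, hidden = 13, pca_threshold = 90,
                           split_ratios = c(0.70, 0.15, 0.15),
                           optimizer = c("pso", "woa", "ga", "none"),
                           opt_config = NULL, control = lm_control(),
                           split_seed = 1, init_seed = 2, opt_seed = 3) {
  optimizer <- match.arg(optimizer)
  x <- as.matrix(features[, feature_schema()])
  y <- features$conc
  idx <- split_data(nrow(x), split_ratios, seed = split_seed)

  pca <- pca_fit(x[idx$train, , drop = FALSE], threshold = pca_threshold)
  sc_train <- predict(pca, x[idx$train, , drop = FALSE])
  x_norm <- fit_range_normalizer(sc_train)
  y_norm <- fit_range_normalizer(matrix(y[idx$train]))

  xn <- function(rows) range_normalize(predict(pca, x[rows, , drop = FALSE]), x_norm)
  yn <- function(rows) as.numeric(range_normalize(matrix(y[rows]), y_norm))

  topo <- net_topology(pca$k, hidden = hidden, n_output = 1)
  w0 <- init_weights(topo, seed = init_seed)
  trace <- NULL
  fitness <- make_weight_fitness(topo, xn(idx$train), yn(idx$train))
  if (optimizer != "none") {
    cfg <- switch(optimizer,
                  pso = pso_config(init = c(-0.5, 0.5)),
                  woa = woa_config(init = c(-0.5, 0.5)),
                  ga = ga_config(init = c(-0.5, 0.5)))
    cfg <- merge_config(cfg, opt_config)
    cfg$seed <- cfg$seed %||% opt_seed
    res <- switch(optimizer,
                  pso = pso_optimize(fitness, count_parameters(topo), cfg),
                  woa = woa_optimize(fitness, count_parameters(topo), cfg),
                  ga = ga_optimize(fitness, count_parameters(topo), cfg))
    w0 <- decode_weights(res$par, topo)
    trace <- res$trace
  }
  init_fitness <- fitness(encode_weights(w0))

  fit <- train_lm(w0, xn(idx$train), yn(idx$train),
                  x_val = xn(idx$validation), y_val = yn(idx$validation),
                  control = control)
  model <- new_conc_model(pca, x_norm, y_norm, topo, fit$weights)

  evaluation <- do.call(rbind, lapply(c("train", "validation", "test"),
    function(s) {
      rows <- idx[[if (s == "train") "train" else s]]
      m <- metrics(y[rows], predict(model, features[rows, , drop = FALSE]))
      data.frame(split = s, r = m$r, r2 = m$r2, mae = m$mae, rmse = m$rmse)
    }))
  pred_test <- predict(model, features[idx$test, , drop = FALSE])
  paired <- paired_t(pred_test, y[idx$test])
  report <- fit$report
  report$r_train <- evaluation$r[evaluation$split == "train"]
  report$r_validation <- evaluation$r[evaluation$split == "validation"]
  report$r_test <- evaluation$r[evaluation$split == "test"]

  list(model = model, report = report, evaluation = evaluation,
       paired = paired, trace = trace, split = idx,
       init_fitness = init_fitness, optimizer = optimizer,
       history = fit$history)
}

#' Serialize / restore a fitted concentration model
#'
#' JSON round trip of the full prediction function: topology, weights,
#' PCA transform and both range normalizers.
#'
#' @param model a `conc_model`.
#' @param path file path.
#' @return `save_model()` the path invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  payload <- list(
    schema = model$schema,
    topology = model$topology$sizes,
    weights = lapply(model$weights, function(l)
      list(W = as.numeric(l$W), dim = dim(l$W), b = l$b)),
    pca = list(center = unname(model$pca$center),
               scale = unname(model$pca$scale),
               eigenvalues = model$pca$eigenvalues,
               loadings = as.numeric(model$pca$loadings),
               p = ncol(model$pca$loadings),
               k = model$pca$k,
               threshold = model$pca$threshold,
               variables = model$pca$variables),
    x_norm = lapply(model$x_norm, unname),
    y_norm = lapply(model$y_norm, unname))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(p$topology)
  topo <- net_topology(sizes[1L],
                       hidden = if (length(sizes) > 2L) sizes[2:(length(sizes) - 1L)]
                                else integer(0),
                       n_output = sizes[length(sizes)])
  weights <- lapply(seq_len(nrow(p$weights)), function(i) {
    list(W = matrix(p$weights$W[[i]], p$weights$dim[[i]][1L],
                    p$weights$dim[[i]][2L]),
         b = as.numeric(p$weights$b[[i]]))
  })
  pp <- p$pca$p
  cr <- contribution_rates(p$pca$eigenvalues)
  pca <- structure(list(
    center = stats::setNames(p$pca$center, p$pca$variables),
    scale = stats::setNames(p$pca$scale, p$pca$variables),
    eigenvalues = p$pca$eigenvalues,
    loadings = matrix(p$pca$loadings, pp, pp),
    rate = cr$rate, accumulated = cr$accumulated,
    k = as.integer(p$pca$k), threshold = p$pca$threshold,
    variables = p$pca$variables), class = "pca_transform")
  new_conc_model(pca, lapply(p$x_norm, as.numeric),
                 lapply(p$y_norm, as.numeric), topo, weights,
                 schema = p$schema)
}
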