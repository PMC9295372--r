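# Levenberg-Marquardt training with early stopping, plus a plain
# gradient-descent-with-momentum alternative.

#' Training hyperparameters
#'
#' Defaults follow the published concentration model: up to 1000 epochs,
#' performance goal 1e-7, 50 validation checks. `learning_rate` is carried
#' as a configuration field for parity with that setup but is inert under
#' pure Levenberg-Marquardt (which adapts `mu`, not a step size); it is the
#' step size of [train_gdm()]. The `mu` schedule (x10 on a rejected step,
#' x0.1 on acceptance, abort above `mu_max`) is the conventional one.
#'
#' @param epochs maximum training epochs.
#' @param goal stop when training MSE (normalized space) falls below this.
#' @param min_grad stop when the gradient norm falls below this.
#' @param mu,mu_dec,mu_inc,mu_max damping parameter schedule.
#' @param max_fail consecutive epochs without validation improvement before
#'   early stopping.
#' @param learning_rate see description.
#' @return list of control parameters.
#' @export
lm_control <- function(epochs = 1000, goal = 1e-7, min_grad = 1e-7,
                       mu = 0.001, mu_dec = 0.1, mu_inc = 10, mu_max = 1e10,
                       max_fail = 50, learning_rate = 0.001) {
  list(epochs = epochs, goal = goal, min_grad = min_grad, mu = mu,
       mu_dec = mu_dec, mu_inc = mu_inc, mu_max = mu_max,
       max_fail = max_fail, learning_rate = learning_rate)
}

add_delta <- function(weights, delta, topology) {
  decode_weights(encode_weights(weights) + delta, topology)
}

#' Train a network by Levenberg-Marquardt with early stopping
#'
#' Iterates `delta = (J'J + mu I)^-1 J'e` on the training rows; `mu` is
#' multiplied by `mu_inc` until a step reduces the training SSE and by
#' `mu_dec` on acceptance, so the training MSE is non-increasing over
#' accepted steps. Stopping reasons: `max_epochs`, `goal`, `min_grad`,
#' `validation` (no validation-MSE improvement for `max_fail` consecutive
#' epochs), `mu_max` (no descent direction found). When a validation set is
#' supplied the returned weights are those at the best validation MSE.
#'
#' @param weights initial layer list (see [init_weights()] or
#'   [decode_weights()]).
#' @param x,y training inputs and targets (normalized space).
#' @param x_val,y_val optional validation set for early stopping.
#' @param control a [lm_control()].
#' @return list with `weights`, `report` (`mse`, `gradient`, `val_fail`,
#'   `epochs`, `stop_reason`) and `history` (per-epoch training/validation
#'   MSE).
#' @export
train_lm <- function(weights, x, y, x_val = NULL, y_val = NULL,
                     control = lm_control()) {
  x <- as.matrix(x); y <- as.numeric(y)
  topo <- topology_of(weights)
  n <- nrow(x)
  mu <- control$mu
  use_val <- !is.null(x_val)
  best_w <- weights
  val_best <- if (use_val) mean((y_val - net_forward(weights, x_val))^2) else Inf
  fail <- 0L
  reason <- "max_epochs"
  gnorm <- NA_real_
  epochs_run <- 0L
  hist <- list()
  for (ep in seq_len(control$epochs)) {
    jb <- net_jacobian(weights, x)
    e <- y - jb$pred
    sse <- sum(e^2)
    Jte <- crossprod(jb$J, e)
    gnorm <- sqrt(sum((2 * Jte)^2))
    if (gnorm < control$min_grad) { reason <- "min_grad"; break }
    JtJ <- crossprod(jb$J)
    accepted <- FALSE
    while (mu <= control$mu_max) {
      delta <- tryCatch(
        solve(JtJ + diag(mu, ncol(JtJ)), Jte),
        error = function(err) NULL)
      if (!is.null(delta)) {
        w_new <- add_delta(weights, as.numeric(delta), topo)
        sse_new <- sum((y - net_forward(w_new, x))^2)
        if (is.finite(sse_new) && sse_new < sse) {
          weights <- w_new
          sse <- sse_new
          mu <- max(mu * control$mu_dec, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * control$mu_inc
    }
    if (!accepted) { reason <- "mu_max"; break }
    epochs_run <- ep
    mse_val <- NA_real_
    if (use_val) {
      mse_val <- mean((y_val - net_forward(weights, x_val))^2)
      if (mse_val < val_best) {
        val_best <- mse_val
        fail <- 0L
        best_w <- weights
      } else {
        fail <- fail + 1L
        if (fail >= control$max_fail) {
          hist[[ep]] <- c(ep, sse / n, mse_val)
          reason <- "validation"
          break
        }
      }
    }
    hist[[ep]] <- c(ep, sse / n, mse_val)
    if (sse / n <= control$goal) { reason <- "goal"; break }
  }
  final_w <- if (use_val) best_w else weights
  history <- if (length(hist)) {
    h <- do.call(rbind, hist)
    data.frame(epoch = h[, 1L], mse_train = h[, 2L], mse_val = h[, 3L])
  } else {
    data.frame(epoch = integer(0), mse_train = numeric(0), mse_val = numeric(0))
  }
  list(weights = final_w,
       report = list(mse = mean((y - net_forward(final_w, x))^2),
                     gradient = gnorm, val_fail = fail,
                     epochs = epochs_run, stop_reason = reason),
       history = history)
}

#' Batch gradient descent with momentum
#'
#' Simple alternative trainer (constant learning rate, momentum 0.9 by
#' default) for comparison with [train_lm()].
#'
#' @inheritParams train_lm
#' @param learning_rate,momentum,epochs optimizer settings.
#' @return list with `weights` and `history` of training MSE.
#' @export
train_gdm <- function(weights, x, y, learning_rate = 0.001, momentum = 0.9,
                      epochs = 100) {
  x <- as.matrix(x); y <- as.numeric(y)
  topo <- topology_of(weights)
  n <- nrow(x)
  vel <- numeric(count_parameters(topo))
  mse <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    jb <- net_jacobian(weights, x)
    e <- y - jb$pred
    grad <- -2 * crossprod(jb$J, e) / n
    vel <- momentum * vel - learning_rate * as.numeric(grad)
    weights <- add_delta(weights, vel, topo)
    mse[ep] <- mean((y - net_forward(weights, x))^2)
  }
  list(weights = weights, history = data.frame(epoch = seq_len(epochs),
                                               mse_train = mse))
}
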