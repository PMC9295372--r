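# Feedforward network: topology, [-1, 1] range normalization, forward pass,
# analytic Jacobian, data splitting.

#' Network topology
#'
#' Fully connected feedforward layout: log-sigmoid hidden layers, linear
#' output. The default single hidden layer of 13 nodes mirrors the
#' published concentration model (7 PCA-score inputs, 13 hidden nodes, one
#' output).
#'
#' @param n_input number of inputs (>= 1).
#' @param hidden integer vector of hidden layer sizes.
#' @param n_output number of outputs.
#' @return object of class `net_topology` with `sizes`.
#' @export
net_topology <- function(n_input, hidden = 13, n_output = 1) {
  sizes <- c(n_input, hidden, n_output)
  if (any(sizes < 1) || any(sizes != round(sizes))) {
    stop("all layer sizes must be positive integers", call. = FALSE)
  }
  structure(list(sizes = as.integer(sizes)), class = "net_topology")
}

#' Total number of weights and biases
#'
#' Sum over layers of n_in * n_out + n_out; equals the length of the
#' flattened vector used by the metaheuristic optimizers.
#'
#' @param topology a [net_topology()].
#' @return integer parameter count.
#' @examples
#' count_parameters(net_topology(7, 13, 1)) # 118
#' @export
count_parameters <- function(topology) {
  s <- topology$sizes
  sum(s[-length(s)] * s[-1L] + s[-1L])
}

#' Seeded uniform weight initialization
#'
#' @param topology a [net_topology()].
#' @param seed optional integer seed.
#' @param range half-width of the uniform interval (default \[-0.5, 0.5\]).
#' @return list of layers, each `list(W, b)` with `W` an n_in x n_out matrix.
#' @export
init_weights <- function(topology, seed = NULL, range = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  s <- topology$sizes
  lapply(seq_len(length(s) - 1L), function(l) {
    list(W = matrix(runif(s[l] * s[l + 1L], -range, range), s[l], s[l + 1L]),
         b = runif(s[l + 1L], -range, range))
  })
}

# reconstruct the topology implied by a weight list
topology_of <- function(weights) {
  net_topology(nrow(weights[[1L]]$W),
               hidden = if (length(weights) > 1L) {
                 vapply(weights[-length(weights)], function(l) ncol(l$W), 1L)
               } else integer(0),
               n_output = ncol(weights[[length(weights)]]$W))
}

#' Fit and apply a \[-1, 1\] range normalizer
#'
#' `fit_range_normalizer()` records per-column observed min and max;
#' `range_normalize()` maps x to 2 (x - min) / (max - min) - 1 and
#' `range_denormalize()` inverts it exactly.
#'
#' @param x numeric matrix (or vector, treated as one column).
#' @return `fit_range_normalizer()`: list with `min`, `max`; the others the
#'   transformed matrix.
#' @export
fit_range_normalizer <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  if (any(maxs <= mins)) {
    bad <- colnames(x)[maxs <= mins] %||% which(maxs <= mins)
    stop("constant feature(s) cannot be range-normalized: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(min = mins, max = maxs)
}

#' @rdname fit_range_normalizer
#' @param normalizer a fitted normalizer.
#' @export
range_normalize <- function(x, normalizer) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, normalizer$min), 2, normalizer$max - normalizer$min, "/") * 2 - 1
}

#' @rdname fit_range_normalizer
#' @param y normalized values.
#' @export
range_denormalize <- function(y, normalizer) {
  y <- as.matrix(y)
  sweep(sweep((y + 1) / 2, 2, normalizer$max - normalizer$min, "*"),
        2, normalizer$min, "+")
}

#' Forward pass through the network
#'
#' Hidden activations are log-sigmoid, the output is linear; vectorized over
#' rows of `x`.
#'
#' @param weights layer list as from [init_weights()].
#' @param x input matrix (n x n_input); a plain vector is accepted for
#'   single-input nets.
#' @param details also return the per-layer activations (for the Jacobian).
#' @return numeric vector of outputs (single-output nets), or a list when
#'   `details = TRUE`.
#' @export
net_forward <- function(weights, x, details = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, ncol = nrow(weights[[1L]]$W))
  x <- as.matrix(x)
  if (ncol(x) != nrow(weights[[1L]]$W)) {
    stop("input has ", ncol(x), " columns; network expects ",
         nrow(weights[[1L]]$W), call. = FALSE)
  }
  L <- length(weights)
  a <- x
  acts <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    a <- logsig(sweep(a %*% weights[[l]]$W, 2, weights[[l]]$b, "+"))
    acts[[l]] <- a
  }
  out <- sweep(a %*% weights[[L]]$W, 2, weights[[L]]$b, "+")
  y <- if (ncol(out) == 1L) as.numeric(out) else out
  if (!details) return(y)
  list(y = y, activations = acts, x = x)
}

#' Analytic Jacobian of a single-output network
#'
#' Per-sample derivatives of the output with respect to every weight and
#' bias, in the flattening order of [encode_weights()] (layer by layer,
#' column-major W then b). Used by the Levenberg-Marquardt trainer.
#'
#' @param weights layer list (final layer must have one output).
#' @param x input matrix.
#' @return list with `J` (n x n_parameters) and `pred`.
#' @export
net_jacobian <- function(weights, x) {
  fw <- net_forward(weights, x, details = TRUE)
  L <- length(weights)
  if (ncol(weights[[L]]$W) != 1L) {
    stop("Jacobian requires a single-output network", call. = FALSE)
  }
  n <- nrow(fw$x)
  blocks <- vector("list", L)
  delta <- matrix(1, n, 1L) # d y / d (output pre-activation)
  for (l in L:1L) {
    a_prev <- if (l == 1L) fw$x else fw$activations[[l - 1L]]
    n_in <- ncol(a_prev); n_out <- ncol(delta)
    JW <- a_prev[, rep(seq_len(n_in), n_out), drop = FALSE] *
      delta[, rep(seq_len(n_out), each = n_in), drop = FALSE]
    blocks[[l]] <- cbind(JW, delta)
    if (l > 1L) {
      ap <- fw$activations[[l - 1L]]
      delta <- (delta %*% t(weights[[l]]$W)) * (ap * (1 - ap))
    }
  }
  list(J = do.call(cbind, blocks), pred = fw$y)
}

#' Random train/validation/test partition
#'
#' Validation and test sizes are `round(ratio * n)`; the remainder goes to
#' training. The partition is disjoint and exhaustive; test rows take part
#' in no stage of model fitting.
#'
#' @param n_rows number of rows to split.
#' @param ratios length-3 positive vector summing to 1.
#' @param seed optional integer seed.
#' @return list with integer index vectors `train`, `validation`, `test`.
#' @export
split_data <- function(n_rows, ratios = c(0.70, 0.15, 0.15), seed = NULL) {
  if (length(ratios) != 3L || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop("`ratios` must be 3 positive numbers summing to 1", call. = FALSE)
  }
  n_val <- round(ratios[2L] * n_rows)
  n_test <- round(ratios[3L] * n_rows)
  n_train <- n_rows - n_val - n_test
  if (min(n_train, n_val, n_test) < 1L) {
    stop("a split is empty with n_rows = ", n_rows, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n_rows)
  list(train = perm[seq_len(n_train)],
       validation = perm[n_train + seq_len(n_val)],
       test = perm[n_train + n_val + seq_len(n_test)])
}
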