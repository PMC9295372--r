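test_that("range normalization maps extremes and inverts exactly", {
  set.seed(10)
  x <- matrix(runif(60, -3, 7), 20, 3)
  nrm <- fit_range_normalizer(x)
  y <- range_normalize(x, nrm)
  expect_equal(range(y), c(-1, 1))
  mid <- matrix((nrm$min + nrm$max) / 2, 1)
  expect_equal(as.numeric(range_normalize(mid, nrm)), rep(0, 3))
  expect_equal(range_denormalize(y, nrm), x, tolerance = 1e-12)
  expect_error(fit_range_normalizer(cbind(x, 1)), "constant")
})

test_that("the forward pass matches pencil-and-paper values", {
  topo <- net_topology(1, hidden = 1, n_output = 1)
  w0 <- decode_weights(rep(0, 4), topo)
  expect_equal(net_forward(w0, matrix(c(-3, 0, 5))), c(0, 0, 0))
  # hand-set single hidden unit
  w <- list(list(W = matrix(2), b = -1), list(W = matrix(3), b = 0.5))
  a <- 1 / (1 + exp(-(2 * 0.7 - 1)))
  expect_equal(net_forward(w, matrix(0.7)), 3 * a + 0.5)
  expect_error(net_forward(w, matrix(1:4, 2, 2)), "expects")
})

test_that("the analytic Jacobian matches central finite differences", {
  for (sizes in list(c(3, 4, 1), c(3, 4, 3, 1))) {
    topo <- net_topology(sizes[1], hidden = sizes[2:(length(sizes) - 1)],
                         n_output = 1)
    w <- init_weights(topo, seed = 11)
    x <- matrix(rnorm(5 * sizes[1], sd = 0.5), 5, sizes[1])
    J <- net_jacobian(w, x)$J
    v <- encode_weights(w)
    h <- 1e-6
    Jnum <- sapply(seq_along(v), function(j) {
      vp <- v; vm <- v
      vp[j] <- v[j] + h; vm[j] <- v[j] - h
      (net_forward(decode_weights(vp, topo), x) -
         net_forward(decode_weights(vm, topo), x)) / (2 * h)
    })
    expect_equal(J, Jnum, tolerance = 1e-6)
  }
})

test_that("parameter counting matches the flattened vector", {
  expect_equal(count_parameters(net_topology(7, 13, 1)), 118)
  expect_equal(count_parameters(net_topology(1, 1, 1)), 4)
  topo <- net_topology(5, hidden = c(6, 3), n_output = 1)
  expect_equal(length(encode_weights(init_weights(topo, seed = 1))),
               count_parameters(topo))
})

test_that("data splitting partitions rows with remainder to training", {
  s <- split_data(20, seed = 12)
  expect_equal(lengths(s), c(train = 14L, validation = 3L, test = 3L))
  expect_setequal(c(s$train, s$validation, s$test), 1:20)
  expect_identical(split_data(100, seed = 3), split_data(100, seed = 3))
  expect_false(identical(split_data(100, seed = 3)$train,
                         split_data(100, seed = 4)$train))
  expect_error(split_data(3, c(0.98, 0.01, 0.01)), "empty")
  expect_error(split_data(10, c(0.5, 0.5, 0.5)), "summing")
})

test_that("LM training defaults mirror the published hyperparameters", {
  ctl <- lm_control()
  expect_equal(ctl$epochs, 1000)
  expect_equal(ctl$goal, 1e-7)
  expect_equal(ctl$max_fail, 50)
  expect_equal(ctl$learning_rate, 0.001)
})

test_that("LM training fits a quadratic and decreases monotonically", {
  set.seed(13)
  x <- matrix(seq(-1, 1, length.out = 50))
  y <- as.numeric(x^2)
  topo <- net_topology(1, hidden = 8, n_output = 1)
  w0 <- init_weights(topo, seed = 14)
  fit <- train_lm(w0, x, y, control = lm_control(epochs = 200))
  expect_lt(fit$report$mse, 1e-3)
  expect_true(all(diff(fit$history$mse_train) <= 1e-15))
  # zero allowed epochs leaves the weights untouched
  fit0 <- train_lm(w0, x, y, control = lm_control(epochs = 0))
  expect_identical(encode_weights(fit0$weights), encode_weights(w0))
  expect_identical(fit0$report$stop_reason, "max_epochs")
  expect_equal(fit0$report$epochs, 0L)
})

test_that("validation early stopping reports its counter at max_fail", {
  set.seed(15)
  x <- matrix(rnorm(40)); y <- rnorm(40) # pure noise -> quick overfit
  xv <- matrix(rnorm(20)); yv <- rnorm(20)
  topo <- net_topology(1, hidden = 6, n_output = 1)
  fit <- train_lm(init_weights(topo, seed = 16), x, y, xv, yv,
                  control = lm_control(epochs = 500, max_fail = 4))
  expect_identical(fit$report$stop_reason, "validation")
  expect_equal(fit$report$val_fail, 4L)
})

test_that("training is bit-reproducible for fixed seeds", {
  x <- matrix(seq(-1, 1, length.out = 30))
  y <- sin(2 * x[, 1])
  topo <- net_topology(1, hidden = 4, n_output = 1)
  f1 <- train_lm(init_weights(topo, seed = 17), x, y,
                 control = lm_control(epochs = 50))
  f2 <- train_lm(init_weights(topo, seed = 17), x, y,
                 control = lm_control(epochs = 50))
  expect_identical(encode_weights(f1$weights), encode_weights(f2$weights))
})

test_that("gradient-descent-with-momentum reduces the training error", {
  set.seed(18)
  x <- matrix(seq(-1, 1, length.out = 40))
  y <- as.numeric(0.5 * x)
  topo <- net_topology(1, hidden = 3, n_output = 1)
  w0 <- init_weights(topo, seed = 19)
  fit <- train_gdm(w0, x, y, learning_rate = 0.05, epochs = 200)
  expect_lt(tail(fit$history$mse_train, 1), mean((y - net_forward(w0, x))^2))
})
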