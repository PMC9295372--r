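test_that("weight encoding is a bijection consistent with the topology", {
  topo <- net_topology(4, hidden = c(5, 3), n_output = 1)
  w <- init_weights(topo, seed = 20)
  v <- encode_weights(w)
  expect_equal(length(v), count_parameters(topo))
  w2 <- decode_weights(v, topo)
  expect_identical(encode_weights(w2), v)
  expect_equal(w2, w)
  expect_error(decode_weights(v[-1], topo), "length")
})

test_that("permuting hidden units changes the vector, not the function", {
  topo <- net_topology(2, hidden = 3, n_output = 1)
  w <- init_weights(topo, seed = 21)
  perm <- c(3, 1, 2)
  wp <- list(list(W = w[[1]]$W[, perm], b = w[[1]]$b[perm]),
             list(W = w[[2]]$W[perm, , drop = FALSE], b = w[[2]]$b))
  x <- matrix(rnorm(10), 5, 2)
  expect_false(identical(encode_weights(w), encode_weights(wp)))
  expect_equal(net_forward(w, x), net_forward(wp, x))
})

test_that("the swarm step reproduces hand-computed updates", {
  cfg <- pso_config(pop = 2, iters = 10, c1 = 1, c2 = 1,
                    bounds = c(-5, 5), v_bounds = c(-1, 1))
  state <- list(X = matrix(0, 1, 1), V = matrix(1, 1, 1),
                P = matrix(2, 1, 1), pfit = 0,
                gbest = 4, gfit = 0, iter = 0L)
  out <- pso_step(state, cfg, function(x) 99, inertia = 0.5,
                  r1 = matrix(0.5), r2 = matrix(0.5))
  # V' = 0.5*1 + 0.5*(2-0) + 0.5*(4-0) = 3.5, clamped to 1; x' = 1
  expect_equal(out$V[1, 1], 1)
  expect_equal(out$X[1, 1], 1)
  expect_equal(out$gfit, 0) # worse candidate rejected, best retained
  # pure drift: inertia 1, c1 = c2 = 0
  cfg0 <- pso_config(pop = 2, iters = 10, c1 = 0, c2 = 0, inertia = 1,
                     v_bounds = c(-2, 2))
  drift <- pso_step(state, cfg0, function(x) 99, inertia = 1)
  expect_equal(drift$V[1, 1], 1)
  expect_equal(drift$X[1, 1], 1)
  # fixed point: x = pbest = gbest, inertia 0
  fx <- list(X = matrix(2, 1, 1), V = matrix(0, 1, 1), P = matrix(2, 1, 1),
             pfit = 1, gbest = 2, gfit = 1, iter = 0L)
  still <- pso_step(fx, cfg, function(x) 1, inertia = 0)
  expect_equal(still$X[1, 1], 2)
  expect_equal(still$V[1, 1], 0)
})

test_that("whale moves honour their analytic limit cases", {
  leader <- c(1, -2)
  # spiral branch with the whale at the leader stays put (D = 0)
  expect_equal(pkswarm:::woa_move(leader, leader, c(9, 9), a = 1, b = 1,
                                  p = 0.1, p_spiral = 0.5,
                                  r1 = c(0.3, 0.3), r2 = c(0.7, 0.7),
                                  l = c(0.25, -0.5)),
               leader)
  # final iteration (a = 0) collapses encircling onto the leader
  expect_equal(pkswarm:::woa_move(c(4, 4), leader, c(9, 9), a = 0, b = 1,
                                  p = 0.9, p_spiral = 0.5,
                                  r1 = c(0.2, 0.8), r2 = c(0.5, 0.5),
                                  l = c(0, 0)),
               leader)
})

test_that("all three optimizers pass their convergence benchmarks", {
  sphere <- function(x) sum(x^2)
  p <- pso_optimize(sphere, 5, pso_config(seed = 22))
  expect_lt(p$value, 1e-2)
  w <- woa_optimize(sphere, 5, woa_config(seed = 23))
  expect_lt(w$value, 1e-1)
  g <- ga_optimize(function(x) (x - 3)^2, 1, ga_config(seed = 24))
  expect_lt(abs(g$par - 3), 0.1)
  for (res in list(p, w, g)) {
    expect_true(all(diff(res$trace) <= 0)) # monotone best-so-far
    expect_true(all(res$par >= -5 & res$par <= 5))
  }
})

test_that("fixed seeds give bit-identical optimizer traces", {
  sphere <- function(x) sum(x^2)
  expect_identical(pso_optimize(sphere, 3, pso_config(pop = 10, iters = 20, seed = 5)),
                   pso_optimize(sphere, 3, pso_config(pop = 10, iters = 20, seed = 5)))
  expect_identical(woa_optimize(sphere, 3, woa_config(pop = 10, iters = 20, seed = 5)),
                   woa_optimize(sphere, 3, woa_config(pop = 10, iters = 20, seed = 5)))
  expect_identical(ga_optimize(sphere, 3, ga_config(pop = 10, gens = 20, seed = 5)),
                   ga_optimize(sphere, 3, ga_config(pop = 10, gens = 20, seed = 5)))
})

test_that("a constant fitness leaves the initial best in place", {
  res <- pso_optimize(function(x) 7, 3, pso_config(pop = 8, iters = 10, seed = 25))
  expect_equal(res$value, 7)
  expect_true(all(res$trace == 7))
})

test_that("turning GA operators off collapses evolution onto the elite", {
  sphere <- function(x) sum(x^2)
  cfg <- ga_config(pop = 10, gens = 15, crossover = 0, mutation = 0, seed = 26)
  res <- ga_optimize(sphere, 2, cfg)
  expect_true(all(res$trace == res$trace[1])) # nothing new can appear
})

test_that("weight fitness is the forward-pass MSE and improves under LM", {
  topo <- net_topology(2, hidden = 3, n_output = 1)
  set.seed(27)
  x <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20) - mean(rnorm(20)) # centered targets
  y <- y - mean(y)
  fitness <- make_weight_fitness(topo, x, y)
  expect_equal(fitness(rep(0, count_parameters(topo))), mean(y^2))
  w0 <- init_weights(topo, seed = 28)
  trained <- train_lm(w0, x, y, control = lm_control(epochs = 30))
  expect_lte(fitness(encode_weights(trained$weights)),
             fitness(encode_weights(w0)))
})
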