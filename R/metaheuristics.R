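# Global optimizers over flattened weight vectors: particle swarm, whale
# optimization, and a real-coded genetic algorithm. All three minimize,
# share the bound conventions, and report a monotone best-fitness trace.

#' Flatten / rebuild network weights
#'
#' `encode_weights()` concatenates, layer by layer, the column-major
#' entries of each weight matrix followed by its bias vector;
#' `decode_weights()` inverts the flattening for a given topology. The
#' mapping is bijective; note that permuting hidden units changes the
#' vector without changing the network function (the usual weight-space
#' symmetry).
#'
#' @param weights layer list.
#' @return numeric vector of length [count_parameters()].
#' @export
encode_weights <- function(weights) {
  unlist(lapply(weights, function(l) c(as.numeric(l$W), l$b)), use.names = FALSE)
}

#' @rdname encode_weights
#' @param vector flattened parameter vector.
#' @param topology a [net_topology()].
#' @export
decode_weights <- function(vector, topology) {
  s <- topology$sizes
  if (length(vector) != count_parameters(topology)) {
    stop("vector length ", length(vector), " does not match topology (",
         count_parameters(topology), " parameters)", call. = FALSE)
  }
  pos <- 0L
  out <- vector("list", length(s) - 1L)
  for (l in seq_len(length(s) - 1L)) {
    nw <- s[l] * s[l + 1L]
    W <- matrix(vector[pos + seq_len(nw)], s[l], s[l + 1L])
    pos <- pos + nw
    b <- vector[pos + seq_len(s[l + 1L])]
    pos <- pos + s[l + 1L]
    out[[l]] <- list(W = W, b = b)
  }
  out
}

#' Training-set MSE of a decoded, untrained network
#'
#' The fitness the optimizers minimize: decode the candidate vector, run
#' the forward pass on the (normalized) training rows, return the MSE. No
#' gradient training happens inside the fitness.
#'
#' @param topology a [net_topology()].
#' @param x,y normalized training inputs and targets.
#' @return a function `f(vector) -> MSE`.
#' @export
make_weight_fitness <- function(topology, x, y) {
  x <- as.matrix(x); y <- as.numeric(y)
  force(topology)
  function(vector) {
    mean((y - net_forward(decode_weights(vector, topology), x))^2)
  }
}

eval_fitness <- function(fitness, X) {
  v <- apply(X, 1L, function(row) {
    f <- tryCatch(fitness(row), error = function(e) Inf)
    if (!is.finite(f)) Inf else f
  })
  as.numeric(v)
}

#' Particle swarm configuration
#'
#' Defaults match the published setup: population 50, 100 iterations,
#' c1 = c2 = 1.49445, position bounds \[-5, 5\], velocity bounds \[-1, 1\].
#' The inertia weight (unspecified there) follows the common linear
#' 0.9 -> 0.4 schedule; pass a single number for a constant inertia.
#'
#' @param pop population size (>= 2).
#' @param iters iterations.
#' @param c1,c2 cognitive / social acceleration factors.
#' @param inertia length-2 schedule `c(start, end)` or a constant.
#' @param bounds,v_bounds position and velocity clamping intervals.
#' @param init interval for the initial population; defaults to `bounds`.
#'   Network-weight searches seed the swarm in the trainer's own
#'   small-weight range so the global search refines rather than inflates
#'   weight magnitudes (large weights saturate the sigmoids).
#' @param seed optional integer seed.
#' @return config list.
#' @export
pso_config <- function(pop = 50, iters = 100, c1 = 1.49445, c2 = 1.49445,
                       inertia = c(0.9, 0.4), bounds = c(-5, 5),
                       v_bounds = c(-1, 1), init = NULL, seed = NULL) {
  stopifnot(pop >= 2, iters >= 1, c1 >= 0, c2 >= 0,
            bounds[1] < bounds[2], v_bounds[1] < v_bounds[2])
  list(pop = pop, iters = iters, c1 = c1, c2 = c2, inertia = inertia,
       bounds = bounds, v_bounds = v_bounds, init = init %||% bounds,
       seed = seed)
}

pso_inertia_at <- function(config, iter) {
  w <- config$inertia
  if (length(w) == 1L) return(w)
  if (config$iters <= 1L) return(w[1L])
  w[1L] - (w[1L] - w[2L]) * (iter - 1) / (config$iters - 1)
}

#' One particle swarm step
#'
#' Velocity update `V' = w V + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with
#' fresh uniform `r1`, `r2` per particle and dimension, velocity clamping,
#' position update and clamping, then fitness evaluation and personal /
#' global best bookkeeping (non-finite fitness rejects the candidate and
#' keeps the stored best).
#'
#' @param state list with `X`, `V` (pop x dim), `P`, `pfit`, `gbest`,
#'   `gfit`, `iter`.
#' @param config a [pso_config()].
#' @param fitness objective function of a parameter vector.
#' @param inertia optional inertia override for this step.
#' @param r1,r2 optional pop x dim matrices replacing the uniform draws
#'   (for deterministic checks).
#' @return updated state.
#' @export
pso_step <- function(state, config, fitness, inertia = NULL,
                     r1 = NULL, r2 = NULL) {
  pop <- nrow(state$X); dim <- ncol(state$X)
  w <- inertia %||% pso_inertia_at(config, state$iter + 1L)
  if (is.null(r1)) r1 <- matrix(runif(pop * dim), pop, dim)
  if (is.null(r2)) r2 <- matrix(runif(pop * dim), pop, dim)
  G <- matrix(state$gbest, pop, dim, byrow = TRUE)
  V <- w * state$V + config$c1 * r1 * (state$P - state$X) +
    config$c2 * r2 * (G - state$X)
  V <- clamp(V, config$v_bounds[1], config$v_bounds[2])
  X <- clamp(state$X + V, config$bounds[1], config$bounds[2])
  fit <- eval_fitness(fitness, X)
  better <- fit < state$pfit
  state$P[better, ] <- X[better, , drop = FALSE]
  state$pfit[better] <- fit[better]
  ibest <- which.min(state$pfit)
  if (state$pfit[ibest] < state$gfit) {
    state$gfit <- state$pfit[ibest]
    state$gbest <- state$P[ibest, ]
  }
  state$X <- X
  state$V <- V
  state$iter <- state$iter + 1L
  state
}

#' Particle swarm optimization
#'
#' @param fitness objective function (minimized).
#' @param dim dimensionality of the search space.
#' @param config a [pso_config()].
#' @return list with `par` (best vector), `value` (best fitness) and
#'   `trace` (global best per iteration, non-increasing).
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- pso_optimize(sphere, 5, pso_config(pop = 20, iters = 30, seed = 1))
#' res$value
#' @export
pso_optimize <- function(fitness, dim, config = pso_config()) {
  stopifnot(dim >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  init <- config$init %||% config$bounds
  X <- matrix(runif(config$pop * dim, init[1], init[2]), config$pop, dim)
  V <- matrix(runif(config$pop * dim, config$v_bounds[1], config$v_bounds[2]),
              config$pop, dim)
  fit <- eval_fitness(fitness, X)
  ibest <- which.min(fit)
  state <- list(X = X, V = V, P = X, pfit = fit,
                gbest = X[ibest, ], gfit = fit[ibest], iter = 0L)
  trace <- numeric(config$iters)
  for (j in seq_len(config$iters)) {
    state <- pso_step(state, config, fitness)
    trace[j] <- state$gfit
  }
  list(par = state$gbest, value = state$gfit, trace = trace)
}

#' Whale optimization configuration
#'
#' Encircling coefficient `a` decreases linearly from 2 to 0 over the
#' iterations; the spiral constant `b = 1` and the 0.5 probability of the
#' spiral (bubble-net) branch are the standard conventions.
#'
#' @param pop population size (>= 2).
#' @param iters iterations.
#' @param b spiral shape constant (non-zero).
#' @param p_spiral probability of the spiral move.
#' @param bounds position clamping interval.
#' @param init interval for the initial population; defaults to `bounds`.
#' @param seed optional integer seed.
#' @return config list.
#' @export
woa_config <- function(pop = 50, iters = 100, b = 1, p_spiral = 0.5,
                       bounds = c(-5, 5), init = NULL, seed = NULL) {
  stopifnot(pop >= 2, iters >= 1, b != 0, p_spiral >= 0, p_spiral <= 1,
            bounds[1] < bounds[2])
  list(pop = pop, iters = iters, b = b, p_spiral = p_spiral,
       bounds = bounds, init = init %||% bounds, seed = seed)
}

# one whale's move given its random draws; exposed for unit testing
woa_move <- function(x, leader, x_rand, a, b, p, p_spiral, r1, r2, l) {
  if (p < p_spiral) {
    D <- abs(leader - x)
    return(leader + D * exp(b * l) * cos(2 * pi * l))
  }
  A <- 2 * a * r1 - a
  C <- 2 * r2
  encircle <- abs(A) < 1
  target <- ifelse(encircle, leader, x_rand)
  D <- abs(C * target - x)
  target - A * D
}

#' Whale optimization algorithm
#'
#' Alternates encircling (`X' = X* - A D`, `D = |C X* - X|`), bubble-net
#' spiral moves (`X' = X* + D e^{bl} cos(2 pi l)`, `D = |X* - X|`,
#' `l ~ U[-1, 1]`), and exploration toward a random whale when `|A| >= 1`,
#' with `a` shrinking linearly 2 -> 0. The leader (best-so-far) is only
#' replaced by an improvement, so the trace is non-increasing.
#'
#' @inheritParams pso_optimize
#' @param config a [woa_config()].
#' @return list with `par`, `value`, `trace`.
#' @export
woa_optimize <- function(fitness, dim, config = woa_config()) {
  stopifnot(dim >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  init <- config$init %||% config$bounds
  X <- matrix(runif(config$pop * dim, init[1], init[2]), config$pop, dim)
  fit <- eval_fitness(fitness, X)
  ibest <- which.min(fit)
  leader <- X[ibest, ]
  lfit <- fit[ibest]
  trace <- numeric(config$iters)
  for (j in seq_len(config$iters)) {
    a <- 2 * (1 - j / config$iters)
    for (i in seq_len(config$pop)) {
      xi <- woa_move(X[i, ], leader, X[sample.int(config$pop, 1L), ],
                     a, config$b, runif(1), config$p_spiral,
                     runif(dim), runif(dim), runif(dim, -1, 1))
      X[i, ] <- clamp(xi, config$bounds[1], config$bounds[2])
    }
    fit <- eval_fitness(fitness, X)
    ibest <- which.min(fit)
    if (fit[ibest] < lfit) {
      lfit <- fit[ibest]
      leader <- X[ibest, ]
    }
    trace[j] <- lfit
  }
  list(par = leader, value = lfit, trace = trace)
}

#' Genetic algorithm configuration
#'
#' Real-coded GA with tournament selection (size 3), whole-arithmetic
#' crossover (rate 0.8), Gaussian mutation (rate 0.05 per gene, SD 5% of
#' the bound width) and elitism of one — conventional operator choices,
#' all configurable.
#'
#' @param pop population size (>= 2).
#' @param gens generations.
#' @param crossover,mutation operator rates in \[0, 1\].
#' @param tournament tournament size.
#' @param bounds gene clamping interval.
#' @param sigma_frac mutation SD as a fraction of the bound width.
#' @param init interval for the initial population; defaults to `bounds`.
#' @param seed optional integer seed.
#' @return config list.
#' @export
ga_config <- function(pop = 50, gens = 100, crossover = 0.8, mutation = 0.05,
                      tournament = 3, bounds = c(-5, 5), sigma_frac = 0.05,
                      init = NULL, seed = NULL) {
  stopifnot(pop >= 2, gens >= 1, crossover >= 0, crossover <= 1,
            mutation >= 0, mutation <= 1, tournament >= 1,
            bounds[1] < bounds[2], sigma_frac >= 0)
  list(pop = pop, gens = gens, crossover = crossover, mutation = mutation,
       tournament = tournament, bounds = bounds, sigma_frac = sigma_frac,
       init = init %||% bounds, seed = seed)
}

#' Genetic algorithm
#'
#' @inheritParams pso_optimize
#' @param config a [ga_config()].
#' @return list with `par`, `value`, `trace` (best-so-far per generation).
#' @export
ga_optimize <- function(fitness, dim, config = ga_config()) {
  stopifnot(dim >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  lo <- config$bounds[1]; hi <- config$bounds[2]
  sigma <- config$sigma_frac * (hi - lo)
  init <- config$init %||% config$bounds
  X <- matrix(runif(config$pop * dim, init[1], init[2]), config$pop, dim)
  fit <- eval_fitness(fitness, X)
  ibest <- which.min(fit)
  best <- X[ibest, ]; bfit <- fit[ibest]
  tournament <- function() {
    cand <- sample.int(config$pop, config$tournament, replace = TRUE)
    X[cand[which.min(fit[cand])], ]
  }
  trace <- numeric(config$gens)
  for (g in seq_len(config$gens)) {
    newX <- matrix(0, config$pop, dim)
    newX[1L, ] <- best # elitism
    for (i in 2:config$pop) {
      child <- tournament()
      if (runif(1) < config$crossover) {
        mate <- tournament()
        alpha <- runif(dim)
        child <- alpha * child + (1 - alpha) * mate
      }
      mut <- runif(dim) < config$mutation
      if (any(mut)) child[mut] <- child[mut] + rnorm(sum(mut), 0, sigma)
      newX[i, ] <- clamp(child, lo, hi)
    }
    X <- newX
    fit <- eval_fitness(fitness, X)
    ibest <- which.min(fit)
    if (fit[ibest] < bfit) {
      bfit <- fit[ibest]
      best <- X[ibest, ]
    }
    trace[g] <- bfit
  }
  list(par = best, value = bfit, trace = trace)
}
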