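## Particle swarm optimizer over flattened network-weight vectors.
## Velocity update: V <- w V + c1 r1 (pbest - X) + c2 r2 (gbest - X), with one
## uniform draw per particle per dimension, velocities clamped to +/- v_max,
## positions unclamped. Fitness: lower is better (mean squared error for the
## network use case).

#' Swarm configuration
#'
#' Defaults use the standard constriction-equivalent coefficients
#' (omega = 0.729, c1 = c2 = 1.49445) and a population of 110 particles.
#'
#' @param population Number of particles (>= 2; default 110).
#' @param omega Inertia weight.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param v_max Per-dimension velocity clamp (> 0).
#' @param x_init_range Length-2 numeric: initial position range.
#' @param max_iters Iteration budget (default 100).
#' @param seed Integer seed.
#' @param tol Early-stop tolerance: stop when the global-best improvement stays
#'   below `tol` for `patience` consecutive iterations.
#' @param patience Consecutive-stall count triggering the early stop.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(population = 110L, omega = 0.729, c1 = 1.49445,
                       c2 = 1.49445, v_max = 0.5, x_init_range = c(-0.5, 0.5),
                       max_iters = 100L, seed = 1L, tol = 1e-8,
                       patience = 20L) {
  if (population < 2) abort("`population` must be >= 2.",
                            class = "psobp_config_error")
  stopifnot(omega >= 0, c1 >= 0, c2 >= 0, v_max > 0, max_iters >= 1,
            length(x_init_range) == 2, x_init_range[2] > x_init_range[1])
  structure(list(population = as.integer(population), omega = omega,
                 c1 = c1, c2 = c2, v_max = v_max,
                 x_init_range = x_init_range,
                 max_iters = as.integer(max_iters), seed = as.integer(seed),
                 tol = tol, patience = as.integer(patience)),
            class = "pso_config")
}

#' Mean-squared-error fitness of a flattened weight vector
#'
#' Unflattens `position` into network weights, forward-propagates the training
#' inputs and returns the mean squared error over samples x output neurons
#' (equal to `2 * nn_loss(...) / (p * n_out)`).
#'
#' @param position Numeric vector in the [flatten_weights()] order.
#' @param arch A [network_architecture()].
#' @param X Training inputs (samples x m), normalized.
#' @param T Training targets (samples x n_out), normalized.
#' @return Scalar fitness (lower is better).
#' @export
mse_fitness <- function(position, arch, X, T) {
  w <- unflatten_weights(position, arch)
  mean((nn_forward(w, X) - T)^2)
}

#' Build a fitness closure over fixed training data
#'
#' @inheritParams mse_fitness
#' @return A function `position -> fitness`.
#' @export
make_mse_fitness <- function(arch, X, T) {
  X <- as_input_matrix(X, arch$m)
  T <- as_target_matrix(T, arch$n_out, nrow(X))
  function(position) mse_fitness(position, arch, X, T)
}

evaluate_swarm <- function(X, fitness) {
  apply(X, 1, fitness)
}

#' Initialize a swarm
#'
#' Positions uniform on `x_init_range`, velocities uniform on
#' `[-v_max, v_max]`; personal bests start at the initial positions and the
#' global best is the fittest initial particle. Draws come from the generator
#' active at call time; [pso_optimize()] seeds it from `config$seed`.
#'
#' @param dim Dimensionality (>= 1).
#' @param config A [pso_config()].
#' @param fitness Function `position -> scalar` (lower is better).
#' @return An object of class `swarm_state`.
#' @export
init_swarm <- function(dim, config, fitness) {
  stopifnot(dim >= 1)
  pop <- config$population
  X <- matrix(runif(pop * dim, config$x_init_range[1], config$x_init_range[2]),
              pop, dim)
  V <- matrix(runif(pop * dim, -config$v_max, config$v_max), pop, dim)
  fit <- evaluate_swarm(X, fitness)
  if (any(!is.finite(fit))) {
    abort("Non-finite fitness in initial swarm.", class = "psobp_divergence_error")
  }
  g <- which.min(fit)
  structure(list(X = X, V = V,
                 pbest_pos = X, pbest_fit = fit,
                 gbest_pos = X[g, ], gbest_fit = fit[g],
                 iteration = 0L, history = fit[g]),
            class = "swarm_state")
}

#' One swarm iteration
#'
#' Updates every velocity with fresh per-particle, per-dimension uniform draws,
#' clamps to `+/- v_max`, moves the particles, re-evaluates fitness and
#' refreshes the personal and global bests. The global best fitness never
#' increases.
#'
#' @param state A `swarm_state`.
#' @param config A [pso_config()].
#' @param fitness Function `position -> scalar`.
#' @return The updated `swarm_state`.
#' @export
pso_step <- function(state, config, fitness) {
  pop <- nrow(state$X); dim <- ncol(state$X)
  R1 <- matrix(runif(pop * dim), pop, dim)
  R2 <- matrix(runif(pop * dim), pop, dim)
  G <- matrix(state$gbest_pos, pop, dim, byrow = TRUE)
  V <- config$omega * state$V +
    config$c1 * R1 * (state$pbest_pos - state$X) +
    config$c2 * R2 * (G - state$X)
  V <- pmin(pmax(V, -config$v_max), config$v_max)
  X <- state$X + V
  fit <- evaluate_swarm(X, fitness)
  if (any(!is.finite(fit))) {
    abort(paste0("Non-finite fitness at iteration ", state$iteration + 1L, "."),
          class = "psobp_divergence_error")
  }
  improved <- fit < state$pbest_fit
  state$pbest_pos[improved, ] <- X[improved, ]
  state$pbest_fit[improved] <- fit[improved]
  g <- which.min(state$pbest_fit)
  if (state$pbest_fit[g] < state$gbest_fit) {
    state$gbest_fit <- state$pbest_fit[g]
    state$gbest_pos <- state$pbest_pos[g, ]
  }
  state$X <- X
  state$V <- V
  state$iteration <- state$iteration + 1L
  state$history <- c(state$history, state$gbest_fit)
  state
}

#' Run the swarm optimizer
#'
#' Seeds the random generator from `config$seed`, initializes the swarm and
#' iterates up to `config$max_iters` steps, stopping early once the global
#' best has improved by less than `config$tol` for `config$patience`
#' consecutive iterations. Fully reproducible for a fixed
#' (seed, config, fitness) triple.
#'
#' @inheritParams init_swarm
#' @return A list of class `pso_result`: `position` (best-ever), `fitness`,
#'   `history` (tibble `iteration`, `gbest_fit`; iteration 0 is the initial
#'   swarm), `iterations_used`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- pso_optimize(5, pso_config(max_iters = 50, seed = 1), sphere)
#' res$fitness
pso_optimize <- function(dim, config, fitness) {
  stopifnot(inherits(config, "pso_config"))
  withr::with_seed(config$seed, {
    state <- init_swarm(dim, config, fitness)
    stall <- 0L
    for (i in seq_len(config$max_iters)) {
      prev <- state$gbest_fit
      state <- pso_step(state, config, fitness)
      stall <- if (prev - state$gbest_fit < config$tol) stall + 1L else 0L
      if (stall >= config$patience) break
    }
    structure(list(position = state$gbest_pos,
                   fitness = state$gbest_fit,
                   history = tibble::tibble(
                     iteration = seq_along(state$history) - 1L,
                     gbest_fit = state$history),
                   iterations_used = state$iteration),
              class = "pso_result")
  })
}
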