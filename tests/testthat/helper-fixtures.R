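# Small fixtures shared across test files; everything is generated in code.

# a reduced factorial design for fast pipeline tests
small_config <- function(seed = 1L, noise_cv = 0.03, ...) {
  generator_config(
    temp_levels = c(18, 24, 32),
    co2_levels = c(300, 900),
    par_levels = c(20, 100, 300, 700, 1000, 1500),
    replicates = 2, noise_cv = noise_cv, seed = seed, ...)
}

# a tiny hand-checkable 1-2-1 network
hand_net_121 <- function(activation = "tansig") {
  arch <- network_architecture(m = 1, L = 2, n_out = 1,
                               hidden_activation = activation)
  w <- init_weights(arch, seed = 1, scale = 0)
  w$W1 <- matrix(c(1, -2), 2, 1)
  w$b1 <- c(0.5, 0.1)
  w$W2 <- matrix(c(1.5, -0.7), 1, 2)
  w$b2 <- 0.3
  w
}

# teacher network data: targets generated by a known (3, 5, 1) network.
# scale 0.7 keeps the teacher's hidden units mildly saturating so that
# recovery tests probe trainer correctness rather than global search.
teacher_data <- function(n = 120, seed = 1L) {
  arch <- network_architecture()
  teacher <- init_weights(arch, seed = seed + 1000L, scale = 0.7)
  X <- withr::with_seed(seed, matrix(runif(n * 3, -1, 1), n, 3))
  list(X = X, T = nn_forward(teacher, X), teacher = teacher, arch = arch)
}

# reduced swarm settings for fast tests
fast_pso <- function(seed = 1L, ...) {
  pso_config(population = 30, max_iters = 40, seed = seed, ...)
}
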