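# Network sizing, forward pass, loss, analytic gradient, trainers,
# flatten/unflatten bridge.

test_that("hidden node sizing rule matches its worked cases", {
  expect_equal(hidden_node_count(3, 1, 3), 5L)
  expect_equal(hidden_node_count(1, 1, 1), 2L)
  expect_equal(hidden_node_count(4, 1, 2), 4L)  # odd m+n takes the floor
  expect_error(hidden_node_count(3, 1, 0), class = "psobp_domain_error")
  expect_error(hidden_node_count(3, 1, 11), class = "psobp_domain_error")
})

test_that("weight initialization is seeded, scaled and shape-correct", {
  arch <- network_architecture()
  expect_identical(init_weights(arch, seed = 4), init_weights(arch, seed = 4))
  expect_false(identical(init_weights(arch, seed = 4), init_weights(arch, seed = 5)))
  w0 <- init_weights(arch, seed = 1, scale = 0)
  expect_true(all(flatten_weights(w0) == 0))
  expect_equal(length(flatten_weights(init_weights(arch, seed = 1))), 26)
  expect_equal(dim(init_weights(arch, seed = 1)$W1), c(5, 3))
})

test_that("forward pass matches hand calculation and zero-weight cases", {
  arch <- network_architecture()
  wz <- init_weights(arch, seed = 1, scale = 0)
  X <- matrix(rnorm(15), 5, 3)
  expect_true(all(nn_forward(wz, X) == 0))          # tansig: tanh(0) = 0
  wzl <- init_weights(network_architecture(hidden_activation = "logsig"),
                      seed = 1, scale = 0)
  expect_true(all(nn_forward(wzl, X) == 0))         # 0.5 hidden x zero W2

  w <- hand_net_121()
  # z = (1.0, -0.9); y = 1.5 tanh(1) - 0.7 tanh(-0.9) + 0.3
  expect_equal(as.vector(nn_forward(w, 0.5)), 1.9437997430729645,
               tolerance = 1e-12)
  wl <- hand_net_121("logsig")
  y_hand <- 1.5 / (1 + exp(-1)) - 0.7 / (1 + exp(0.9)) + 0.3
  expect_equal(as.vector(nn_forward(wl, 0.5)), y_hand, tolerance = 1e-12)

  expect_error(nn_forward(w, matrix(1, 2, 3)), class = "psobp_domain_error")
})

test_that("batch forward equals per-sample forward concatenated", {
  arch <- network_architecture()
  w <- init_weights(arch, seed = 2)
  X <- withr::with_seed(1, matrix(runif(30, -1, 1), 10, 3))
  batch <- nn_forward(w, X)
  rows <- t(sapply(seq_len(10), function(i) nn_forward(w, X[i, , drop = FALSE])))
  expect_equal(as.vector(batch), as.vector(rows), tolerance = 1e-14)
})

test_that("loss is half the sum of squared residuals", {
  arch <- network_architecture(m = 1, L = 1)
  w <- init_weights(arch, seed = 1, scale = 0)   # predicts 0 everywhere
  expect_equal(nn_loss(w, matrix(c(1, 2)), matrix(c(1, -1))), 1.0)
  expect_equal(nn_loss(w, matrix(c(1, 2)), matrix(c(0.3, 0.4))), 0.125)
  expect_equal(nn_loss(w, matrix(c(1, 2)), matrix(c(0, 0))), 0)
})

test_that("analytic gradient matches central finite differences", {
  fd_gradient <- function(w, X, T, h = 1e-6) {
    v <- flatten_weights(w)
    sapply(seq_along(v), function(k) {
      vp <- v; vp[k] <- vp[k] + h
      vm <- v; vm[k] <- vm[k] - h
      (nn_loss(unflatten_weights(vp, w$arch), X, T) -
         nn_loss(unflatten_weights(vm, w$arch), X, T)) / (2 * h)
    })
  }
  withr::with_seed(5, {
    for (i in 1:20) {
      m <- sample(1:4, 1); L <- sample(1:6, 1)
      act <- sample(c("tansig", "logsig"), 1)
      arch <- network_architecture(m = m, L = L, hidden_activation = act)
      w <- init_weights(arch, seed = i, scale = 1)
      n <- sample(3:12, 1)
      X <- matrix(runif(n * m, -1, 1), n, m)
      T <- matrix(runif(n, -1, 1), n, 1)
      ga <- flatten_weights(nn_gradient(w, X, T))
      gf <- fd_gradient(w, X, T)
      expect_lt(max(abs(ga - gf)) / max(1, max(abs(ga))), 1e-6)
    }
  })
})

test_that("gradient vanishes at a perfect fit and is additive over data", {
  td <- teacher_data(n = 20, seed = 3)
  g0 <- flatten_weights(nn_gradient(td$teacher, td$X, td$T))
  expect_lt(max(abs(g0)), 1e-10)

  arch <- network_architecture()
  w <- init_weights(arch, seed = 9)
  X <- td$X; T <- td$T
  g1 <- flatten_weights(nn_gradient(w, X, T))
  g2 <- flatten_weights(nn_gradient(w, rbind(X, X), rbind(T, T)))
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
})

test_that("flatten/unflatten round-trips in the documented order", {
  arch <- network_architecture()
  w <- init_weights(arch, seed = 7)
  v <- flatten_weights(w)
  expect_equal(length(v), 26)
  expect_equal(v[1:3], w$W1[1, ])                 # W1 row-major first
  w2 <- unflatten_weights(v, arch)
  expect_equal(w2$W1, w$W1)
  expect_equal(w2$b1, w$b1)
  expect_equal(w2$W2, w$W2)
  expect_equal(w2$b2, w$b2)
  expect_error(unflatten_weights(v[-1], arch), class = "psobp_domain_error")
})

test_that("gradient descent respects the step factor and stopping rule", {
  td <- teacher_data(n = 50, seed = 1)
  w0 <- init_weights(td$arch, seed = 2)
  # zero step: weights unchanged, flat trace
  frozen <- nn_train(w0, td$X, td$T,
                     train_config(eta = 0, max_epochs = 5, goal = 1e-12,
                                  optimizer = "gd"))
  expect_equal(flatten_weights(frozen$weights), flatten_weights(w0))
  expect_equal(length(unique(frozen$trace$mse)), 1)
  # a huge goal is met immediately
  quick <- nn_train(w0, td$X, td$T,
                    train_config(goal = 1e6, optimizer = "gd"))
  expect_true(quick$converged)
  expect_equal(quick$epochs_used, 1)
  # a small gd step decreases the error from a random start
  gd <- nn_train(w0, td$X, td$T,
                 train_config(eta = 1e-3, max_epochs = 2, goal = 1e-12,
                              optimizer = "gd"))
  mse0 <- mean((nn_forward(w0, td$X) - td$T)^2)
  expect_lt(gd$trace$mse[1], mse0)
})

test_that("LM training recovers a teacher network and never increases its trace", {
  recovered <- 0
  td <- teacher_data(n = 150, seed = 1)
  for (s in 51:55) {   # five random starts at the same teacher
    w0 <- init_weights(td$arch, seed = s, scale = 0.5)
    fit <- nn_train(w0, td$X, td$T,
                    train_config(max_epochs = 400, goal = 1e-7))
    expect_true(all(diff(fit$trace$mse) <= 1e-12))
    if (min(fit$trace$mse) < 1e-6) recovered <- recovered + 1
  }
  expect_gte(recovered, 4)
})
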