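## From-scratch single-hidden-layer feedforward network: tansig/logsig hidden
## activation, linear output, half-sum-of-squares error, analytic
## back-propagated gradient, full-batch gradient-descent and damped
## least-squares (Levenberg-Marquardt) trainers.

#' Hidden layer size rule
#'
#' The conventional `L = (m + n) / 2 + c` sizing rule, with the integer part
#' taken when `m + n` is odd and the offset constant `c` restricted to 1..10.
#'
#' @param m Number of input nodes.
#' @param n_out Number of output nodes.
#' @param c Offset constant, integer in \[1, 10\].
#' @return Integer hidden node count.
#' @export
#' @examples
#' hidden_node_count(3, 1, 3)  # 5, the default architecture used here
hidden_node_count <- function(m, n_out, c = 3L) {
  stopifnot(m >= 1, n_out >= 1)
  if (c != round(c) || c < 1 || c > 10) {
    abort("`c` must be an integer in [1, 10].", class = "psobp_domain_error")
  }
  as.integer(floor((m + n_out) / 2) + c)
}

#' Network architecture descriptor
#'
#' @param m Input node count (default 3: Tem, CO2, Par).
#' @param L Hidden node count; defaults to [hidden_node_count()] with `c = 3`.
#' @param n_out Output node count (default 1).
#' @param hidden_activation `"tansig"` (hyperbolic tangent, the default,
#'   consistent with \[-1, 1\]-normalized data) or `"logsig"` (logistic
#'   `1 / (1 + exp(-x))`).
#' @return An object of class `network_architecture`.
#' @export
network_architecture <- function(m = 3L, L = hidden_node_count(m, n_out, 3L),
                                 n_out = 1L,
                                 hidden_activation = c("tansig", "logsig")) {
  hidden_activation <- match.arg(hidden_activation)
  stopifnot(m >= 1, n_out >= 1, L >= 1)
  structure(list(m = as.integer(m), L = as.integer(L),
                 n_out = as.integer(n_out),
                 hidden_activation = hidden_activation),
            class = "network_architecture")
}

n_params <- function(arch) {
  arch$L * arch$m + arch$L + arch$n_out * arch$L + arch$n_out
}

#' Seeded random initial weights
#'
#' Entries drawn uniformly on \[-scale, scale\] from a seeded generator.
#'
#' @param arch A [network_architecture()].
#' @param seed Integer seed.
#' @param scale Half-width of the uniform initialization interval.
#' @return An object of class `network_weights`: list of `W1` (L x m), `b1`
#'   (L), `W2` (n_out x L), `b2` (n_out) and the architecture.
#' @export
init_weights <- function(arch, seed = 1L, scale = 0.5) {
  stopifnot(inherits(arch, "network_architecture"), scale >= 0)
  withr::with_seed(seed, {
    structure(list(
      W1 = matrix(runif(arch$L * arch$m, -scale, scale), arch$L, arch$m),
      b1 = runif(arch$L, -scale, scale),
      W2 = matrix(runif(arch$n_out * arch$L, -scale, scale), arch$n_out, arch$L),
      b2 = runif(arch$n_out, -scale, scale),
      arch = arch
    ), class = "network_weights")
  })
}

hidden_act <- function(z, kind) {
  switch(kind, tansig = tanh(z), logsig = 1 / (1 + exp(-z)))
}

hidden_act_deriv <- function(h, kind) {
  switch(kind, tansig = 1 - h^2, logsig = h * (1 - h))
}

as_input_matrix <- function(X, m) {
  if (is.vector(X)) X <- matrix(X, ncol = m)
  X <- as.matrix(X)
  if (ncol(X) != m) {
    abort(paste0("Input has ", ncol(X), " columns; architecture expects ", m, "."),
          class = "psobp_domain_error")
  }
  X
}

#' Forward pass
#'
#' `hidden = act(W1 x + b1)`, `output = W2 hidden + b2` (linear, unbounded).
#'
#' @param weights A `network_weights` object.
#' @param X Input matrix (samples x m) or a length-m vector.
#' @return Matrix of predictions (samples x n_out).
#' @export
nn_forward <- function(weights, X) {
  arch <- weights$arch
  X <- as_input_matrix(X, arch$m)
  Z1 <- X %*% t(weights$W1) + matrix(weights$b1, nrow(X), arch$L, byrow = TRUE)
  H <- hidden_act(Z1, arch$hidden_activation)
  H %*% t(weights$W2) + matrix(weights$b2, nrow(X), arch$n_out, byrow = TRUE)
}

as_target_matrix <- function(T, n_out, n_samples) {
  if (is.vector(T)) T <- matrix(T, ncol = n_out)
  T <- as.matrix(T)
  if (nrow(T) != n_samples || ncol(T) != n_out) {
    abort("Targets are not aligned with inputs.", class = "psobp_domain_error")
  }
  T
}

#' Half-sum-of-squares training error
#'
#' `E = 1/2 sum_j (yhat_j - y_j)^2` over all samples and outputs.
#'
#' @param weights A `network_weights` object.
#' @param X Inputs (samples x m).
#' @param T Targets (samples x n_out).
#' @return Scalar error.
#' @export
nn_loss <- function(weights, X, T) {
  X <- as_input_matrix(X, weights$arch$m)
  T <- as_target_matrix(T, weights$arch$n_out, nrow(X))
  sum((nn_forward(weights, X) - T)^2) / 2
}

#' Analytic back-propagated gradient
#'
#' Exact gradient of [nn_loss()] with respect to every weight and bias.
#'
#' @inheritParams nn_loss
#' @return A `network_weights`-shaped list of gradients.
#' @export
nn_gradient <- function(weights, X, T) {
  arch <- weights$arch
  X <- as_input_matrix(X, arch$m)
  T <- as_target_matrix(T, arch$n_out, nrow(X))
  Z1 <- X %*% t(weights$W1) + matrix(weights$b1, nrow(X), arch$L, byrow = TRUE)
  H <- hidden_act(Z1, arch$hidden_activation)
  Y <- H %*% t(weights$W2) + matrix(weights$b2, nrow(X), arch$n_out, byrow = TRUE)
  dY <- Y - T                                   # p x n_out
  dH <- dY %*% weights$W2                       # p x L
  dZ1 <- dH * hidden_act_deriv(H, arch$hidden_activation)
  structure(list(
    W1 = t(dZ1) %*% X,
    b1 = colSums(dZ1),
    W2 = t(dY) %*% H,
    b2 = colSums(dY),
    arch = arch
  ), class = "network_weights")
}

#' Flatten weights to a parameter vector and back
#'
#' Fixed order: `W1` row-major, `b1`, `W2` row-major, `b2` — the order used for
#' particle positions in the swarm optimizer.
#'
#' @param weights A `network_weights` object.
#' @return `flatten_weights()`: numeric vector; `unflatten_weights()`: a
#'   `network_weights` object.
#' @export
flatten_weights <- function(weights) {
  c(as.vector(t(weights$W1)), weights$b1,
    as.vector(t(weights$W2)), weights$b2)
}

#' @rdname flatten_weights
#' @param v Numeric vector of length `L*m + L + n_out*L + n_out`.
#' @param arch A [network_architecture()].
#' @export
unflatten_weights <- function(v, arch) {
  expected <- n_params(arch)
  if (length(v) != expected) {
    abort(paste0("Parameter vector has length ", length(v),
                 "; architecture needs ", expected, "."),
          class = "psobp_domain_error")
  }
  i <- 0
  take <- function(k) { out <- v[(i + 1):(i + k)]; i <<- i + k; out }
  structure(list(
    W1 = matrix(take(arch$L * arch$m), arch$L, arch$m, byrow = TRUE),
    b1 = take(arch$L),
    W2 = matrix(take(arch$n_out * arch$L), arch$n_out, arch$L, byrow = TRUE),
    b2 = take(arch$n_out),
    arch = arch
  ), class = "network_weights")
}

#' Training configuration
#'
#' @param eta Gradient-descent step factor (default 0.05).
#' @param max_epochs Maximum training epochs (default 500).
#' @param goal Target mean squared error on normalized training data
#'   (default 1e-3); training stops once reached.
#' @param optimizer `"lm"` (damped least squares, the default) or `"gd"`
#'   (full-batch steepest descent `w <- w - eta * grad`).
#' @param lm_lambda0 Initial damping factor for `"lm"` (default 1e-3).
#' @param lm_lambda_max Damping cap; an `"lm"` epoch that cannot improve even
#'   at this damping terminates training (stalled).
#' @param seed Integer seed (reserved; both trainers are deterministic).
#' @return An object of class `train_config`.
#' @export
train_config <- function(eta = 0.05, max_epochs = 500L, goal = 1e-3,
                         optimizer = c("lm", "gd"), lm_lambda0 = 1e-3,
                         lm_lambda_max = 1e12, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(eta >= 0, goal > 0, max_epochs >= 1)
  structure(list(eta = eta, max_epochs = as.integer(max_epochs), goal = goal,
                 optimizer = optimizer, lm_lambda0 = lm_lambda0,
                 lm_lambda_max = lm_lambda_max, seed = as.integer(seed)),
            class = "train_config")
}

## Jacobian of the residual vector w.r.t. the flattened parameters
## (single-hidden-layer closed form; rows = samples x outputs, flatten order).
nn_jacobian <- function(weights, X) {
  arch <- weights$arch
  p <- nrow(X)
  Z1 <- X %*% t(weights$W1) + matrix(weights$b1, p, arch$L, byrow = TRUE)
  H <- hidden_act(Z1, arch$hidden_activation)
  dHdZ <- hidden_act_deriv(H, arch$hidden_activation)
  npar <- n_params(arch)
  J <- matrix(0, p * arch$n_out, npar)
  for (o in seq_len(arch$n_out)) {
    rows <- seq.int(o, by = arch$n_out, length.out = p)  # sample-major blocks
    # W1 (row-major): d y_o / d W1[l, j] = W2[o, l] * act'(z_l) * x_j
    col <- 0
    for (l in seq_len(arch$L)) {
      J[rows, col + seq_len(arch$m)] <- weights$W2[o, l] * dHdZ[, l] * X
      col <- col + arch$m
    }
    # b1: d y_o / d b1[l] = W2[o, l] * act'(z_l)
    J[rows, col + seq_len(arch$L)] <-
      dHdZ * matrix(weights$W2[o, ], p, arch$L, byrow = TRUE)
    col <- col + arch$L
    # W2 (row-major): d y_o / d W2[o', l] = h_l if o' == o else 0
    J[rows, col + (o - 1) * arch$L + seq_len(arch$L)] <- H
    col <- col + arch$n_out * arch$L
    # b2
    J[rows, col + o] <- 1
  }
  J
}

mse_of <- function(weights, X, T) {
  mean((nn_forward(weights, X) - T)^2)
}

#' Train a network by gradient descent or damped least squares
#'
#' `"gd"` performs full-batch steepest-descent updates `w <- w - eta * grad E`.
#' `"lm"` performs Levenberg-Marquardt damped least-squares steps: solve
#' `(J'J + lambda I) delta = -J' r`, multiply `lambda` by 10 on a rejected step
#' and divide by 10 on an accepted one. Both stop when the training MSE
#' reaches `config$goal` or `config$max_epochs` is exhausted; `"lm"` also stops
#' when no improvement is possible at the damping cap. The `"lm"` MSE trace is
#' non-increasing by construction.
#'
#' @param weights0 Initial `network_weights`.
#' @param X Inputs (samples x m), normalized.
#' @param T Targets (samples x n_out), normalized.
#' @param config A [train_config()].
#' @return A list of class `train_result`: `weights`, `trace` (tibble `epoch`,
#'   `mse`), `converged` (goal reached), `epochs_used`.
#' @export
nn_train <- function(weights0, X, T, config = train_config()) {
  arch <- weights0$arch
  X <- as_input_matrix(X, arch$m)
  T <- as_target_matrix(T, arch$n_out, nrow(X))
  w <- weights0
  trace <- numeric(0)
  converged <- FALSE
  lambda <- config$lm_lambda0
  p <- nrow(X); n_out <- arch$n_out

  for (epoch in seq_len(config$max_epochs)) {
    if (config$optimizer == "gd") {
      g <- nn_gradient(w, X, T)
      w$W1 <- w$W1 - config$eta * g$W1
      w$b1 <- w$b1 - config$eta * g$b1
      w$W2 <- w$W2 - config$eta * g$W2
      w$b2 <- w$b2 - config$eta * g$b2
      mse <- mse_of(w, X, T)
    } else {
      v <- flatten_weights(w)
      r <- as.vector(t(nn_forward(w, X) - T))   # sample-major residuals
      sse <- sum(r^2)
      J <- nn_jacobian(w, X)
      JtJ <- crossprod(J)
      Jtr <- crossprod(J, r)
      accepted <- FALSE
      while (!accepted && lambda <= config$lm_lambda_max) {
        delta <- tryCatch(
          solve(JtJ + lambda * diag(ncol(J)), -Jtr),
          error = function(e) NULL)
        if (!is.null(delta)) {
          w_new <- unflatten_weights(v + as.vector(delta), arch)
          sse_new <- sum((nn_forward(w_new, X) - T)^2)
          if (is.finite(sse_new) && sse_new < sse) {
            w <- w_new
            lambda <- max(lambda / 10, 1e-12)
            accepted <- TRUE
            break
          }
        }
        lambda <- lambda * 10
      }
      mse <- mse_of(w, X, T)
      if (!accepted) {
        # stalled: no damped step improves; record and terminate
        trace <- c(trace, mse)
        if (mse <= config$goal) converged <- TRUE
        break
      }
    }
    if (!is.finite(mse)) {
      abort(paste0("Training diverged (non-finite loss) at epoch ", epoch, "."),
            class = "psobp_divergence_error")
    }
    trace <- c(trace, mse)
    if (mse <= config$goal) { converged <- TRUE; break }
  }

  structure(list(weights = w,
                 trace = tibble::tibble(epoch = seq_along(trace), mse = trace),
                 converged = converged,
                 epochs_used = length(trace)),
            class = "train_result")
}
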