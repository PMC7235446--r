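# The DECOLLE plasticity rule: fixed random local readouts, per-layer losses,
# boxcar surrogate derivative, (optionally sign-concordant) error feedback,
# closed-form three-factor weight updates, firing-rate regularizers, and the
# AdaMax optimizer.
#
# For a layer with spikes S, membrane U and presynaptic traces P, the readout
# is Y = S %*% t(G) with G fixed and random. The per-layer loss L(Y, Yhat)
# drives the update
#
#   dW[i, j] = -eta * error[i] * boxcar(U[i]) * P[j]
#   error[i] = sum_k H[i, k] * dL/dY[k]
#
# i.e. a three-factor rule with a modulatory error factor, a postsynaptic
# gate on the membrane potential, and a presynaptic trace factor. H = t(G)
# gives the exact surrogate gradient of the local loss; the sign-concordant
# alternative multiplies t(G) elementwise by rectified Gaussian noise, so
# feedback weights share the sign of the readout weights without being
# numerically symmetric.

#' Boxcar surrogate derivative of the spike function
#'
#' The derivative of the hard-threshold spike nonlinearity is replaced by an
#' indicator on a window around the threshold: 1 where `-0.5 <= U <= 0.5`
#' (boundaries inclusive), 0 elsewhere. Plasticity is thereby gated on the
#' postsynaptic membrane potential sitting near threshold.
#'
#' @param U membrane potential (any shape).
#' @return 0/1 gate, same shape as `U`.
#' @export
surrogate_derivative <- function(U) {
  G <- U
  G[] <- as.numeric(U >= -0.5 & U <= 0.5)
  G
}

#' Build a fixed random readout matrix
#'
#' Entries are drawn uniformly on `[-1/sqrt(n_units), +1/sqrt(n_units)]` and
#' are never modified afterwards.
#'
#' @param n_units number of layer units projected from.
#' @param n_targets number of readout (target) units.
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return matrix `G` of shape (n_targets x n_units).
#' @export
build_readout <- function(n_units, n_targets, seed) {
  n_units <- check_count(n_units, "n_units")
  n_targets <- check_count(n_targets, "n_targets")
  lim <- 1 / sqrt(n_units)
  with_seed(seed, matrix(stats::runif(n_targets * n_units, -lim, lim), n_targets, n_units))
}

#' Build the fixed error-feedback matrix for a readout
#'
#' With `concordant = FALSE` the feedback is the exact transpose `t(G)`,
#' giving the true surrogate gradient of the local loss. With
#' `concordant = TRUE` each entry of `t(G)` is multiplied by an independent
#' rectified Gaussian factor `max(omega, 0)`, `omega ~ N(omega_mean,
#' omega_var)`: feedback weights share the sign of the corresponding readout
#' weight (or are zero) but are not numerically symmetric, emulating
#' bidirectionally sign-programmed connections with fabrication mismatch.
#'
#' @param G readout matrix from [build_readout()].
#' @param seed RNG seed for the noise draw.
#' @param concordant use sign-concordant noisy feedback instead of `t(G)`.
#' @param omega_mean,omega_var mean and variance of the Gaussian noise
#'   (defaults 1 and 0.5).
#' @return matrix `H` of shape (n_units x n_targets), fixed thereafter.
#' @export
build_feedback <- function(G, seed, concordant = TRUE, omega_mean = 1, omega_var = 0.5) {
  if (!is.matrix(G)) abort("`G` must be a matrix")
  H <- t(G)
  if (!concordant) return(H)
  check_scalar_number(omega_var, "omega_var", nonneg = TRUE)
  omega <- with_seed(seed, matrix(
    stats::rnorm(length(H), mean = omega_mean, sd = sqrt(omega_var)),
    nrow(H), ncol(H)
  ))
  H * pmax(omega, 0)
}

#' Instantaneous local readout
#'
#' `Y = G %*% S` per batch element; the readout has no temporal state.
#'
#' @param S layer spikes (batch x n_units, or vector).
#' @param G readout matrix (n_targets x n_units).
#' @return readout values (batch x n_targets).
#' @export
local_readout <- function(S, G) {
  S <- as_batch(S)
  if (ncol(S) != ncol(G)) abort("`S` length must equal ncol(G)")
  S %*% t(G)
}

#' Per-layer loss and its derivative w.r.t. the readout
#'
#' `mse` is `0.5 * sum((Y - Yhat)^2)` with derivative `Y - Yhat`;
#' `smooth_l1` (transition point delta = 1) is quadratic inside
#' `|Y - Yhat| <= 1` and linear outside, with derivative clipped to
#' `[-1, 1]`. Both are summed over readout units and averaged over the
#' batch.
#'
#' @param Y readout values (batch x n_targets).
#' @param Y_hat pseudo-targets, same shape (vectors are broadcast to one
#'   batch row).
#' @param kind `"mse"` or `"smooth_l1"`.
#' @return list with scalar `loss` and matrix `dY` (dL/dY, batch x
#'   n_targets).
#' @export
loss_and_error <- function(Y, Y_hat, kind = c("mse", "smooth_l1")) {
  kind <- match.arg(kind)
  Y <- as_batch(Y)
  Y_hat <- as_batch(Y_hat)
  if (nrow(Y_hat) == 1L && nrow(Y) > 1L) {
    Y_hat <- Y_hat[rep(1L, nrow(Y)), , drop = FALSE]
  }
  check_same_shape(Y, Y_hat, "Y", "Y_hat")
  d <- Y - Y_hat
  B <- nrow(Y)
  if (kind == "mse") {
    loss <- 0.5 * sum(d^2) / B
    dY <- d
  } else {
    a <- abs(d)
    loss <- sum(ifelse(a <= 1, 0.5 * d^2, a - 0.5)) / B
    dY <- pmin(pmax(d, -1), 1)
  }
  list(loss = loss, dY = dY)
}

#' Backproject the readout error onto the layer neurons
#'
#' `error[i] = sum_k H[i, k] * dY[k]`, the modulatory third factor of the
#' plasticity rule.
#'
#' @param dY loss derivative w.r.t. the readout (batch x n_targets).
#' @param H feedback matrix (n_units x n_targets) from [build_feedback()].
#' @return per-neuron error (batch x n_units).
#' @export
backproject_error <- function(dY, H) {
  dY <- as_batch(dY)
  if (ncol(dY) != ncol(H)) abort("`dY` length must equal ncol(H)")
  dY %*% t(H)
}

#' Closed-form three-factor gradient for a dense layer
#'
#' `gW[i, j] = error[i] * boxcar(U[i]) * P[j]` and
#' `gb[i] = error[i] * boxcar(U[i])` (the membrane is linear in the bias).
#' With a batch dimension, gradients are averaged over the batch so the
#' learning rate keeps its meaning across batch sizes. The refractory
#' dependence of U on past weights is deliberately dropped; the regularizers
#' keep firing rates in the regime where it is negligible.
#'
#' @param error backprojected error (batch x n_neurons).
#' @param U membrane potential (batch x n_neurons).
#' @param P presynaptic traces (batch x n_inputs).
#' @return list with `gW` (n_neurons x n_inputs) and `gb` (length
#'   n_neurons).
#' @export
decolle_gradient <- function(error, U, P) {
  error <- as_batch(error)
  U <- as_batch(U)
  P <- as_batch(P)
  check_same_shape(error, U, "error", "U")
  if (nrow(error) != nrow(P)) abort("batch sizes of `error` and `P` differ")
  d <- error * surrogate_derivative(U)
  B <- nrow(d)
  list(gW = crossprod(d, P) / B, gb = colSums(d) / B)
}

#' Membrane-potential regularizers and their gradient
#'
#' Two terms keep firing in a useful regime: `lambda1 * mean_i(relu(U_i +
#' 0.01))` pushes membranes below threshold on average (low firing rates),
#' and `lambda2 * relu(0.1 - mean_i(U_i))` enforces a minimum level of
#' activity so layers do not fall silent. Averages are over the neurons of
#' the layer (per batch element; the loss and gradient are then averaged
#' over the batch). The gradient is taken w.r.t. U directly and is *not*
#' gated by the boxcar: U is a linear function of the weights, so this term
#' reaches the weights through the traces P with no surrogate involved.
#'
#' @param U membrane potentials of the layer (batch x n_neurons).
#' @param lambda1 weight of the upper (low-activity) penalty, >= 0.
#' @param lambda2 weight of the lower (minimum-activity) penalty, >= 0.
#' @return list with scalar `loss` and `dU` (batch x n_neurons).
#' @export
regularizer <- function(U, lambda1, lambda2) {
  check_scalar_number(lambda1, "lambda1", nonneg = TRUE)
  check_scalar_number(lambda2, "lambda2", nonneg = TRUE)
  U <- as_batch(U)
  n <- ncol(U)
  B <- nrow(U)
  up <- rowSums(pmax(U + 0.01, 0)) / n
  mu <- rowMeans(U)
  lo <- pmax(0.1 - mu, 0)
  loss <- (lambda1 * sum(up) + lambda2 * sum(lo)) / B
  dU <- lambda1 * (U > -0.01) / n - lambda2 * matrix(mu < 0.1, B, n) / n
  list(loss = loss, dU = dU)
}

#' Initialise AdaMax optimizer state for a set of parameter tensors
#'
#' @param params named list of numeric arrays (the trainable parameters).
#' @param eta learning rate.
#' @param beta1 first-moment decay (default 0: the update follows the raw
#'   gradient direction, normalised by its running infinity norm).
#' @param beta2 infinity-norm decay (default 0.95).
#' @param eps guard added to the denominator.
#' @return an object of class `decolle_adamax` holding first-moment (`m`)
#'   and infinity-norm (`u`) accumulators per parameter, a step counter and
#'   the hyperparameters.
#' @export
adamax_init <- function(params, eta = 1e-6, beta1 = 0, beta2 = 0.95, eps = 1e-8) {
  check_scalar_number(eta, "eta", nonneg = TRUE)
  zeros <- lapply(params, function(p) {
    z <- p
    z[] <- 0
    z
  })
  structure(list(
    m = zeros, u = zeros, t = 0L,
    eta = eta, beta1 = beta1, beta2 = beta2, eps = eps
  ), class = "decolle_adamax")
}

#' One AdaMax step
#'
#' Standard AdaMax recurrences: `m <- beta1 * m + (1 - beta1) * g`;
#' `u <- max(beta2 * u, |g|)` elementwise; `param <- param - (eta /
#' (1 - beta1^t)) * m / (u + eps)`.
#'
#' @param params named list of parameter tensors.
#' @param grads named list of gradients, same shapes.
#' @param state optimizer state from [adamax_init()].
#' @param eta optional learning-rate override for this step (used by
#'   learning-rate schedules); defaults to the rate stored in `state`.
#' @return list with updated `params` and `state`.
#' @export
adamax_step <- function(params, grads, state, eta = NULL) {
  if (!inherits(state, "decolle_adamax")) abort("`state` must come from adamax_init()")
  if (!identical(names(params), names(state$m))) {
    abort("`params` must have the same names as the optimizer state")
  }
  if (is.null(eta)) eta <- state$eta
  state$t <- state$t + 1L
  corr <- if (state$beta1 > 0) 1 - state$beta1^state$t else 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$u[[nm]] <- pmax(state$beta2 * state$u[[nm]], abs(g))
    params[[nm]] <- params[[nm]] -
      (eta / corr) * state$m[[nm]] / (state$u[[nm]] + state$eps)
  }
  list(params = params, state = state)
}
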