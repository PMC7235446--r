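# Shared fixtures: small random problem instances built in code.

# A neuron config with alpha = beta = gamma = 0.5 (tau = dt / log 2), handy
# for hand-iterated trace arithmetic.
half_decay_config <- function() {
  neuron_config(tau_mem = 1 / log(2), tau_syn = 1 / log(2), tau_ref = 1 / log(2), dt = 1)
}

# Random dense instance for gradient checks.
random_dense_instance <- function(n_in, n_out, n_targets, seed) {
  withr::with_seed(seed, {
    list(
      W = matrix(stats::rnorm(n_out * n_in, sd = 0.3), n_out, n_in),
      b = stats::rnorm(n_out, sd = 0.2),
      P = stats::runif(n_in),
      R = stats::runif(n_out, 0, 0.3),
      G = build_readout(n_out, n_targets, seed + 1L),
      Y_hat = stats::rnorm(n_targets)
    )
  })
}

# Relaxed single-timestep loss: the spike threshold replaced by the
# piecewise-linear hard sigmoid clip(U + 0.5, 0, 1), whose derivative is the
# boxcar. Used as the numeric-differentiation oracle for the closed-form
# rule (mse loss + membrane regularizers, feedback = t(G)).
relaxed_loss <- function(W, b, P, R, rho, G, Y_hat, lambda1, lambda2) {
  U <- as.vector(W %*% P) - rho * R + b
  s <- pmin(pmax(U + 0.5, 0), 1)
  Y <- as.vector(G %*% s)
  0.5 * sum((Y - Y_hat)^2) +
    lambda1 * mean(pmax(U + 0.01, 0)) + lambda2 * max(0.1 - mean(U), 0)
}

# Nudge biases so every membrane potential sits at least `margin` away from
# the boxcar kinks (+-0.5), the upper-regularizer kink (-0.01) and the
# mean-activity kink, so central differences are valid.
nudge_off_kinks <- function(inst, rho = 1, margin = 5e-3) {
  for (pass in 1:3) {
    U <- as.vector(inst$W %*% inst$P) - rho * inst$R + inst$b
    for (k in c(-0.5, 0.5, -0.01)) {
      close <- abs(U - k) < margin
      inst$b[close] <- inst$b[close] + 2 * margin
    }
    U <- as.vector(inst$W %*% inst$P) - rho * inst$R + inst$b
    if (abs(mean(U) - 0.1) < margin) inst$b <- inst$b + 2 * margin
  }
  inst
}

# Closed-form gradient of the relaxed loss, assembled from the package's
# own pieces (backprojection through t(G), boxcar gate, trace factor,
# ungated regularizer term).
closed_form_grad <- function(inst, rho = 1, lambda1 = 0.05, lambda2 = 0.05) {
  U <- as.vector(inst$W %*% inst$P) - rho * inst$R + inst$b
  s <- pmin(pmax(U + 0.5, 0), 1)
  Y <- as.vector(inst$G %*% s)
  err <- backproject_error(Y - inst$Y_hat, t(inst$G))
  gr <- decolle_gradient(err, U, inst$P)
  reg <- regularizer(U, lambda1, lambda2)
  list(
    gW = gr$gW + crossprod(reg$dU, matrix(inst$P, 1)),
    gb = gr$gb + as.vector(reg$dU),
    U = U
  )
}

# Central finite differences of the relaxed loss w.r.t. W and b.
fd_grad <- function(inst, rho = 1, lambda1 = 0.05, lambda2 = 0.05, eps = 1e-6) {
  f <- function(W, b) relaxed_loss(W, b, inst$P, inst$R, rho, inst$G, inst$Y_hat,
                                   lambda1, lambda2)
  gW <- inst$W
  for (i in seq_len(nrow(gW))) {
    for (j in seq_len(ncol(gW))) {
      Wp <- inst$W; Wp[i, j] <- Wp[i, j] + eps
      Wm <- inst$W; Wm[i, j] <- Wm[i, j] - eps
      gW[i, j] <- (f(Wp, inst$b) - f(Wm, inst$b)) / (2 * eps)
    }
  }
  gb <- inst$b
  for (i in seq_along(gb)) {
    bp <- inst$b; bp[i] <- bp[i] + eps
    bm <- inst$b; bm[i] <- bm[i] - eps
    gb[i] <- (f(inst$W, bp) - f(inst$W, bm)) / (2 * eps)
  }
  list(gW = gW, gb = gb)
}

max_rel_err <- function(a, b, floor = 1e-4) {
  max(abs(a - b) / pmax(abs(b), floor))
}
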