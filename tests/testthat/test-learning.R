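# The three-factor learning rule, readouts, regularizers and AdaMax.

test_that("boxcar surrogate derivative is 1 exactly on [-0.5, 0.5]", {
  expect_equal(surrogate_derivative(0), 1)
  expect_equal(surrogate_derivative(0.6), 0)
  expect_equal(surrogate_derivative(c(-0.5, 0.5)), c(1, 1)) # inclusive boundaries
  expect_equal(surrogate_derivative(c(-0.50001, 0.50001)), c(0, 0))
  U <- matrix(c(-1, 0.2, 0.7, 0), 2, 2)
  expect_identical(dim(surrogate_derivative(U)), dim(U))
})

test_that("readout matrices are fixed, seeded and uniformly bounded", {
  G1 <- build_readout(100, 11, 42)
  G2 <- build_readout(100, 11, 42)
  expect_identical(G1, G2)
  expect_identical(dim(G1), c(11L, 100L))
  expect_true(all(abs(G1) <= 1 / sqrt(100)))
  expect_error(build_readout(0, 3, 1), "n_units")
  # empirical mean of the uniform entries is ~0
  G <- build_readout(1000, 100, 7)
  lim <- 1 / sqrt(1000)
  sd_mean <- (2 * lim / sqrt(12)) / sqrt(length(G))
  expect_lt(abs(mean(G)), 3 * sd_mean)
})

test_that("feedback is t(G) exactly, or sign-concordant rectified-Gaussian noise on it", {
  G <- build_readout(50, 4, 3)
  expect_identical(build_feedback(G, 9, concordant = FALSE), t(G))
  H <- build_feedback(G, 9, concordant = TRUE)
  expect_identical(H, build_feedback(G, 9, concordant = TRUE))
  # sign of every entry is the sign of t(G) or zero
  expect_true(all(H * t(G) >= 0))
  # the multiplicative factor has the rectified-Gaussian mean
  # E[max(omega, 0)], omega ~ N(1, 0.5): mu*pnorm(mu/s) + s*dnorm(mu/s)
  Gbig <- build_readout(400, 250, 5)
  Hbig <- build_feedback(Gbig, 6, concordant = TRUE)
  ratio <- Hbig / t(Gbig)
  mu <- 1; s <- sqrt(0.5)
  expected_mean <- mu * stats::pnorm(mu / s) + s * stats::dnorm(mu / s)
  v <- (mu^2 + s^2) * stats::pnorm(mu / s) + mu * s * stats::dnorm(mu / s) - expected_mean^2
  expect_lt(abs(mean(ratio) - expected_mean), 4 * sqrt(v / length(ratio)))
})

test_that("local readout is the instantaneous projection G S", {
  G <- diag(2)
  expect_equal(as.vector(local_readout(c(1, 0), G)), c(1, 0))
  expect_equal(as.vector(local_readout(c(0, 0), G)), c(0, 0))
  G <- build_readout(6, 3, 2)
  S <- rep(0, 6); S[4] <- 1
  expect_equal(as.vector(local_readout(S, G)), G[, 4])
  expect_error(local_readout(rep(1, 5), G), "ncol")
})

test_that("losses and their readout derivatives are correct", {
  le <- loss_and_error(c(1, 2), c(1, 2), "mse")
  expect_equal(le$loss, 0)
  expect_equal(as.vector(le$dY), c(0, 0))
  le <- loss_and_error(c(0.3, 0), c(1, 0), "mse")
  expect_equal(le$loss, 0.245)
  expect_equal(as.vector(le$dY), c(-0.7, 0))
  # smooth L1 saturates the derivative outside the unit transition band
  le <- loss_and_error(3, 0, "smooth_l1")
  expect_equal(as.vector(le$dY), 1)
  expect_equal(le$loss, 2.5)
  le <- loss_and_error(0.4, 0, "smooth_l1") # quadratic inside
  expect_equal(le$loss, 0.08)
  expect_equal(as.vector(le$dY), 0.4)
  expect_error(loss_and_error(1, 0, "hinge"))
})

test_that("error backprojection equals the explicit sum over readout units", {
  expect_equal(as.vector(backproject_error(c(-0.7, 0), diag(2))), c(-0.7, 0))
  expect_equal(as.vector(backproject_error(c(0, 0), diag(2))), c(0, 0))
  G <- build_readout(8, 3, 12)
  dY <- withr::with_seed(13, stats::rnorm(3))
  H <- t(G)
  err <- backproject_error(dY, H)
  loop <- numeric(8)
  for (i in 1:8) for (k in 1:3) loop[i] <- loop[i] + G[k, i] * dY[k]
  expect_equal(as.vector(err), loop, tolerance = 1e-14)
})

test_that("the three-factor gradient multiplies error, boxcar gate and trace", {
  g <- decolle_gradient(-0.7, 0.1, 0.2)
  expect_equal(as.vector(g$gW), -0.14)
  expect_equal(g$gb, -0.7, ignore_attr = TRUE)
  # membrane outside the plasticity window: update gated off entirely
  g <- decolle_gradient(5, 0.8, c(1, 1))
  expect_true(all(g$gW == 0) && all(g$gb == 0))
  g <- decolle_gradient(0, 0.1, c(1, 1))
  expect_true(all(g$gW == 0) && all(g$gb == 0))
  # batched gradients are averaged over the batch
  err <- matrix(c(1, 3), 2, 1)
  U <- matrix(0, 2, 1)
  P <- matrix(c(1, 1), 2, 1)
  g <- decolle_gradient(err, U, P)
  expect_equal(as.vector(g$gW), 2)
})

test_that("vectorized update equals the literal triple-loop form", {
  withr::with_seed(21, {
    for (rep_i in 1:5) {
      n_in <- sample(3:12, 1); n_out <- sample(2:8, 1); n_t <- sample(1:4, 1)
      G <- build_readout(n_out, n_t, rep_i)
      S <- stats::rbinom(n_out, 1, 0.5)
      U <- stats::rnorm(n_out, sd = 0.4)
      P <- stats::runif(n_in)
      Y_hat <- stats::rnorm(n_t)
      Y <- as.vector(G %*% S)
      le <- loss_and_error(Y, Y_hat, "mse")
      err <- backproject_error(le$dY, t(G))
      g <- decolle_gradient(err, U, P)
      gate <- as.numeric(abs(U) <= 0.5)
      loop <- matrix(0, n_out, n_in)
      for (i in 1:n_out) for (j in 1:n_in) {
        e_i <- 0
        for (k in 1:n_t) e_i <- e_i + G[k, i] * (Y[k] - Y_hat[k])
        loop[i, j] <- e_i * gate[i] * P[j]
      }
      expect_lt(max(abs(g$gW - loop)) / max(abs(loop), 1e-12), 1e-12)
    }
  })
})

test_that("closed-form rule matches finite differences of the relaxed loss", {
  # smaller spot check; the full 50-instance audit runs in the acceptance
  # suite
  worst <- 0
  withr::with_seed(99, {
    for (i in 1:10) {
      inst <- random_dense_instance(sample(2:20, 1), sample(2:10, 1), sample(1:5, 1), 100 + i)
      inst <- nudge_off_kinks(inst)
      cf <- closed_form_grad(inst)
      fd <- fd_grad(inst)
      worst <- max(worst, max_rel_err(cf$gW, fd$gW), max_rel_err(cf$gb, fd$gb))
    }
  })
  expect_lt(worst, 1e-5)
})

test_that("membrane regularizers penalise high and vanishing activity", {
  r <- regularizer(matrix(-0.5, 1, 4), 1, 1)
  expect_equal(r$loss, 0.6) # no upper penalty, 0.1 - (-0.5) from the floor
  r <- regularizer(matrix(-0.01, 1, 4), 1, 2)
  expect_equal(r$loss, 2 * 0.11) # upper term at its boundary contributes 0
  expect_error(regularizer(matrix(0, 1, 2), -1, 0), "lambda1")
  # gradient check away from the kinks
  U <- withr::with_seed(31, matrix(stats::rnorm(12, sd = 0.4), 1, 12))
  r <- regularizer(U, 0.7, 1.3)
  eps <- 1e-6
  for (j in c(1, 5, 12)) {
    Up <- U; Up[j] <- U[j] + eps
    Um <- U; Um[j] <- U[j] - eps
    fd <- (regularizer(Up, 0.7, 1.3)$loss - regularizer(Um, 0.7, 1.3)$loss) / (2 * eps)
    expect_equal(r$dU[1, j], fd, tolerance = 1e-5)
  }
})

test_that("AdaMax normalises steps by the running infinity norm", {
  p <- list(W = matrix(1, 2, 2))
  st <- adamax_init(p, eta = 0.1, beta1 = 0, beta2 = 0.95)
  g <- list(W = matrix(c(2, -3, 0, 4), 2, 2))
  r <- adamax_step(p, g, st)
  # beta1 = 0: first step moves each coordinate by eta * sign(g)
  expect_equal(r$params$W, matrix(1, 2, 2) - 0.1 * sign(g$W), tolerance = 1e-6)
  # zero gradient leaves parameters untouched
  r0 <- adamax_step(p, list(W = matrix(0, 2, 2)), st)
  expect_identical(r0$params$W, p$W)
  # constant gradient: second step still eta (u saturates at |g|)
  r2 <- adamax_step(r$params, g, r$state)
  step2 <- abs(r2$params$W - r$params$W)
  expect_equal(step2[g$W != 0], rep(0.1, 3), tolerance = 1e-6)
  expect_error(adamax_step(p, g, list()), "adamax_init")
})

test_that("readout and feedback are bit-identical across training", {
  spec <- network_spec(10, list(layer_dense(8), layer_dense(6)), n_targets = 2)
  net <- build_network(spec, 77)
  G_before <- lapply(net$layers, `[[`, "G")
  H_before <- lapply(net$layers, `[[`, "H")
  input <- poisson_spike_train(rep(80, 10), 60, 1, seed = 3)
  tgt <- matrix(0.5, 60, 2)
  run <- train_online(net, array(input, c(60, 1, 10)), tgt,
                      train_config(eta = 1e-3))
  expect_identical(lapply(run$net$layers, `[[`, "G"), G_before)
  expect_identical(lapply(run$net$layers, `[[`, "H"), H_before)
  # ...while the trainable weights did change
  expect_false(identical(run$net$layers[[1]]$W, net$layers[[1]]$W))
})
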