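# Network construction, forward stepping, online training, evaluation.

small_dense_net <- function(seed = 1, n_in = 10, units = c(8, 6, 5), n_targets = 2) {
  spec <- network_spec(n_in, lapply(units, layer_dense), n_targets = n_targets)
  build_network(spec, seed)
}

test_that("network construction is seeded, shaped and validated", {
  net <- small_dense_net(3)
  expect_length(net$layers, 3)
  expect_identical(dim(net$layers[[1]]$W), c(8L, 10L))
  expect_identical(dim(net$layers[[2]]$W), c(6L, 8L))
  expect_identical(dim(net$layers[[1]]$G), c(2L, 8L))
  expect_true(all(net$layers[[1]]$b == -0.01))
  expect_identical(net, small_dense_net(3))
  expect_false(identical(net$layers[[1]]$W, small_dense_net(4)$layers[[1]]$W))
  # weights bounded by the fan-in rule
  expect_true(all(abs(net$layers[[1]]$W) <= 1 / sqrt(10)))
  expect_error(
    build_network(network_spec(5, list(layer_conv(4, 3)), n_targets = 2), 1),
    "layer 1"
  )
})

test_that("the event-vision architecture preset reproduces its feature-map chain", {
  # 32x32 two-polarity input through three 7x7 conv layers with padding 2:
  # 30x30 -> pool 15x15 -> 13x13 -> 11x11 -> pool 5x5
  spec <- network_spec(
    c(2, 32, 32),
    list(
      layer_conv(8, 7, padding = 2, pool = 2),
      layer_conv(8, 7, padding = 2, pool = 1),
      layer_conv(8, 7, padding = 2, pool = 2)
    ),
    n_targets = 11
  )
  net <- build_network(spec, 1)
  expect_identical(net$layers[[1]]$conv_shape[2:3], c(30L, 30L))
  expect_identical(net$layers[[1]]$out_shape[2:3], c(15L, 15L))
  expect_identical(net$layers[[2]]$out_shape[2:3], c(13L, 13L))
  expect_identical(net$layers[[3]]$conv_shape[2:3], c(11L, 11L))
  expect_identical(net$layers[[3]]$out_shape[2:3], c(5L, 5L))
})

test_that("a quiescent network stays at rest and a single layer reduces to step_layer", {
  net <- small_dense_net(5)
  state <- net_init_state(net, 1)
  fw <- decolle:::forward_step(net, state, matrix(0, 1, 10))
  for (l in 1:3) {
    expect_true(all(fw$state[[l]]$S == 0))
    expect_true(all(fw$layers[[l]]$Y == 0))
  }
  # single-layer network equals step_layer + local_readout
  spec1 <- network_spec(10, list(layer_dense(8)), n_targets = 2)
  net1 <- build_network(spec1, 7)
  st1 <- net_init_state(net1, 1)
  frame <- withr::with_seed(7, matrix(stats::rbinom(10, 1, 0.5), 1, 10))
  fw1 <- decolle:::forward_step(net1, st1, frame)
  ref <- step_layer(init_state(1, 10, 8), frame, net1$layers[[1]]$W, net1$layers[[1]]$b,
                    net1$neuron)
  expect_equal(fw1$state[[1]]$U, ref$state$U)
  expect_equal(fw1$state[[1]]$S, ref$S_out)
  expect_equal(fw1$layers[[1]]$Y, local_readout(ref$S_out, net1$layers[[1]]$G))
})

test_that("persistent state size does not depend on how long the net has run", {
  net <- small_dense_net(6)
  cfg <- train_config(eta = 1e-3)
  run_for <- function(T_steps) {
    input <- poisson_spike_train(rep(100, 10), T_steps, 1, seed = 2)
    tgt <- matrix(0.3, T_steps, 2)
    run <- train_online(net, array(input, c(T_steps, 1, 10)), tgt, cfg)
    state_footprint(run$net, run$state, run$opt)
  }
  expect_identical(run_for(100), run_for(10000))
})

test_that("eta = 0 training changes nothing but still reports metrics", {
  net <- small_dense_net(8)
  input <- poisson_spike_train(rep(80, 10), 120, 1, seed = 9)
  tgt <- matrix(0.4, 120, 2)
  run <- train_online(net, array(input, c(120, 1, 10)), tgt, train_config(eta = 0))
  expect_identical(run$net$layers[[1]]$W, net$layers[[1]]$W)
  expect_identical(run$net$layers[[3]]$b, net$layers[[3]]$b)
  expect_gt(nrow(run$metrics), 0)
  expect_true(all(is.finite(run$metrics$loss)))
})

test_that("burn-in suppresses updates and sets the update count", {
  net <- small_dense_net(10)
  input <- poisson_spike_train(rep(80, 10), 300, 1, seed = 10)
  tgt <- matrix(0.4, 300, 2)
  # 300-step sequence, 50 ms burn-in at dt = 1 ms: exactly 250 updates
  run <- train_online(net, array(input, c(300, 1, 10)), tgt,
                      train_config(eta = 1e-3, burn_in = 50))
  expect_identical(run$n_updates, 250L)
  # burn-in covering the whole sequence: no updates at all
  run2 <- train_online(net, array(input, c(300, 1, 10)), tgt,
                       train_config(eta = 1e-3, burn_in = 300))
  expect_identical(run2$n_updates, 0L)
  expect_identical(run2$net$layers[[1]]$W, net$layers[[1]]$W)
})

test_that("a layer's update is blind to every other layer's weights", {
  net <- small_dense_net(12)
  input <- poisson_spike_train(rep(90, 10), 40, 1, seed = 13)
  tgt <- matrix(0.4, 40, 2)
  cfg <- train_config(eta = 1e-3)
  run_a <- train_online(net, array(input, c(40, 1, 10)), tgt, cfg)
  # zero out layer 3's weights: layer 1 must receive the bit-identical update
  net_b <- net
  net_b$layers[[3]]$W[] <- 0
  run_b <- train_online(net_b, array(input, c(40, 1, 10)), tgt, cfg)
  expect_identical(run_a$net$layers[[1]]$W, run_b$net$layers[[1]]$W)
  expect_identical(run_a$net$layers[[1]]$b, run_b$net$layers[[1]]$b)
})

test_that("learning-rate schedule divides eta at the configured interval", {
  net <- small_dense_net(14)
  input <- poisson_spike_train(rep(90, 10), 30, 1, seed = 14)
  tgt <- matrix(0.4, 30, 2)
  cfg <- train_config(eta = 1e-3, schedule_divisor = 5, schedule_interval = 10)
  run <- train_online(net, array(input, c(30, 1, 10)), tgt, cfg)
  expect_identical(run$n_updates, 30L)
  # indirect check: training with the schedule differs from without
  run_flat <- train_online(net, array(input, c(30, 1, 10)), tgt,
                           train_config(eta = 1e-3))
  expect_false(identical(run$net$layers[[1]]$W, run_flat$net$layers[[1]]$W))
})

test_that("dropout masks spikes with inverted scaling and respects eval mode", {
  s <- matrix(1, 1, 1e5)
  expect_identical(apply_dropout(s, 0, "train"), s)
  expect_identical(apply_dropout(s, 0.5, "eval"), s)
  masked <- apply_dropout(s, 0.5, "train", seed = 3)
  keep <- mean(masked > 0)
  expect_lt(abs(keep - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_true(all(masked %in% c(0, 2))) # survivors scaled by 1/(1-p)
  expect_false(identical(apply_dropout(s, 0.5, "eval", seed = 3, active_at_eval = TRUE), s))
  expect_error(apply_dropout(s, 1, "train"), "dropout")
})

test_that("classification accumulates readouts after burn-in, ties to the lowest class", {
  net <- small_dense_net(15, n_targets = 4)
  # force a constant one-hot readout on the last layer by zeroing G except
  # one row that sums spikes positively
  net$layers[[3]]$G[] <- 0
  net$layers[[3]]$G[3, ] <- 0.1
  input <- array(poisson_spike_train(rep(200, 10), 80, 1, seed = 16), c(80, 1, 10))
  pred <- evaluate_classification(net, input, train_config(burn_in = 10))
  expect_identical(pred[1, 3], 3L)
  # exact tie between classes 2 and 5 resolves to 2
  expect_identical(max.col(matrix(c(0, 1, 0, 0, 1), 1), ties.method = "first"), 2L)
  net$layers[[3]]$G[] <- 0 # all-zero readout: every class ties, class 1 wins
  pred0 <- evaluate_classification(net, input, train_config(burn_in = 10))
  expect_identical(pred0[1, 3], 1L)
  expect_error(
    evaluate_classification(net, input, train_config(burn_in = 100)),
    "burn-in"
  )
})

test_that("accumulated-readout argmax equals an explicit sum-then-argmax loop", {
  net <- small_dense_net(17, n_targets = 3)
  input <- array(poisson_spike_train(rep(150, 10), 60, 1, seed = 18), c(60, 1, 10))
  cfg <- train_config(burn_in = 5)
  pred <- evaluate_classification(net, input, cfg)
  # replay the forward pass manually
  state <- net_init_state(net, 1)
  acc <- lapply(1:3, function(l) rep(0, 3))
  for (t in 1:60) {
    fw <- decolle:::forward_step(net, state, input[t, , , drop = FALSE][1, , , drop = FALSE])
    state <- fw$state
    if (t > 5) for (l in 1:3) acc[[l]] <- acc[[l]] + as.vector(fw$layers[[l]]$Y)
  }
  for (l in 1:3) expect_identical(pred[1, l], which.max(acc[[l]]))
})

test_that("spike-count classification requires one output unit per class", {
  spec <- network_spec(10, list(layer_dense(8), layer_dense(4)), n_targets = 4)
  net <- build_network(spec, 19)
  input <- array(poisson_spike_train(rep(150, 10), 40, 1, seed = 20), c(40, 1, 10))
  pred <- evaluate_classification(net, input, train_config(burn_in = 5), mode = "spikes")
  expect_true(pred[1, 2] %in% 1:4)
  expect_true(is.na(pred[1, 1]))
  net_bad <- small_dense_net(21, n_targets = 4)
  expect_error(
    evaluate_classification(net_bad, input, train_config(burn_in = 5), mode = "spikes"),
    "one unit per class"
  )
})

test_that("convolutional networks train end to end and keep map geometry", {
  spec <- network_spec(
    c(2, 8, 8),
    list(layer_conv(3, 3, padding = 1, pool = 2, dropout = 0.2), layer_conv(4, 3, padding = 1)),
    n_targets = 2
  )
  net <- build_network(spec, 22)
  expect_identical(net$layers[[1]]$out_shape, c(3L, 4L, 4L))
  expect_identical(net$layers[[2]]$out_shape, c(4L, 4L, 4L))
  T_steps <- 30
  input <- withr::with_seed(23, array(stats::rbinom(T_steps * 2 * 8 * 8, 1, 0.1),
                                      c(T_steps, 1, 2, 8, 8)))
  tgt <- matrix(c(1, 0), T_steps, 2, byrow = TRUE)
  run <- withr::with_seed(24, train_online(net, input, tgt, train_config(eta = 1e-3, burn_in = 5)))
  expect_identical(run$n_updates, 25L)
  expect_false(identical(run$net$layers[[1]]$W, net$layers[[1]]$W))
  expect_true(all(is.finite(run$metrics$loss)))
})
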