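# Bridge between the R reference implementation and the compiled engine.
# Both engines implement the same semantics; "r" is the readable reference,
# "cpp" the fast path used by default for training and classification
# evaluation. The test suite asserts their numerical equivalence.

engine_layers <- function(net, state) {
  lapply(seq_along(net$layers), function(l) {
    lay <- net$layers[[l]]
    st <- state[[l]]
    base <- list(
      conv = if (lay$kind == "conv") 1L else 0L,
      W = lay$W, b = as.numeric(lay$b),
      Gt = t(lay$G), Ht = lay$H,
      dropout = lay$dropout,
      n_in = as.integer(lay$n_in), n_out = as.integer(lay$n_out),
      state = list(
        P = matrix(st$P, nrow = dim(st$P)[1]),
        Q = matrix(st$Q, nrow = dim(st$Q)[1]),
        R = st$R, U = st$U, S = st$S
      )
    )
    if (lay$kind == "conv") {
      base$C <- lay$in_shape[1]; base$H <- lay$in_shape[2]; base$Wd <- lay$in_shape[3]
      base$k <- lay$kernel; base$pad <- lay$padding; base$pool <- lay$pool
      base$F <- lay$filters
    }
    base
  })
}

engine_opt <- function(net, cfg, opt) {
  if (is.null(opt)) {
    opt <- lapply(net$layers, function(lay) {
      adamax_init(list(W = lay$W, b = lay$b),
        eta = cfg$eta, beta1 = cfg$beta1, beta2 = cfg$beta2
      )
    })
    attr(opt, "n_updates") <- 0L
  }
  opt
}

engine_cfg <- function(net, cfg, burn_steps, training, dropout_active, n_updates) {
  list(
    training = training, dropout_active = dropout_active,
    alpha = net$neuron$alpha, beta = net$neuron$beta, gamma = net$neuron$gamma,
    rho = net$neuron$rho, burn_steps = as.integer(burn_steps),
    eta = cfg$eta, beta1 = cfg$beta1, beta2 = cfg$beta2, eps = 1e-8,
    lambda1 = cfg$lambda1, lambda2 = cfg$lambda2,
    loss_kind = if (cfg$loss == "mse") 0L else 1L,
    schedule_divisor = cfg$schedule_divisor,
    schedule_interval = cfg$schedule_interval,
    log_every = as.integer(cfg$log_every),
    n_updates = as.numeric(n_updates)
  )
}

# Rebuild R-side state objects from the engine's flat matrices.
engine_restore_state <- function(net, flat) {
  lapply(seq_along(net$layers), function(l) {
    lay <- net$layers[[l]]
    st <- flat[[l]]
    if (lay$kind == "conv") {
      dim(st$P) <- c(nrow(st$R), lay$in_shape[2], lay$in_shape[3], lay$in_shape[1])
      dim(st$Q) <- dim(st$P)
      st
    } else {
      structure(st, class = "decolle_layer_state")
    }
  })
}

run_engine <- function(net, input, targets, cfg, opt, state, training,
                       dropout_active = FALSE) {
  T_steps <- dim(input)[1]
  B <- dim(input)[2]
  if (is.null(state)) state <- net_init_state(net, B)
  burn_steps <- round(cfg$burn_in / net$neuron$dt)
  opt <- engine_opt(net, cfg, opt)
  opt_flat <- lapply(opt, function(o) {
    list(mW = o$m$W, uW = o$u$W, mb = as.numeric(o$m$b), ub = as.numeric(o$u$b))
  })
  res <- .cpp_run_network(
    engine_layers(net, state),
    as.numeric(input), as.integer(dim(input)),
    if (is.null(targets)) vector("list", length(net$layers)) else targets,
    opt_flat,
    engine_cfg(net, cfg, burn_steps, training, dropout_active,
               attr(opt, "n_updates"))
  )
  if (training) {
    for (l in seq_along(net$layers)) {
      net$layers[[l]]$W <- res$layers[[l]]$W
      net$layers[[l]]$b <- as.numeric(res$layers[[l]]$b)
      o <- res$opt[[l]]
      steps_run <- res$n_updates - attr(opt, "n_updates")
      opt[[l]]$m <- list(W = o$mW, b = as.numeric(o$mb))
      opt[[l]]$u <- list(W = o$uW, b = as.numeric(o$ub))
      opt[[l]]$t <- opt[[l]]$t + as.integer(steps_run)
    }
    attr(opt, "n_updates") <- as.integer(res$n_updates)
  }
  list(
    net = net, opt = opt,
    state = engine_restore_state(net, res$state),
    n_updates = as.integer(res$n_updates),
    metrics = as.data.frame(res$metrics),
    accY = res$accY, accS = res$accS
  )
}
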