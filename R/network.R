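# Layer stacking and the online training loop. Each layer is a spiking layer
# (dense or convolutional, optionally with 2x2 max pooling and dropout on
# its spike output) with its own fixed random readout G, feedback H and
# per-layer loss. Spikes are passed between layers as values only: no error
# information ever crosses a layer boundary, so each layer's update is a
# pure function of its own state at the current time step.

#' Dense layer descriptor
#'
#' @param n_units number of neurons.
#' @param dropout dropout probability on the spike output, in `[0, 1)`.
#' @return a layer descriptor for [network_spec()].
#' @export
layer_dense <- function(n_units, dropout = 0) {
  n_units <- check_count(n_units, "n_units")
  check_dropout(dropout)
  list(kind = "dense", n_units = n_units, dropout = dropout)
}

#' Convolutional layer descriptor
#'
#' Square kernels, stride 1, optional zero padding and non-overlapping 2x2
#' max pooling of the membrane map before thresholding (order: convolution
#' -> pooling -> spiking nonlinearity -> dropout).
#'
#' @param filters number of output channels.
#' @param kernel kernel size.
#' @param padding zero padding on each side.
#' @param pool 1 (no pooling) or 2 (2x2 max pooling).
#' @param dropout dropout probability on the spike output.
#' @return a layer descriptor for [network_spec()].
#' @export
layer_conv <- function(filters, kernel, padding = 0, pool = 1, dropout = 0) {
  filters <- check_count(filters, "filters")
  kernel <- check_count(kernel, "kernel")
  if (!pool %in% c(1, 2)) abort("`pool` must be 1 (none) or 2 (2x2 max pooling)")
  check_dropout(dropout)
  list(
    kind = "conv", filters = filters, kernel = kernel,
    padding = check_count(padding, "padding", min = 0L), pool = as.integer(pool),
    dropout = dropout
  )
}

check_dropout <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 1) {
    abort("`dropout` must be in [0, 1)")
  }
}

#' Network architecture specification
#'
#' @param input_shape for dense networks, the number of input channels; for
#'   convolutional networks, `c(channels, height, width)`.
#' @param layers list of [layer_dense()] / [layer_conv()] descriptors
#'   (convolutional layers must precede dense layers).
#' @param n_targets number of local-readout target units attached to every
#'   layer.
#' @param neuron a [neuron_config()].
#' @return an object of class `decolle_network_spec`.
#' @export
network_spec <- function(input_shape, layers, n_targets, neuron = neuron_config()) {
  if (length(layers) < 1L) abort("at least one layer is required")
  n_targets <- check_count(n_targets, "n_targets")
  structure(list(
    input_shape = as.integer(input_shape), layers = layers,
    n_targets = n_targets, neuron = neuron
  ), class = "decolle_network_spec")
}

#' Build a trainable network from a specification
#'
#' Weights are initialised uniformly on `[-1/sqrt(fan_in), +1/sqrt(fan_in)]`
#' and biases at -0.01, so resting neurons sit just below threshold and
#' inside the boxcar plasticity window. Each layer gets its own fixed
#' readout `G` and feedback `H` from seeds derived deterministically from
#' the master seed; the same seed always yields a bit-identical network.
#'
#' @param spec a [network_spec()].
#' @param seed master RNG seed.
#' @param concordant build sign-concordant feedback matrices (default);
#'   `FALSE` uses the exact transpose `t(G)`.
#' @return an object of class `decolle_network`.
#' @export
build_network <- function(spec, seed, concordant = TRUE) {
  if (!inherits(spec, "decolle_network_spec")) abort("`spec` must come from network_spec()")
  shape <- spec$input_shape
  layers <- vector("list", length(spec$layers))
  for (l in seq_along(spec$layers)) {
    ld <- spec$layers[[l]]
    lay <- ld
    if (ld$kind == "conv") {
      if (length(shape) != 3L) {
        abort(sprintf("layer %d: convolutional layer needs a (channels, height, width) input", l))
      }
      C <- shape[1]; H <- shape[2]; W <- shape[3]
      Ho <- H + 2L * ld$padding - ld$kernel + 1L
      Wo <- W + 2L * ld$padding - ld$kernel + 1L
      if (Ho < 1L || Wo < 1L) abort(sprintf("layer %d: kernel exceeds the padded input map", l))
      Hp <- Ho %/% ld$pool
      Wp <- Wo %/% ld$pool
      fan_in <- C * ld$kernel^2
      lay$in_shape <- c(C, H, W)
      lay$conv_shape <- c(ld$filters, Ho, Wo)
      lay$out_shape <- c(ld$filters, Hp, Wp)
      lay$n_in <- prod(lay$in_shape)
      lay$n_out <- prod(lay$out_shape)
      lim <- 1 / sqrt(fan_in)
      lay$W <- with_seed(
        derive_seed(seed, 10L * l + 1L),
        matrix(stats::runif(ld$filters * fan_in, -lim, lim), ld$filters, fan_in)
      )
      lay$b <- rep(-0.01, ld$filters)
    } else {
      n_in <- prod(shape)
      lay$in_shape <- n_in
      lay$out_shape <- ld$n_units
      lay$n_in <- n_in
      lay$n_out <- ld$n_units
      lim <- 1 / sqrt(n_in)
      lay$W <- with_seed(
        derive_seed(seed, 10L * l + 1L),
        matrix(stats::runif(ld$n_units * n_in, -lim, lim), ld$n_units, n_in)
      )
      lay$b <- rep(-0.01, ld$n_units)
    }
    lay$G <- build_readout(lay$n_out, spec$n_targets, derive_seed(seed, 10L * l + 2L))
    lay$H <- build_feedback(lay$G, derive_seed(seed, 10L * l + 3L), concordant = concordant)
    layers[[l]] <- lay
    shape <- lay$out_shape
  }
  structure(list(
    spec = spec, layers = layers, neuron = spec$neuron,
    n_targets = spec$n_targets, seed = seed, concordant = concordant
  ), class = "decolle_network")
}

#' @export
print.decolle_network <- function(x, ...) {
  cat(sprintf(
    "DECOLLE network: %d layer(s), %d readout target(s) per layer\n",
    length(x$layers), x$n_targets
  ))
  for (l in seq_along(x$layers)) {
    lay <- x$layers[[l]]
    if (lay$kind == "conv") {
      cat(sprintf(
        "  [%d] conv %dx%d, %d filters, pad %d, pool %d, dropout %.2f: (%s) -> (%s)\n",
        l, lay$kernel, lay$kernel, lay$filters, lay$padding, lay$pool, lay$dropout,
        paste(lay$in_shape, collapse = "x"), paste(lay$out_shape, collapse = "x")
      ))
    } else {
      cat(sprintf(
        "  [%d] dense %d -> %d, dropout %.2f\n", l, lay$n_in, lay$n_out, lay$dropout
      ))
    }
  }
  invisible(x)
}

#' Initialise the full network state at rest
#'
#' @param net a [build_network()] result.
#' @param batch_size number of sequences simulated in parallel.
#' @return list of per-layer states (traces and membrane variables, all
#'   zero).
#' @export
net_init_state <- function(net, batch_size) {
  batch_size <- check_count(batch_size, "batch_size")
  lapply(net$layers, function(lay) {
    if (lay$kind == "conv") {
      # input maps are held channel-last (B, H, W, C); output-side states
      # are flat (B, units) matrices with unit order (y, x, channel)
      list(
        P = array(0, c(batch_size, lay$in_shape[2], lay$in_shape[3], lay$in_shape[1])),
        Q = array(0, c(batch_size, lay$in_shape[2], lay$in_shape[3], lay$in_shape[1])),
        R = matrix(0, batch_size, lay$n_out),
        U = matrix(0, batch_size, lay$n_out),
        S = matrix(0, batch_size, lay$n_out)
      )
    } else {
      init_state(batch_size, lay$n_in, lay$n_out)
    }
  })
}

# Precompute per-layer im2col and pooling plans for a given batch size
# (NULL entries for dense layers); reused across all time steps of a run.
conv_plans <- function(net, batch_size) {
  lapply(net$layers, function(lay) {
    if (lay$kind != "conv") return(NULL)
    plan <- make_im2col_plan(batch_size, lay$in_shape[1], lay$in_shape[2],
                             lay$in_shape[3], lay$kernel, lay$padding, layout = "cl")
    if (lay$pool == 2L) plan$pool <- make_pool_plan(batch_size, plan$Ho, plan$Wo)
    plan
  })
}

#' Dropout on spike outputs
#'
#' Inverted dropout: in training mode each unit is zeroed independently
#' with probability `p` and survivors are scaled by `1/(1-p)`; in
#' evaluation mode the identity is applied unless `active_at_eval` is set
#' (test-time dropout can be kept active deliberately, as an ensemble-like
#' evaluation).
#'
#' @param spikes spike values (any numeric array).
#' @param p dropout probability in `[0, 1)`.
#' @param mode `"train"` or `"eval"`.
#' @param seed optional seed; by default the current RNG stream is used.
#' @param active_at_eval apply dropout in evaluation mode too.
#' @return masked spikes, same shape.
#' @export
apply_dropout <- function(spikes, p, mode = c("train", "eval"), seed = NULL,
                          active_at_eval = FALSE) {
  mode <- match.arg(mode)
  check_dropout(p)
  if (p == 0 || (mode == "eval" && !active_at_eval)) return(spikes)
  draw <- function() stats::runif(length(spikes)) >= p
  keep <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- spikes
  out[] <- spikes * keep / (1 - p)
  out
}

# One forward time step through every layer. `frame` is the input at this
# time step: (B, n_inputs) for dense networks, (B, C, H, W) for
# convolutional ones. Dropout masks (when active) are drawn from the
# current RNG stream. Returns the new state plus per-layer transient
# caches used by the learning rule; the caches are recomputed every step
# and never persist.
forward_step <- function(net, state, frame, training = FALSE, dropout_active = FALSE,
                         plans = NULL) {
  cfg <- net$neuron
  B <- dim(frame)[1]
  S_in <- frame
  caches <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    st <- state[[l]]
    if (lay$kind == "conv") {
      if (length(dim(S_in)) != 4L) abort("convolutional layer fed with non-map input")
      plan <- if (is.null(plans[[l]])) conv_plans(net, B)[[l]] else plans[[l]]
      P <- cfg$alpha * st$P + (1 - cfg$alpha) * st$Q
      Q <- cfg$beta * st$Q + (1 - cfg$beta) * S_in
      M <- im2col(P, lay$kernel, lay$padding, plan)
      V <- M %*% t(lay$W) # rows (b, oy, ox), cols filter
      V <- V + rep(lay$b, each = nrow(V))
      if (lay$pool == 2L) {
        pr <- plan$pool$rows
        v1 <- V[pr[[1]], , drop = FALSE]; v2 <- V[pr[[2]], , drop = FALSE]
        v3 <- V[pr[[3]], , drop = FALSE]; v4 <- V[pr[[4]], , drop = FALSE]
        pooled <- pmax(v1, v2, v3, v4)
        i1 <- v1 == pooled
        i2 <- !i1 & (v2 == pooled)
        i3 <- !i1 & !i2 & (v3 == pooled)
        pool_idx <- 4L - 3L * i1 - 2L * i2 - 1L * i3
        Umat <- pooled
      } else {
        pool_idx <- NULL
        Umat <- V
      }
      # reinterpret (b, y, x) rows x filter cols as flat (b, units):
      # same linear order, no copy
      dim(Umat) <- c(B, lay$n_out)
      Umat <- Umat - cfg$rho * st$R
      S <- spike_threshold(Umat)
      state[[l]] <- list(
        P = P, Q = Q, R = cfg$gamma * st$R + (1 - cfg$gamma) * S, U = Umat, S = S
      )
      U_flat <- Umat
      S_flat <- S
      cache <- list(M = M, plan = plan, pool_idx = pool_idx)
    } else {
      if (length(dim(S_in)) > 2L) S_in <- map_to_mat(S_in)
      tr <- update_traces(st$P, st$Q, S_in, cfg$alpha, cfg$beta)
      ms <- membrane_and_spike(tr$P, st$R, lay$W, lay$b, cfg$rho)
      state[[l]] <- structure(list(
        P = tr$P, Q = tr$Q,
        R = update_refractory(st$R, ms$S, cfg$gamma), U = ms$U, S = ms$S
      ), class = "decolle_layer_state")
      U_flat <- ms$U
      S_flat <- ms$S
      cache <- list()
    }
    # dropout feeds both the next layer and this layer's readout
    mask <- NULL
    S_masked <- state[[l]]$S
    if (lay$dropout > 0 && (training || dropout_active)) {
      keep <- stats::runif(length(S_masked)) >= lay$dropout
      mask <- array(keep / (1 - lay$dropout), dim = dim(S_masked))
      S_masked <- S_masked * mask
    }
    S_masked_flat <- if (is.matrix(S_masked)) S_masked else map_to_mat(S_masked)
    cache$U <- U_flat
    cache$P <- state[[l]]$P
    cache$mask <- mask
    cache$Y <- local_readout(S_masked_flat, lay$G)
    caches[[l]] <- cache
    if (lay$kind == "conv") {
      # hand the next layer a channel-last map view of the (masked) spikes
      dim(S_masked) <- c(B, lay$out_shape[2], lay$out_shape[3], lay$out_shape[1])
    }
    S_in <- S_masked
  }
  list(state = state, layers = caches)
}

# Per-layer loss and parameter gradients at the current time step. Pure
# function of this layer's transient cache and its pseudo-target: nothing
# from other layers or other time steps enters.
layer_loss_and_grads <- function(net, l, cache, target, loss_kind, lambda1, lambda2) {
  lay <- net$layers[[l]]
  le <- loss_and_error(cache$Y, target, loss_kind)
  err <- backproject_error(le$dY, lay$H)
  if (!is.null(cache$mask)) {
    # the readout saw masked spikes; the surrogate gradient flows back
    # through the same mask and scale
    err <- err * map_to_mat(cache$mask)
  }
  reg <- regularizer(cache$U, lambda1, lambda2)
  d <- err * surrogate_derivative(cache$U) + reg$dU
  B <- nrow(d)
  if (lay$kind == "conv") {
    # back to (b, y, x) rows x filter cols (no copy), then route through
    # the pool argmax onto the pre-pool grid
    dmat <- d
    dim(dmat) <- c(B * lay$out_shape[2] * lay$out_shape[3], lay$out_shape[1])
    if (lay$pool == 2L) {
      pr <- cache$plan$pool$rows
      dpre <- matrix(0, B * cache$plan$Ho * cache$plan$Wo, lay$out_shape[1])
      for (pos in 1:4) {
        dpre[pr[[pos]], ] <- dpre[pr[[pos]], , drop = FALSE] +
          dmat * (cache$pool_idx == pos)
      }
    } else {
      dpre <- dmat
    }
    gW <- crossprod(dpre, cache$M) / B
    gb <- colSums(dmat) / B
  } else {
    gW <- crossprod(d, cache$P) / B
    gb <- colSums(d) / B
  }
  list(loss = le$loss, reg_loss = reg$loss, gW = gW, gb = gb)
}

#' Online training configuration
#'
#' @param eta AdaMax learning rate.
#' @param burn_in initial interval (ms) of each sequence during which states
#'   equilibrate and no update is applied.
#' @param lambda1,lambda2 membrane regularizer weights (see
#'   [regularizer()]).
#' @param loss per-layer loss kind, `"mse"` or `"smooth_l1"`.
#' @param beta1,beta2 AdaMax decay parameters.
#' @param schedule_divisor,schedule_interval divide the learning rate by
#'   `schedule_divisor` every `schedule_interval` optimizer steps
#'   (`Inf` interval disables the schedule).
#' @param dropout_active_at_eval keep dropout layers active during
#'   evaluation.
#' @param log_every record metrics every this many update steps.
#' @return an object of class `decolle_train_config`.
#' @export
train_config <- function(eta = 1e-6, burn_in = 0, lambda1 = 0.001, lambda2 = 0.001,
                         loss = c("mse", "smooth_l1"), beta1 = 0, beta2 = 0.95,
                         schedule_divisor = 1, schedule_interval = Inf,
                         dropout_active_at_eval = FALSE, log_every = 50) {
  loss <- match.arg(loss)
  check_scalar_number(eta, "eta", nonneg = TRUE)
  check_scalar_number(burn_in, "burn_in", nonneg = TRUE)
  if (schedule_divisor < 1) abort("`schedule_divisor` must be >= 1")
  if (schedule_interval < 1) abort("`schedule_interval` must be >= 1")
  structure(list(
    eta = eta, burn_in = burn_in, lambda1 = lambda1, lambda2 = lambda2,
    loss = loss, beta1 = beta1, beta2 = beta2,
    schedule_divisor = schedule_divisor, schedule_interval = schedule_interval,
    dropout_active_at_eval = dropout_active_at_eval, log_every = log_every
  ), class = "decolle_train_config")
}

# Coerce a time-major input to (T, B, ...) and targets to a per-layer list
# of (T, B, n_targets) arrays (single matrices are broadcast over batch).
canonical_input <- function(net, input) {
  d <- dim(input)
  conv_first <- net$layers[[1]]$kind == "conv"
  want <- if (conv_first) 5L else 3L
  if (length(d) == want - 1L) {
    # no batch dimension: insert B = 1
    input <- array(input, c(d[1], 1L, d[-1]))
    d <- dim(input)
  }
  if (length(d) != want) abort("input has the wrong number of dimensions for this network")
  # convolutional inputs are (T, B, C, H, W) at the interface; internally
  # maps are channel-last, so permute once per run
  if (conv_first) input <- aperm(input, c(1L, 2L, 4L, 5L, 3L))
  input
}

canonical_targets <- function(net, targets, T_steps, B) {
  n_layers <- length(net$layers)
  if (!is.list(targets)) targets <- rep(list(targets), n_layers)
  if (length(targets) != n_layers) abort("`targets` must have one element per layer")
  lapply(targets, function(tg) {
    if (is.matrix(tg)) {
      if (nrow(tg) != T_steps) abort("target length does not match the input stream")
      array(rep(tg, each = 1L), c(T_steps, 1L, ncol(tg)))[, rep(1L, B), , drop = FALSE]
    } else {
      if (!identical(dim(tg)[1:2], c(T_steps, B))) abort("target array shape mismatch")
      tg
    }
  })
}

#' Online training on one pass through an input stream
#'
#' For every time step after the burn-in period, the network takes one
#' forward step and every layer immediately applies its three-factor
#' update from its own local loss: there is one optimizer step per layer
#' per simulation time step. States persist across time steps within the
#' pass; call [net_init_state()] (or rely on the default) to reset them
#' between sequences.
#'
#' @param net a [build_network()] result.
#' @param input time-major input stream: `(T, B, n_inputs)` (dense) or
#'   `(T, B, C, H, W)` (convolutional); the batch dimension may be
#'   omitted.
#' @param targets per-layer pseudo-targets: a list with one element per
#'   layer, each a `(T, n_targets)` matrix (broadcast over batch) or a
#'   `(T, B, n_targets)` array; a single matrix is recycled to all layers.
#' @param cfg a [train_config()].
#' @param opt optional list of per-layer optimizer states from a previous
#'   call (continues the update clock and schedule); fresh states are
#'   created when omitted.
#' @param state optional initial network state; rest state when omitted.
#' @param engine `"cpp"` (compiled fast path, default) or `"r"` (the pure-R
#'   reference implementation); both compute the same updates and the test
#'   suite checks their agreement.
#' @return list with the updated `net`, `opt`, final `state`, the number of
#'   optimizer steps taken so far (`n_updates`), the scheduled learning
#'   rate in effect (`eta`), and a `metrics` data frame with per-layer
#'   loss, regularizer loss and spike-rate traces.
#' @export
train_online <- function(net, input, targets, cfg, opt = NULL, state = NULL,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!inherits(cfg, "decolle_train_config")) abort("`cfg` must come from train_config()")
  input <- canonical_input(net, input)
  T_steps <- dim(input)[1]
  B <- dim(input)[2]
  targets <- canonical_targets(net, targets, T_steps, B)
  if (engine == "cpp") {
    run <- run_engine(net, input, targets, cfg, opt, state, training = TRUE)
    run$eta <- cfg$eta
    return(run[c("net", "opt", "state", "n_updates", "eta", "metrics")])
  }
  burn_steps <- round(cfg$burn_in / net$neuron$dt)
  if (is.null(state)) state <- net_init_state(net, B)
  plans <- conv_plans(net, B)
  n_layers <- length(net$layers)
  if (is.null(opt)) {
    opt <- lapply(net$layers, function(lay) {
      adamax_init(list(W = lay$W, b = lay$b),
        eta = cfg$eta, beta1 = cfg$beta1, beta2 = cfg$beta2
      )
    })
    attr(opt, "n_updates") <- 0L
  }
  n_updates <- attr(opt, "n_updates")
  metrics <- list()
  for (t in seq_len(T_steps)) {
    frame <- if (length(dim(input)) == 3L) {
      array(input[t, , ], c(B, dim(input)[3]))
    } else {
      array(input[t, , , , ], c(B, dim(input)[3:5]))
    }
    fw <- forward_step(net, state, frame, training = TRUE, plans = plans)
    state <- fw$state
    if (t > burn_steps) {
      eta_t <- cfg$eta / cfg$schedule_divisor^(
        if (is.finite(cfg$schedule_interval)) n_updates %/% cfg$schedule_interval else 0
      )
      losses <- numeric(n_layers)
      regs <- numeric(n_layers)
      for (l in seq_len(n_layers)) {
        tgt <- matrix(targets[[l]][t, , ], B, dim(targets[[l]])[3])
        gr <- layer_loss_and_grads(net, l, fw$layers[[l]], tgt, cfg$loss, cfg$lambda1, cfg$lambda2)
        upd <- adamax_step(
          list(W = net$layers[[l]]$W, b = net$layers[[l]]$b),
          list(W = gr$gW, b = gr$gb), opt[[l]],
          eta = eta_t
        )
        net$layers[[l]]$W <- upd$params$W
        net$layers[[l]]$b <- upd$params$b
        opt[[l]] <- upd$state
        losses[l] <- gr$loss
        regs[l] <- gr$reg_loss
      }
      n_updates <- n_updates + 1L
      if (n_updates %% cfg$log_every == 0L || t == T_steps) {
        rates <- vapply(state, function(st) mean(st$S), numeric(1))
        metrics[[length(metrics) + 1L]] <- data.frame(
          step = n_updates, layer = seq_len(n_layers),
          loss = losses, reg_loss = regs, spike_rate = rates
        )
      }
    }
  }
  attr(opt, "n_updates") <- n_updates
  list(
    net = net, opt = opt, state = state, n_updates = n_updates,
    eta = cfg$eta, metrics = if (length(metrics)) do.call(rbind, metrics) else
      data.frame(step = integer(), layer = integer(), loss = numeric(),
                 reg_loss = numeric(), spike_rate = numeric())
  )
}

#' Evaluate per-layer losses on a stream without updating any parameter
#'
#' Runs the forward dynamics from rest and accumulates each layer's
#' readout loss over the time steps after burn-in. Equivalent to
#' [train_online()] with a zero learning rate, but cheaper.
#'
#' @inheritParams train_online
#' @return list with per-layer mean loss (`loss`), regularizer loss and
#'   mean spike rates.
#' @export
evaluate_loss <- function(net, input, targets, cfg) {
  input <- canonical_input(net, input)
  T_steps <- dim(input)[1]
  B <- dim(input)[2]
  targets <- canonical_targets(net, targets, T_steps, B)
  burn_steps <- round(cfg$burn_in / net$neuron$dt)
  state <- net_init_state(net, B)
  plans <- conv_plans(net, B)
  n_layers <- length(net$layers)
  loss <- numeric(n_layers)
  reg <- numeric(n_layers)
  rate <- numeric(n_layers)
  n <- 0L
  for (t in seq_len(T_steps)) {
    frame <- if (length(dim(input)) == 3L) {
      array(input[t, , ], c(B, dim(input)[3]))
    } else {
      array(input[t, , , , ], c(B, dim(input)[3:5]))
    }
    fw <- forward_step(net, state, frame, training = FALSE,
                       dropout_active = cfg$dropout_active_at_eval, plans = plans)
    state <- fw$state
    if (t > burn_steps) {
      n <- n + 1L
      for (l in seq_len(n_layers)) {
        tgt <- matrix(targets[[l]][t, , ], B, dim(targets[[l]])[3])
        le <- loss_and_error(fw$layers[[l]]$Y, tgt, cfg$loss)
        loss[l] <- loss[l] + le$loss
        reg[l] <- reg[l] + regularizer(fw$layers[[l]]$U, cfg$lambda1, cfg$lambda2)$loss
        rate[l] <- rate[l] + mean(state[[l]]$S)
      }
    }
  }
  list(loss = loss / n, reg_loss = reg / n, spike_rate = rate / n)
}

#' Per-layer classification on an input stream
#'
#' In the default `"readout"` mode each layer's readout values are
#' accumulated over the time steps after burn-in and the predicted class
#' is the argmax (ties broken toward the lowest class index). The
#' `"spikes"` mode instead counts the final layer's output spikes per
#' unit, which requires that layer to have exactly one unit per class.
#'
#' @inheritParams train_online
#' @param mode `"readout"` or `"spikes"`.
#' @return integer matrix `(B, n_layers)` of predicted class indices
#'   (`"spikes"` mode fills only the last column).
#' @export
evaluate_classification <- function(net, input, cfg, mode = c("readout", "spikes"),
                                    engine = c("cpp", "r")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  input <- canonical_input(net, input)
  T_steps <- dim(input)[1]
  B <- dim(input)[2]
  burn_steps <- round(cfg$burn_in / net$neuron$dt)
  if (T_steps <= burn_steps) abort("input stream is shorter than the burn-in period")
  n_layers <- length(net$layers)
  if (mode == "spikes" && net$layers[[n_layers]]$n_out != net$n_targets) {
    abort("`spikes` mode needs the last layer to have one unit per class")
  }
  if (engine == "cpp") {
    run <- run_engine(net, input, NULL, cfg, NULL, NULL, training = FALSE,
                      dropout_active = cfg$dropout_active_at_eval)
    pred <- matrix(NA_integer_, B, n_layers)
    if (mode == "readout") {
      for (l in seq_len(n_layers)) {
        pred[, l] <- max.col(run$accY[[l]], ties.method = "first")
      }
    } else {
      pred[, n_layers] <- max.col(run$accS, ties.method = "first")
    }
    return(pred)
  }
  state <- net_init_state(net, B)
  plans <- conv_plans(net, B)
  accY <- lapply(seq_len(n_layers), function(l) matrix(0, B, net$n_targets))
  accS <- matrix(0, B, net$layers[[n_layers]]$n_out)
  for (t in seq_len(T_steps)) {
    frame <- if (length(dim(input)) == 3L) {
      array(input[t, , ], c(B, dim(input)[3]))
    } else {
      array(input[t, , , , ], c(B, dim(input)[3:5]))
    }
    fw <- forward_step(net, state, frame, training = FALSE,
                       dropout_active = cfg$dropout_active_at_eval, plans = plans)
    state <- fw$state
    if (t > burn_steps) {
      for (l in seq_len(n_layers)) accY[[l]] <- accY[[l]] + fw$layers[[l]]$Y
      Sl <- state[[n_layers]]$S
      accS <- accS + (if (is.matrix(Sl)) Sl else map_to_mat(Sl))
    }
  }
  pred <- matrix(NA_integer_, B, n_layers)
  if (mode == "readout") {
    for (l in seq_len(n_layers)) pred[, l] <- max.col(accY[[l]], ties.method = "first")
  } else {
    pred[, n_layers] <- max.col(accS, ties.method = "first")
  }
  pred
}

#' Count the persistent scalar training state of a network
#'
#' Sums the number of scalar values in all trainable parameters, fixed
#' readout/feedback matrices, neuron state variables and optimizer
#' accumulators. This count is the entire memory footprint of training:
#' it does not depend on how many time steps have been simulated, because
#' the learning rule consumes only the current step's forward variables.
#'
#' @param net a [build_network()] result.
#' @param state a network state (from [net_init_state()] or a training
#'   run); optional.
#' @param opt per-layer optimizer states; optional.
#' @return integer number of persistent scalars.
#' @export
state_footprint <- function(net, state = NULL, opt = NULL) {
  n <- 0L
  for (lay in net$layers) {
    n <- n + length(lay$W) + length(lay$b) + length(lay$G) + length(lay$H)
  }
  if (!is.null(state)) {
    for (st in state) n <- n + sum(lengths(lapply(st, as.vector)))
  }
  if (!is.null(opt)) {
    for (o in opt) {
      n <- n + sum(lengths(o$m)) + sum(lengths(o$u)) + 1L
    }
  }
  n
}
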