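# Runnable experiments tying the modules together: the Poisson-input
# regression task, a gesture-like moving-bar classification task, YAML
# experiment configs, and checkpoint plumbing. Every constant that the
# method itself does not fix lives in the config with a documented default,
# so deviations are auditable in one place.

#' Default configuration for the regression experiment
#'
#' A three-layer fully connected network is driven by one fixed Poisson
#' spike train; layer 1 is trained to reproduce a ramp, layer 2 a
#' high-frequency sinusoid and layer 3 a low-frequency sinusoid through
#' its fixed random readout.
#'
#' The default schedule anneals the learning rate (halved every 100,000
#' updates, i.e. every ~222 passes) over 2,000 passes; a 50 ms burn-in per
#' pass lets the states equilibrate before updates and before the loss is
#' scored.
#'
#' @param n_hidden neurons per layer.
#' @param n_inputs Poisson input channels.
#' @param n_passes training passes over the fixed stimulus.
#' @param eta AdaMax learning rate.
#' @param seed master seed.
#' @return a named list (an experiment config).
#' @export
regression_config <- function(n_hidden = 64, n_inputs = 100, n_passes = 2000,
                              eta = 2e-3, seed = 1) {
  list(
    task = "regression",
    seed = seed,
    n_inputs = n_inputs,
    n_hidden = n_hidden,
    n_layers = 3,
    T_ms = 500,
    dt = 1,
    rate_min = 10,
    rate_max = 100,
    f_hi = 20,
    f_lo = 2,
    n_passes = n_passes,
    eta = eta,
    lambda1 = 0.02,
    lambda2 = 0.001,
    loss = "mse",
    burn_in = 50,
    schedule_divisor = 2,
    schedule_interval = 1e5,
    concordant = TRUE,
    tau_mem = 20, tau_syn = 5, tau_ref = 5, rho = 1
  )
}

#' Default configuration for the moving-bar classification experiment
#'
#' A small convolutional stack (conv + 2x2 max pool + dropout, twice) is
#' trained online on synthetic two-polarity moving-bar event streams; each
#' layer carries a local readout with one target unit per class, trained
#' against a constant one-hot pseudo-target. The `eval_dropout` and
#' `eval_untrained` fields control whether the extra evaluation passes
#' (dropout kept active at eval; untrained chance level) are run.
#'
#' @param n_classes number of bar-motion classes (up to 8).
#' @param n_train,n_test sequences per class for training / testing.
#' @param n_epochs training passes over the training batch.
#' @param eta AdaMax learning rate.
#' @param seed master seed.
#' @return a named list (an experiment config).
#' @export
classification_config <- function(n_classes = 4, n_train = 16, n_test = 25,
                                  n_epochs = 60, eta = 1e-3, seed = 1) {
  list(
    task = "classification",
    seed = seed,
    n_classes = n_classes,
    width = 16, height = 16,
    duration = 300,
    dt = 1,
    bar_width = 2,
    speed = 1,
    jitter = 0.5,
    noise_rate = 2,
    n_train = n_train,
    n_test = n_test,
    filters = c(16, 32),
    kernels = c(5, 3),
    paddings = c(2, 1),
    pools = c(2, 2),
    dropout = 0.5,
    n_epochs = n_epochs,
    eta = eta,
    lambda1 = 0.02,
    lambda2 = 0.001,
    loss = "smooth_l1",
    burn_in = 50,
    target_amplitude = 1,
    schedule_divisor = 2,
    schedule_interval = 15000,
    eval_dropout = TRUE,
    eval_untrained = TRUE,
    concordant = TRUE,
    tau_mem = 20, tau_syn = 5, tau_ref = 5, rho = 1
  )
}

neuron_from_config <- function(config) {
  neuron_config(
    tau_mem = config$tau_mem, tau_syn = config$tau_syn,
    tau_ref = config$tau_ref, dt = config$dt, rho = config$rho
  )
}

#' Read / write experiment configurations as YAML
#'
#' Configs round-trip losslessly; unknown keys in a file are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param config an experiment config list.
#' @param path file path.
#' @return `read_experiment_config` returns the config list.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  config <- yaml::read_yaml(path)
  if (is.null(config$task)) abort("config file has no `task` field")
  template <- switch(config$task,
    regression = regression_config(),
    classification = classification_config(),
    abort(sprintf("unknown task `%s`", config$task))
  )
  unknown <- setdiff(names(config), names(template))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  merged <- template
  merged[names(config)] <- config
  if (is.character(merged$schedule_interval)) {
    merged$schedule_interval <- as.numeric(merged$schedule_interval)
  }
  merged
}

#' Run the Poisson-input regression experiment
#'
#' Builds the fully connected network, generates the fixed Poisson
#' stimulus and the three pseudo-target traces, measures the initial
#' per-layer readout loss (a forward pass with no updates), trains online
#' for `n_passes` passes (states reset between passes), and measures the
#' final loss the same way.
#'
#' @param config from [regression_config()] (or a YAML file via
#'   [read_experiment_config()]).
#' @param out_dir optional directory; when given, metrics (CSV), a
#'   checkpoint and the fully resolved config (YAML) are written there.
#' @return list with the trained `net`, `initial_loss` and `final_loss`
#'   per layer, `reduction` factors, the per-pass `trace` and the inputs
#'   used.
#' @export
run_regression <- function(config = regression_config(), out_dir = NULL) {
  stopifnot(identical(config$task, "regression"))
  T_steps <- round(config$T_ms / config$dt)
  rates <- with_seed(
    derive_seed(config$seed, 101L),
    stats::runif(config$n_inputs, config$rate_min, config$rate_max)
  )
  input <- poisson_spike_train(rates, T_steps, config$dt, derive_seed(config$seed, 102L))
  targets_mat <- regression_targets(T_steps, config$dt, config$f_hi, config$f_lo)
  targets <- lapply(seq_len(config$n_layers), function(l) {
    targets_mat[, min(l, ncol(targets_mat)), drop = FALSE]
  })
  spec <- network_spec(
    input_shape = config$n_inputs,
    layers = replicate(config$n_layers, layer_dense(config$n_hidden), simplify = FALSE),
    n_targets = 1,
    neuron = neuron_from_config(config)
  )
  net <- build_network(spec, derive_seed(config$seed, 103L), concordant = config$concordant)
  cfg <- train_config(
    eta = config$eta, burn_in = config$burn_in,
    lambda1 = config$lambda1, lambda2 = config$lambda2, loss = config$loss,
    schedule_divisor = config$schedule_divisor,
    schedule_interval = config$schedule_interval
  )
  input_arr <- array(input, c(T_steps, 1L, config$n_inputs))
  initial <- evaluate_loss(net, input_arr, targets, cfg)
  trace <- matrix(NA_real_, config$n_passes, config$n_layers)
  opt <- NULL
  if (config$n_passes > 0) {
    for (pass in seq_len(config$n_passes)) {
      run <- train_online(net, input_arr, targets, cfg, opt = opt)
      net <- run$net
      opt <- run$opt
      if (nrow(run$metrics)) {
        last <- run$metrics[run$metrics$step == max(run$metrics$step), ]
        trace[pass, ] <- last$loss[order(last$layer)]
      }
    }
  }
  final <- evaluate_loss(net, input_arr, targets, cfg)
  res <- list(
    net = net, opt = opt,
    initial_loss = initial$loss, final_loss = final$loss,
    reduction = initial$loss / final$loss,
    spike_rate = final$spike_rate,
    trace = trace, input = input, targets = targets_mat, config = config
  )
  if (!is.null(out_dir)) write_experiment_outputs(res, out_dir, trace_df = data.frame(
    pass = rep(seq_len(nrow(trace)), times = ncol(trace)),
    layer = rep(seq_len(ncol(trace)), each = nrow(trace)),
    loss = as.vector(trace)
  ))
  res
}

# Generate the full moving-bar dataset for one split.
make_bar_dataset <- function(config, n_per_class, seed_base) {
  tensors <- list()
  labels <- integer(0)
  i <- 0L
  for (cls in seq_len(config$n_classes)) {
    for (rep_i in seq_len(n_per_class)) {
      i <- i + 1L
      ev <- moving_bar_events(
        class_id = cls, width = config$width, height = config$height,
        duration = config$duration, dt = config$dt, speed = config$speed,
        bar_width = config$bar_width, jitter = config$jitter,
        noise_rate = config$noise_rate,
        seed = derive_seed(seed_base, i)
      )
      tensors[[i]] <- bin_events(ev, bin_ms = config$dt)
      labels[i] <- cls
    }
  }
  list(input = frames_to_batch(tensors), labels = labels)
}

#' Run the moving-bar classification experiment
#'
#' Generates train/test event streams for each class, bins them into
#' two-polarity frame tensors, trains the convolutional stack online
#' (per-time-step updates after the burn-in, one-hot pseudo-targets on
#' every layer's readout), and reports per-layer test error with dropout
#' off and kept active at evaluation.
#'
#' @inheritParams run_regression
#' @param config from [classification_config()].
#' @return list with the trained `net`, per-layer `accuracy` (dropout off)
#'   and `accuracy_dropout` (dropout kept active at eval), chance-level
#'   `accuracy_untrained`, training `metrics` and the test labels and
#'   predictions.
#' @export
run_classification <- function(config = classification_config(), out_dir = NULL) {
  stopifnot(identical(config$task, "classification"))
  train_set <- make_bar_dataset(config, config$n_train, derive_seed(config$seed, 201L))
  test_set <- make_bar_dataset(config, config$n_test, derive_seed(config$seed, 202L))
  spec <- network_spec(
    input_shape = c(2L, config$height, config$width),
    layers = lapply(seq_along(config$filters), function(l) {
      layer_conv(config$filters[l], config$kernels[l],
        padding = config$paddings[l], pool = config$pools[l],
        dropout = config$dropout
      )
    }),
    n_targets = config$n_classes,
    neuron = neuron_from_config(config)
  )
  net <- build_network(spec, derive_seed(config$seed, 203L), concordant = config$concordant)
  cfg <- train_config(
    eta = config$eta, burn_in = config$burn_in,
    lambda1 = config$lambda1, lambda2 = config$lambda2, loss = config$loss,
    schedule_divisor = config$schedule_divisor,
    schedule_interval = config$schedule_interval
  )
  T_steps <- dim(train_set$input)[1]
  onehot <- matrix(0, length(train_set$labels), config$n_classes)
  onehot[cbind(seq_along(train_set$labels), train_set$labels)] <- config$target_amplitude
  targets <- array(0, c(T_steps, nrow(onehot), config$n_classes))
  for (t in seq_len(T_steps)) targets[t, , ] <- onehot
  target_list <- rep(list(targets), length(net$layers))

  pred_untrained <- if (isTRUE(config$eval_untrained)) {
    with_seed(
      derive_seed(config$seed, 204L),
      evaluate_classification(net, test_set$input, cfg)
    )
  }
  opt <- NULL
  metrics <- list()
  with_seed(derive_seed(config$seed, 205L), {
    for (epoch in seq_len(config$n_epochs)) {
      run <- train_online(net, train_set$input, target_list, cfg, opt = opt)
      net <- run$net
      opt <- run$opt
      m <- run$metrics
      m$epoch <- epoch
      metrics[[epoch]] <- m
    }
  })
  pred <- with_seed(
    derive_seed(config$seed, 206L),
    evaluate_classification(net, test_set$input, cfg)
  )
  pred_drop <- if (isTRUE(config$eval_dropout)) {
    cfg_drop <- cfg
    cfg_drop$dropout_active_at_eval <- TRUE
    with_seed(
      derive_seed(config$seed, 207L),
      evaluate_classification(net, test_set$input, cfg_drop)
    )
  }
  acc <- function(p) if (is.null(p)) NULL else colMeans(p == test_set$labels)
  res <- list(
    net = net, opt = opt,
    accuracy = acc(pred),
    accuracy_dropout = acc(pred_drop),
    accuracy_untrained = acc(pred_untrained),
    predictions = pred, labels = test_set$labels,
    metrics = do.call(rbind, metrics), config = config
  )
  if (!is.null(out_dir)) {
    write_experiment_outputs(res, out_dir, trace_df = res$metrics)
  }
  res
}

write_experiment_outputs <- function(res, out_dir, trace_df) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trace_df, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write_experiment_config(res$config, file.path(out_dir, "config.yaml"))
  save_checkpoint(res$net, file.path(out_dir, "checkpoint.rds"), opt = res$opt,
                  config = res$config)
  invisible(out_dir)
}

#' Save / load / inspect a network checkpoint
#'
#' A checkpoint bundles all trainable weights and biases, the fixed
#' readout and feedback matrices, the optimizer accumulators and the
#' resolved experiment config into a single archive; loading restores
#' bit-identical tensors.
#'
#' @param net a [build_network()] result.
#' @param path file path (`.rds`).
#' @param opt optional per-layer optimizer states.
#' @param config optional experiment config to embed.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `net`, `opt` and `config`.
#' @export
save_checkpoint <- function(net, path, opt = NULL, config = NULL) {
  saveRDS(list(net = net, opt = opt, config = config,
               package_version = as.character(utils::packageVersion("decolle"))), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort(sprintf("checkpoint `%s` does not exist", path))
  ck <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("`%s` is not a readable checkpoint: %s", path, conditionMessage(e)))
  })
  if (!is.list(ck) || is.null(ck$net) || !inherits(ck$net, "decolle_network")) {
    abort(sprintf("`%s` is not a network checkpoint", path))
  }
  ck
}

#' Count the trainable and fixed parameters of a network
#'
#' @param net a [build_network()] result.
#' @return list with `trainable` (weights + biases) and `fixed` (readout +
#'   feedback) scalar counts.
#' @export
parameter_count <- function(net) {
  trainable <- sum(vapply(net$layers, function(l) length(l$W) + length(l$b), numeric(1)))
  fixed <- sum(vapply(net$layers, function(l) length(l$G) + length(l$H), numeric(1)))
  list(trainable = trainable, fixed = fixed)
}

#' @rdname save_checkpoint
#' @param quiet suppress printing (summary is still returned).
#' @export
inspect_checkpoint <- function(path, quiet = FALSE) {
  ck <- load_checkpoint(path)
  net <- ck$net
  pc <- parameter_count(net)
  lines <- c(
    sprintf("Checkpoint: %s", path),
    sprintf("Layers: %d | readout targets per layer: %d", length(net$layers), net$n_targets),
    sprintf("Trainable parameters: %d | fixed readout/feedback parameters: %d",
            pc$trainable, pc$fixed)
  )
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    wsum <- sprintf("W: mean %.4g sd %.4g | b: mean %.4g", mean(lay$W), stats::sd(lay$W),
                    mean(lay$b))
    if (lay$kind == "conv") {
      lines <- c(lines, sprintf(
        "  [%d] conv %dx%d x%d (%s -> %s) %s", l, lay$kernel, lay$kernel, lay$filters,
        paste(lay$in_shape, collapse = "x"), paste(lay$out_shape, collapse = "x"), wsum
      ))
      # first-layer kernel summary supports visual inspection of learned
      # filters per polarity channel
      if (l == 1L) {
        K <- kernel_matrix_to_array(lay$W, lay$in_shape[1], lay$kernel)
        for (chn in seq_len(dim(K)[2])) {
          lines <- c(lines, sprintf(
            "      channel %d kernels: |mean| %.4g, max |w| %.4g",
            chn, mean(abs(apply(K[, chn, , , drop = FALSE], 1, mean))), max(abs(K[, chn, , ]))
          ))
        }
      }
    } else {
      lines <- c(lines, sprintf(
        "  [%d] dense %d -> %d %s", l, lay$n_in, lay$n_out, wsum
      ))
    }
  }
  if (!quiet) cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
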