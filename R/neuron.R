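# Discrete-time current-based leaky integrate-and-fire neurons with synaptic
# traces and a relative refractory mechanism.
#
# Per simulation step of width dt the layer state advances as
#
#   P[t+dt] = alpha * P[t] + (1 - alpha) * Q[t]
#   Q[t+dt] = beta  * Q[t] + (1 - beta)  * S_in[t]
#   U       = W %*% P[t+dt] - rho * R[t] + b
#   S       = step(U)                       (step(0) = 1)
#   R[t+dt] = gamma * R[t] + (1 - gamma) * S
#
# with alpha = exp(-dt/tau_mem), beta = exp(-dt/tau_syn),
# gamma = exp(-dt/tau_ref). P and Q are indexed by presynaptic unit (one
# trace per input channel, not per synapse), which is what makes the state
# linear in the number of neurons. The membrane potential is equivalently the
# discretisation of the two-compartment (V, I) dynamics: V = W %*% P holds
# exactly by linearity.

#' Exponential decay factor for a leaky state variable
#'
#' @param tau time constant in ms (> 0).
#' @param dt simulation step in ms (> 0).
#' @return `exp(-dt/tau)`, strictly in (0, 1).
#' @examples
#' decay_constant(20, 1) # membrane decay over a 1 ms step
#' @export
decay_constant <- function(tau, dt) {
  check_scalar_number(tau, "tau", positive = TRUE)
  check_scalar_number(dt, "dt", positive = TRUE)
  exp(-dt / tau)
}

#' Neuron model configuration
#'
#' Bundles the time constants of the membrane, synapse and refractory
#' dynamics with the simulation step and the refractory coupling weight, and
#' precomputes the per-step decay factors.
#'
#' @param tau_mem membrane time constant, ms.
#' @param tau_syn synaptic-current time constant, ms.
#' @param tau_ref refractory time constant, ms.
#' @param dt simulation time step, ms.
#' @param rho refractory self-inhibition weight (>= 0); after each spike the
#'   membrane is depressed by `rho * R`.
#' @return an object of class `decolle_neuron_config` with fields
#'   `tau_mem`, `tau_syn`, `tau_ref`, `dt`, `rho` and derived decay factors
#'   `alpha`, `beta`, `gamma`.
#' @examples
#' cfg <- neuron_config()
#' cfg$alpha # exp(-1/20)
#' @export
neuron_config <- function(tau_mem = 20, tau_syn = 5, tau_ref = 5, dt = 1, rho = 1) {
  check_scalar_number(rho, "rho", nonneg = TRUE)
  cfg <- list(
    tau_mem = tau_mem, tau_syn = tau_syn, tau_ref = tau_ref,
    dt = dt, rho = rho,
    alpha = decay_constant(tau_mem, dt),
    beta = decay_constant(tau_syn, dt),
    gamma = decay_constant(tau_ref, dt)
  )
  structure(cfg, class = "decolle_neuron_config")
}

#' @export
print.decolle_neuron_config <- function(x, ...) {
  cat(sprintf(
    "Neuron config: tau_mem=%g ms, tau_syn=%g ms, tau_ref=%g ms, dt=%g ms, rho=%g\n",
    x$tau_mem, x$tau_syn, x$tau_ref, x$dt, x$rho
  ))
  cat(sprintf("  decay factors: alpha=%.6f beta=%.6f gamma=%.6f\n", x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Initialise the state of one spiking layer
#'
#' All traces, membrane potentials and spikes start at zero (rest).
#'
#' @param batch_size number of batch elements (>= 1).
#' @param n_inputs number of presynaptic channels (>= 1).
#' @param n_neurons number of neurons in the layer (>= 1).
#' @return an object of class `decolle_layer_state`: a list with matrices
#'   `P`, `Q` of shape `(batch_size, n_inputs)` and `R`, `U`, `S` of shape
#'   `(batch_size, n_neurons)`.
#' @export
init_state <- function(batch_size, n_inputs, n_neurons) {
  batch_size <- check_count(batch_size, "batch_size")
  n_inputs <- check_count(n_inputs, "n_inputs")
  n_neurons <- check_count(n_neurons, "n_neurons")
  structure(list(
    P = matrix(0, batch_size, n_inputs),
    Q = matrix(0, batch_size, n_inputs),
    R = matrix(0, batch_size, n_neurons),
    U = matrix(0, batch_size, n_neurons),
    S = matrix(0, batch_size, n_neurons)
  ), class = "decolle_layer_state")
}

#' Advance the presynaptic traces by one time step
#'
#' The membrane trace P is updated from the pre-update synaptic trace Q, and
#' Q is then updated from the incoming spikes, matching the discrete-time
#' index pattern of the neuron model (states at t+dt depend on states at t).
#'
#' @param P membrane trace (batch x n_inputs, or vector).
#' @param Q synaptic trace, same shape as `P`.
#' @param S_in incoming spikes, same shape, non-negative (binary for spike
#'   trains; binned event counts may exceed 1).
#' @param alpha,beta decay factors in (0, 1).
#' @return list with updated `P` and `Q`.
#' @export
update_traces <- function(P, Q, S_in, alpha, beta) {
  check_same_shape(P, Q, "P", "Q")
  check_same_shape(P, S_in, "P", "S_in")
  if (any(S_in < 0)) abort("`S_in` must be non-negative")
  list(
    P = alpha * P + (1 - alpha) * Q,
    Q = beta * Q + (1 - beta) * S_in
  )
}

#' Membrane potential and spike emission
#'
#' `U = P %*% t(W) - rho * R + b`; a spike is emitted where the membrane
#' reaches the threshold at zero: `S = step(U)` with `step(0) = 1`.
#' Excitability is controlled by the bias `b`, not by a movable threshold.
#'
#' @param P membrane traces (batch x n_inputs, or vector of length n_inputs).
#' @param R refractory state (batch x n_neurons).
#' @param W weight matrix (n_neurons x n_inputs).
#' @param b bias vector (length n_neurons).
#' @param rho refractory coupling weight.
#' @return list with membrane potential `U` and binary spikes `S`, both
#'   (batch x n_neurons).
#' @export
membrane_and_spike <- function(P, R, W, b, rho) {
  P <- as_batch(P)
  R <- as_batch(R)
  if (!is.matrix(W)) W <- matrix(W, nrow = length(b))
  if (ncol(P) != ncol(W)) abort("`P` length must equal ncol(W)")
  if (ncol(R) != nrow(W)) abort("`R` length must equal nrow(W)")
  if (length(b) != nrow(W)) abort("`b` length must equal nrow(W)")
  U <- P %*% t(W) - rho * R + matrix(b, nrow(P), length(b), byrow = TRUE)
  list(U = U, S = spike_threshold(U))
}

# Heaviside step with step(0) = 1, applied elementwise.
spike_threshold <- function(U) {
  S <- U
  S[] <- as.numeric(U >= 0)
  S
}

#' Advance the refractory state by one time step
#'
#' @param R refractory state.
#' @param S spikes just emitted (binary, same shape).
#' @param gamma refractory decay factor in (0, 1).
#' @return updated refractory state `gamma * R + (1 - gamma) * S`.
#' @export
update_refractory <- function(R, S, gamma) {
  check_same_shape(R, S, "R", "S")
  check_binary(S, "S")
  gamma * R + (1 - gamma) * S
}

#' One full update of a spiking layer
#'
#' Applies, in order: the trace update (P from the pre-update Q, Q from the
#' input spikes), the membrane/spike computation on the new P and the old R,
#' and the refractory update with the new spikes. Purely functional: the
#' returned state fully replaces the old one and no history is retained.
#'
#' @param state a `decolle_layer_state`.
#' @param S_in input spikes (batch x n_inputs).
#' @param W weights (n_neurons x n_inputs).
#' @param b biases (length n_neurons).
#' @param config a [neuron_config()].
#' @return list with the updated `state` and the emitted spikes `S_out`.
#' @export
step_layer <- function(state, S_in, W, b, config) {
  S_in <- as_batch(S_in)
  tr <- update_traces(state$P, state$Q, S_in, config$alpha, config$beta)
  ms <- membrane_and_spike(tr$P, state$R, W, b, config$rho)
  Rn <- update_refractory(state$R, ms$S, config$gamma)
  state$P <- tr$P
  state$Q <- tr$Q
  state$R <- Rn
  state$U <- ms$U
  state$S <- ms$S
  list(state = state, S_out = ms$S)
}
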