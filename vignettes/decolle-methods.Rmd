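---
title: "Online local learning for deep spiking networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online local learning for deep spiking networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decolle)
```

## The problem

Training deep spiking neural networks with exact gradient methods
(backpropagation through time) requires storing the activation history of the
whole sequence, which grows linearly with sequence length and quickly
dominates memory at millisecond resolution. Deep continuous local learning
(DECOLLE) avoids this entirely: every layer carries its own fixed random
readout and its own loss, the gradient is taken only within the current time
step and the current layer, and the variables the update needs (presynaptic
traces, membrane potential) are exactly the ones the forward dynamics already
maintains. Training therefore has no memory overhead at all, and the update
is a biologically interpretable three-factor rule.

## Neuron model

Neurons are current-based leaky integrate-and-fire units with a relative
refractory mechanism, simulated in discrete time (step `dt`, default 1 ms).
Writing `alpha = exp(-dt/tau_mem)`, `beta = exp(-dt/tau_syn)`,
`gamma = exp(-dt/tau_ref)`, one step of layer `l` is

    P[t+dt] = alpha P[t] + (1 - alpha) Q[t]
    Q[t+dt] = beta  Q[t] + (1 - beta)  S_in[t]
    U       = W P[t+dt] - rho R[t] + b
    S       = step(U)                       (step(0) = 1)
    R[t+dt] = gamma R[t] + (1 - gamma) S

`P` and `Q` are the membrane and synaptic traces of each *input channel* —
one pair per presynaptic unit, not per synapse, which is what makes the state
linear in the number of neurons. The membrane is equivalently the
discretisation of a two-compartment `(V, I)` model with `V = W P` holding
exactly by linearity; the test suite asserts this equivalence numerically
over 1,000 random-input steps at 1e-9 relative tolerance.

Update order within a step follows the discrete index pattern above: traces
advance first (`P` from the pre-update `Q`), the membrane and spike are
computed from the new `P` and the old `R`, and the refractory state then
integrates the new spike. The threshold is fixed at zero; excitability is
carried by the bias `b`, initialised at -0.01 so resting neurons sit just
below threshold and inside the plasticity window. Binary spike trains keep
all traces in `[0, 1]`; binned event counts above 1 are accepted as inputs,
in which case the input traces may exceed 1.

Defaults (`tau_mem` 20 ms, `tau_syn` 5 ms, `tau_ref` 5 ms, `rho` 1) are
standard cortical-modelling conventions; all are configurable in
`neuron_config()`.

## The learning rule

Each layer's spikes are read out through a fixed random matrix `G`
(uniform on ±1/sqrt(n_units)): `Y = G S`, instantaneous, with no temporal
state. The layer loss `L(Y, Yhat)` (squared error, or a smooth L1 with unit
transition point) is defined per time step. Since the spike function has no
useful derivative, the update uses a surrogate: the derivative of the hard
sigmoid `clip(U + 0.5, 0, 1)`, i.e. a boxcar gate `1{-0.5 <= U <= 0.5}`.
The resulting update for weight `W[i, j]` is the product of three factors,

    dW[i,j] = -eta * error[i] * boxcar(U[i]) * P[j]
    error[i] = sum_k H[i,k] dL/dY[k]

a modulatory error term, a postsynaptic gate, and a presynaptic trace. With
`H = t(G)` this is exactly the surrogate gradient of the local loss
restricted to the current time step; the test suite certifies the chain rule
against central finite differences of the relaxed (hard-sigmoid) loss on
random instances, at relative error below 1e-5 away from the kinks. The
dependence of `U` on past weights through the refractory term is dropped, as
the rule intends: regularisation keeps firing rates in the regime where that
term is negligible.

By default `H` is instead *sign-concordant* noisy feedback: `t(G)` multiplied
elementwise by `max(omega, 0)` with `omega ~ N(1, 0.5)`. Feedback then shares
the sign of the readout weights without being numerically symmetric (zeros
allowed), emulating hardware in which forward and backward connections are
programmed with the same sign but mismatched gains. Both modes are exposed;
`concordant = FALSE` recovers the exact transpose. The mean and variance of
`omega` are configurable because different mismatch models are plausible;
the rectified-Gaussian default keeps roughly 92% of feedback entries
nonzero.

Because no error crosses a layer boundary (spikes are passed forward as
values only), each layer's update is a pure function of that layer's state at
the current time step. The suite asserts this both ways: zeroing another
layer's weights leaves a layer's update bit-identical, and the persistent
scalar state of the trainer is independent of sequence length.

### Regularizers

Two membrane penalties per layer keep firing useful:
`lambda1 * mean_i(relu(U_i + 0.01))` discourages sustained supra-threshold
membranes (low firing rates, and membranes kept near the plasticity window),
and `lambda2 * relu(0.1 - mean_i(U_i))` prevents a layer from falling silent.
Their gradient is taken with respect to `U` directly and is *not* gated by
the boxcar — `U` is linear in the weights, so this term needs no surrogate.
Each layer applies its own penalty. Both shipped studies default to
`lambda1 = 0.02` and `lambda2 = 0.001`. The upper penalty does most of the
work: units whose membranes drift far below the plasticity window receive
no task gradient at all, and only the (weak, layer-mean-gated) lower
penalty can revive them, so a moderate `lambda1` that keeps membranes near
the window is worth more than aggressive rate suppression.

### Optimizer

AdaMax with `beta1 = 0`, `beta2 = 0.95`: the first moment is the raw
gradient and the denominator is a slowly decaying running infinity norm, so
each step is close to `eta * sign(gradient)` coordinate-wise. An update is
applied to every layer at every simulation time step after the burn-in.
Because the per-step error of an instantaneous spike readout is noisy,
sign-like steps random-walk around the solution unless the rate decays:
both studies therefore halve the learning rate on a fixed update schedule
(every 1e5 updates for the regression study, every 1.5e4 for the
classification study). At GPU scale this optimizer is typically paired
with learning rates as small as 1e-9 over hundreds of thousands of
iterations on large batches; at the desk scale of this package's synthetic
tasks, rates of 1e-3 to 2e-3 with tens to hundreds of thousands of updates
are the equivalent regime, and the defaults are set accordingly per
experiment.

## Architectures

Dense and convolutional spiking layers can be stacked (convolutions first).
Convolutional layers use square kernels with stride 1 and explicit zero
padding, optional non-overlapping 2x2 max pooling applied to the membrane
map *before* thresholding (order: convolution → pooling → spiking
nonlinearity → dropout), and inverted dropout on the spike output feeding
both the next layer and the local readout. The surrogate gradient routes
through the pooling argmax, and the kernel gradient is literally the dense
three-factor rule applied to the unrolled patch matrix of the input traces —
an equivalence the tests assert by explicit patch enumeration.

With a 32x32 two-polarity input, three 7x7 convolutions with padding 2 and
pooling after layers 1 and 3 reproduce the event-vision feature-map
chain 30x30 → 15x15 → 13x13 → 11x11 → 5x5 used for gesture recognition; the
padding needed to obtain those sizes is not unique from the sizes alone, so the builder
exposes padding per layer and the tests pin this preset.

## Synthetic tasks

The package generates all of its own data; passing its tests therefore shows
that the learning rule and dynamics are implemented correctly and that the
training loop can fit structured synthetic spatiotemporal data — it does not
show performance on real event-camera recordings, which have richer noise
statistics, sensor biases and class overlap than these generators emulate.

**Regression.** A fixed 500 ms Poisson spike train (100 input channels,
rates drawn once uniformly from 10–100 Hz — per-bin Bernoulli at 1 ms, the
standard approximation at that resolution) drives a three-layer dense
network. Layer 1 is trained to reproduce a unit ramp through its readout,
layer 2 a 20 Hz sinusoid, layer 3 a 2 Hz sinusoid, all scaled to `[0, 1]`.
The sinusoid frequencies are package choices (one fast component with 10
periods and one slow component with exactly one period inside the 500 ms
window). The quantity reported is the per-layer readout loss on the training
stimulus before and after training, evaluated with updates disabled.

**Classification.** A bright bar sweeps across a 16x16 two-polarity sensor
(ON events at the leading edge, OFF at the trailing edge, wrap-around, with
0.5 ms timestamp jitter and 2 noise events per ms), in four directions for
the four-class default; classes 5–8 double the speed. Streams are binned at
1 ms into `(300, 2, 16, 16)` count tensors. A two-layer convolutional stack
(16 then 32 filters, 5x5/3x3 kernels, 2x2 pooling, dropout 0.5) is trained
online with a constant one-hot pseudo-target on every layer's readout and a
50 ms burn-in, giving 250 updates per 300 ms sequence pass. Feature
capacity matters more than anything else on this task: halving the filter
counts costs tens of accuracy points, while the first layer's local readout
stays near chance regardless (its features are class-relevant but its
random readout cannot separate them — the same depth effect the local-loss
literature reports). Evaluation
accumulates each layer's readout after the burn-in and takes the argmax
(ties resolve to the lowest class index); a spike-count mode is also
provided for networks whose last layer has one unit per class, since
"counting spikes at the output" is ambiguous between the two when the
readout units themselves do not spike. Test error is reported with dropout both off and kept active at
evaluation.

## Numerical and design choices

- `step(0) = 1`, boxcar boundaries inclusive, exactly as the definitions
  state; no stochasticity anywhere in the forward pass.
- Trace input gains are `(1 - decay)`, bounding traces by 1 for binary
  input; unit-jump kernels are not used.
- Batched gradients are averaged (not summed) over the batch so `eta` keeps
  its meaning across batch sizes; AdaMax has a 1e-8 denominator guard.
- Dropout masks are drawn fresh each time step; the readout sees the masked,
  rescaled spikes during training, and the backprojected error is passed
  through the same mask, keeping the update the exact within-step surrogate
  gradient of what the readout actually saw.
- States are zeroed between sequences (the burn-in re-equilibrates them);
  whether to carry state across sequence boundaries is an open choice and
  resetting is the reproducible one.
- Pooling truncates odd trailing rows/columns; argmax ties break in a fixed
  window order.
- All randomness derives from one master seed through a deterministic
  sub-seed hash, so any run is bit-reproducible from its resolved
  configuration file, and readout/feedback matrices are bit-identical before
  and after training (asserted).

## Problem sizes

The shipped experiment defaults are desk-scale: 3x64 neurons and 2,000
passes (900,000 updates) for the regression study; a 16x16 sensor, 64
training and 100 held-out sequences, and 60 epochs (15,000 updates) for
the classification study. These sizes were chosen so each study completes
in a few minutes on one CPU core while leaving the learning behaviour
qualitatively intact; the test suite runs the same studies with the same
thresholds but fewer training passes where that keeps the suite fast, and
everything scales up through configuration alone.

## What the studies do and do not achieve

At these scales the ramp and the 2 Hz target reach loss reductions well
above tenfold, and the deepest local readout of the classification stack
reaches high held-out accuracy. Two behaviours are characteristic rather
than incidental, and worth knowing about:

- the 20 Hz regression layer learns the target's *mean* quickly but its
  *phase* only very slowly: an instantaneous readout of binary spikes must
  place threshold crossings at 20 Hz against readout flicker of comparable
  magnitude, while the 20 ms / 5 ms membrane and synapse filters attenuate
  the fast component of the drive several-fold. Its loss reduction
  saturates far below the slow layers' across every learning-rate,
  regularizer and schedule regime we explored, at 64 and at 256 neurons
  per layer.
- the first convolutional layer's local readout hovers near chance even
  when deeper readouts classify well; class-independent offsets in its
  accumulated readout dominate its (real, weak) class-conditional signal.

## Known limitations

- Readouts are non-spiking linear projections; spiking readouts would add
  temporal credit assignment that this rule deliberately avoids.
- No recurrent (lateral) connectivity, axonal delays, or adaptive
  thresholds; stride is fixed at 1 and pooling at 2x2.
- The gesture-like moving-bar task is an explicit stand-in for event-camera
  gesture data, not a reproduction of any recorded benchmark; accuracies
  reported for real event-camera gesture benchmarks are out of this
  package's desk-scale scope.
- Local learning forgoes cross-layer feature coordination by design; deeper
  layers improve on shallower ones only through the statistics of their
  inputs, and this tendency is statistical, not guaranteed per seed.
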