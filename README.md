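# decolle

Online local learning for deep spiking neural networks in R.

Deep spiking networks are usually trained with backpropagation through time,
which needs the entire activation history of a sequence and therefore memory
that grows with sequence length — prohibitive at millisecond resolution, and
incompatible with the locality constraints of neuromorphic hardware and
biology. This package implements *deep continuous local learning* (DECOLLE):
every spiking layer carries a fixed random readout `Y = G S` and its own loss
against a pseudo-target, and each weight is updated online, at every
simulation time step, by a three-factor rule

```
dW[i,j] = -eta * error_i * boxcar(U_i) * P_j
error_i = sum_k H[i,k] dL/dY_k
```

— a modulatory error backprojected through fixed feedback `H` (the exact
transpose of `G`, or sign-concordant rectified-Gaussian noise on it), a
postsynaptic gate on the membrane potential `U` (the boxcar surrogate
derivative of the spike threshold), and the presynaptic trace `P`. All three
factors are available from the forward dynamics of the discrete-time leaky
integrate-and-fire neurons, so training carries **no memory overhead**: the
persistent state of the trainer is independent of sequence length (and the
test suite asserts exactly that).

The package is aimed at computational-neuroscience and neuromorphic-computing
work: it provides the neuron simulator (current-based LIF with synaptic
traces and relative refractoriness), dense and convolutional spiking layers
with max pooling and dropout, the local-learning rule with membrane-potential
regularizers and the AdaMax optimizer, generators for Poisson spike trains,
regression pseudo-targets and DVS-like moving-bar event streams, the standard
event preprocessing (1 ms binning, polarity channels, spatial summing, random
slicing), and a small CLI. A compiled (RcppArmadillo) engine mirrors the
pure-R reference implementation; the two are cross-checked numerically in the
tests.

## Worked example

Train a three-layer dense spiking network on a fixed 500 ms Poisson stimulus;
layer 1 learns to reproduce a ramp through its random readout, layer 2 a
20 Hz sinusoid, layer 3 a 2 Hz sinusoid:

```r
library(decolle)
res <- run_regression(regression_config(n_passes = 200, seed = 1))
round(res$initial_loss / res$final_loss, 2)
#> [1] 10.87  0.68  0.27
```

The three numbers are the factor by which each layer's readout loss dropped
from its untrained value (evaluated with updates disabled on the training
stimulus). A 200-pass run has only begun: the ramp layer is already past
tenfold while the sinusoid layers are still mid-flight at the initial
learning rate. The default configuration runs 2,000 passes with an annealed
learning rate, after which the ramp and the slow 2 Hz layer sit well above
tenfold while the 20 Hz layer saturates near threefold — an instantaneous
binary readout over 64 neurons tracks the mean of a fast sinusoid long
before it tracks its phase (see the methods vignette).

A gesture-like classification study — a bar sweeping in one of four
directions across a 16x16 two-polarity event sensor, binned at 1 ms — trains
a two-layer convolutional spiking stack online and reports per-layer test
accuracy:

```r
res <- run_classification(classification_config(n_epochs = 60, seed = 1))
res$accuracy           # per-layer accuracy, dropout off at eval
res$accuracy_untrained # chance level (~0.25) before training
```

Checkpoints, per-step metrics and the fully resolved configuration are
written next to the outputs when `out_dir` is given, and `exec/decolle`
exposes the same runs from a shell:

```sh
Rscript exec/decolle train-regression --seed 1 --out runs/reg
Rscript exec/decolle inspect --checkpoint runs/reg/checkpoint.rds
```

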