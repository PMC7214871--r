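---
title: "Streaming rollouts, ANN-to-SNN conversion, and the simulator: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming rollouts, ANN-to-SNN conversion, and the simulator: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamsnn)
```

This vignette records the model, the assumptions, and the design choices
behind `streamsnn`, in the spirit of a methods section: what is computed,
why it is computed that way, and what the defaults mean.

## The network graph and its streaming rollout

A network is a DAG of *layer* nodes (input, convolution, transition,
dense, classifier head); each edge carries an integer delay `d_ANN` in
rollout frames (1 throughout this package). A streaming rollout unrolls
the graph so that a node at rollout frame `k` reads its predecessors at
frame `k - d_ANN`: all layers update in parallel within a frame, exactly
as spiking neurons do on model-parallel hardware. Consequences, all
computed by `path_stats()` rather than assumed:

* latency of the first prediction = shortest input-output path `l_s`;
* receptive field `tau = l_max - l_s + 1` input frames;
* `K = N + l_s` rollout frames for `N` input frames, one output per input
  frame at frames `l_s + 1, ..., K`.

Output indexing was genuinely open: one convention would emit outputs at
frames `l_s, ..., K` (yielding `N + 1`), the other at `l_s + 1, ..., K`
(yielding `N`). We adopt the latter — the first input reaches the output
no earlier than after `l_s` edges of delay, so frame `l_s + 1` is the
first frame at which an input-dependent output exists, and the number of
outputs then equals the number of inputs.

The dependency cone of output `k` is computed from the *set of realized
path lengths* (a DP over the DAG), not from the interval
`[l_s, l_max]`: for dense blocks the two coincide, but for arbitrary
graphs an intermediate path length may not exist, and causality tests
(zeroing an input frame must change exactly the cone's outputs) hold only
for the realized-length definition.

When `N < tau`, the rollout keeps its `tau` input slots and the `N`
frames are placed at slots `round(i * tau / N)`; empty slots receive zero
frames. This is one admissible reading of "evenly distributed" — it is
deterministic, order-preserving, and reduces to the identity at
`N = tau`.

The DenseNet-style builder (`build_densenet_graph()`) uses dense
intra-block connectivity (every layer sees the block input and all
previous block layers), transitions with 3x3 convolutions (not 1x1) plus
2x2 average pooling, and a global-average-pool + fully-connected head fed
by the whole final block. The conventional depth `D = N_l * N_b + 1`
counts block layers plus the classifier; it is recorded as metadata
because it is *not* the longest-path length (transitions and the initial
convolution add edges but are conventionally not counted in `D`).

## Training the rollout

One parameter set exists per node and is shared across all rollout
frames; backpropagation through time accumulates all frames' gradients
into it. The loss is the weighted multi-output cross entropy
`L = sum_k -a_k log(y_k[class])` with `sum a_k = 1`; seven weighting
schemes are provided (`make_loss_weights()`), from `first-only` to
`last-only`. The normalisation keeps the effective learning rate
comparable across schemes. The log is clamped at `eps = 1e-12`.

Numerical/optimisation choices (there is no canonical setting for this
class of models, so these are package-level defaults):

* **Optimizer** Adam (`lr = 1e-3` default; the rectangles study uses
  `3e-3`), plain minibatch shuffling, best-epoch selection by validation
  accuracy of the final output, early stop at perfect validation
  accuracy.
* **Initialisation** He-scaled Gaussians, zero biases.
* **Weight decay** L2 on weights (default `1e-4`).
* **Activation decay** an L2 penalty on all hidden post-ReLU activations
  summed over rollout frames, encouraging the sparser activity that makes
  the converted SNN cheaper. Because the penalty sums over every unit,
  position and frame, its useful magnitude is tiny: on the order of
  `1e-6`. Strengths around `1e-4` make the regulariser dominate the
  cross entropy and collapse the network to dead ReLUs — an easy failure
  mode worth documenting.
* **Spatial dropout** per-channel masks, drawn once per sample and shared
  across rollout frames, training only; default 0.

All hidden activations are ReLU and all pooling is average pooling — the
assumptions under which the rate-coding conversion is exact in the limit;
max pooling and batch normalisation are deliberately excluded.
Transitions are defined as `ReLU(avgpool(conv(x)))` (pooling on
pre-activations), so conv + pool form a single linear map followed by one
ReLU and convert to a single layer of integrate-and-fire neurons; the
classifier head (`GAP` then linear) is likewise one linear readout.

## Conversion

`calibrate_percentiles()` computes, per node, the `p`-th percentile of
all activation values pooled over the calibration samples *and over all
rollout frames* (activations change over time in a rollout, so a single
frame would miscalibrate). Average-pooling transitions are calibrated
like any other node. Default `p = 99.9`, the robust choice from the
conversion literature: rescaling by the maximum is dominated by outliers,
while a high percentile lets a few neurons saturate in exchange for
faster information propagation. Percentiles use linear interpolation
between order statistics (`stats::quantile`, type 7), verified in the
tests against a hand-rolled sort-and-interpolate oracle.

`rescale_model()` multiplies the weights into node `l` by
`lambda_source / lambda_l` — branch-wise for concatenated (DenseNet)
inputs, each branch by its own source `lambda`, which is the only choice
consistent with concatenation — and biases by `1 / lambda_l`. With the
input divided by `lambda_input`, every activation becomes
`a_l / lambda_l` exactly, so the readout argmax is invariant. The readout
node itself keeps `lambda = 1`: it is a non-spiking accumulator, its
scores may be negative, and leaving it on the ANN scale changes no
prediction.

Biases are injected as a constant additive current every simulation step;
this preserves the linear rate mapping (a bias `b` adds `b` to the mean
drive per step, exactly its ANN role after rescaling).

## Simulation

Non-leaky integrate-and-fire neurons: add delayed weighted presynaptic
spikes plus bias current; spike once (at most) when `V >= V_th = 1`;
subtract `V_th`; clamp at `V_min = 0` (from the unit dynamic range of the
rescaled activations; configurable). The lower bound prevents long
silent recovery after sustained negative drive. Membrane potentials
persist across frame boundaries — with slowly changing inputs the stored
voltage is a good initialisation for the next frame and shortens
re-convergence. All delays are `d = n_sf * d_ANN` simulation steps, so
the spike wavefront traverses the graph exactly as the rollout
prescribes; `K` rollout frames take `T_tot = n_sf * K` steps.

Input encoding is deterministic: the first layer receives the analog
frame value (divided by `lambda_input`) as a constant current per step,
not a Poisson spike train. This matches the rate-mapping theory, avoids
sampling noise, and mirrors feeding averaged event frames to the ANN.

The prediction at step `t` is the argmax of the readout's weighted input
summed over the trailing `min(t, n_sf)` steps (one frame interval). Ties
break toward the lowest class index — fixed and documented because an
all-silent network must still emit a defined prediction. Whether bias
currents should saturate like spikes does not arise: biases enter the
membrane sum before thresholding like any other current.

## Operation accounting

ANN cost: multiply-adds, `k^2 C_in C_out H W` per convolution,
`F_in F_out` per dense layer, 4 per average-pooled unit, 1 per
global-average-pool input. The per-frame ledger skips nodes before their
warm-up (a node first computes at frame `1 +` its shortest distance from
the input); the cumulative cost at output `k` sums frames `1..k`. SNN
cost: one synaptic operation per spike per structural target synapse;
per-neuron fan-outs account exactly for image borders and pooled targets
(verified against per-synapse enumeration). Analog input injections and
bias currents are not spikes and are not counted; this choice is
conservative toward the ANN side of the comparison. The accuracy ratio
`rho` integrates both accuracy curves rectangularly on the per-step grid
from the first ANN output (`l_s * n_sf + 1`) to `K * n_sf` and takes
their ratio; `rho = 1` would require instantaneous rate convergence and
is unreachable in principle.

## What the synthetic data does and does not emulate

`gen_rectangles()` builds the minimal temporal-integration task: two
binary images, the second a horizontal shift of the first, class = shift
direction, expanded to six input frames (3 + 3). Defaults — 16x16 pixels,
rectangle edges 3–8 px, shift 2 px, balanced classes — are chosen so the
`N_l = 1` rollout model trains on one CPU in minutes; no canonical
geometry exists for this task, so these are documented stand-ins. The first image's position is drawn
from a range independent of the label, so no output that sees only the
first image can beat chance; on a bounded canvas the *second* image's
position distribution necessarily differs slightly between classes near
the borders (a translate of a bounded distribution cannot equal its
opposite translate), but no rollout output observes the second image
alone, so this residue is unobservable in the study design.

`gen_random_events()` produces homogeneous Poisson ON/OFF streams —
adequate for format, binning and counting properties, but without the
spatial structure, correlations, or polarity asymmetries of real sensors.
`gen_fixture_network()` yields small random ReLU chains with non-negative
biases for the conversion-fidelity harness. Problem sizes used by the
test suite and acceptance script (2000 training samples, 300–400 test
samples, 128–256 calibration/sweep samples, `n_sf` up to 50) are the
package's chosen desk-scale study conditions. Passing tests demonstrate
the mechanics and the qualitative phenomena (chance-level early outputs,
perfect late outputs, SNN lag of about one frame, sub-ANN operation
counts, `rho` saturation); they do not certify accuracy on real
event-camera benchmarks, which require external datasets and much larger
training budgets.

## Known limitations

* Purely feed-forward graphs with unit edge delays; recurrent edges and
  multi-delay temporal convolutions are not constructed.
* Non-leaky IF only; no refractory period, no leak, no spike-timing code.
* The simulator is time-stepped, not event-driven; cost scales with
  `n_sf * K` regardless of activity.
* Binary event dialects beyond the packed 40-bit layout need adapters.
* Training is CPU-bound R + one compiled kernel: adequate for the
  desk-scale studies here, not for large benchmarks.
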