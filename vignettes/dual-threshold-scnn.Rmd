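---
title: "Dual-threshold spiking convolutional networks: model, training and accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-threshold spiking convolutional networks: model, training and accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Spiking convolutional neural networks (SCNNs) communicate through binary
spike events, so on neuromorphic hardware most of their arithmetic reduces
to accumulate-only (ACC) operations. What makes them expensive on small
devices is volume: each convolutional layer keeps one real-valued membrane
potential (Vm) per output position and channel, and needs many output
channels — spiking feature maps, SFmaps — for accuracy. In practice many of
those SFmaps are near-duplicates of one another. A dual-threshold SCNN
(DT-SCNN) exploits that redundancy directly: each membrane map is compared
against *two* learned firing thresholds and emits two similar-but-distinct
binary maps, so half the membranes, half the convolutional kernels and half
the convolution operations produce the same number of SFmaps as a
conventional SCNN.

`dtscnn` implements the neuron model, the network forward pass, the
surrogate-gradient training algorithm (including learned thresholds and the
two-stage single-timestep strategy), the operation/weight/storage
accounting, and the feature-map similarity analysis that motivates the
design.

## Neuron model

A plain leaky integrate-and-fire (LIF) neuron updates as

$$v(t) = \lambda\, v(t-1)\,\bigl(1 - x(t-1)\bigr) + i(t), \qquad
  x(t) = \bigl[\, v(t) \ge V_{th} \,\bigr],$$

with leak factor $\lambda \in [0,1]$ and synaptic current
$i(t) = \sum_j w_j x_j(t)$ from the previous layer. The update order is
fixed and literal: (1) the previous step's spike annihilates the carried
membrane (hard reset to zero), (2) the leak scales what remains, (3) the
current is integrated, (4) the result is compared to the threshold with
`>=`. The membrane is *not* clamped; negative values are legal, because
clamping would change the recurrence.

The dual-threshold (DT-LIF) neuron keeps one membrane and two thresholds:

$$x_0(t) = [\,v(t) \ge V_{th0}\,], \qquad x_1(t) = [\,v(t) \ge V_{th1}\,],$$

and **only a pathway-0 spike resets the membrane**. We read that rule
literally even when training pushes $V_{th1}$ above $V_{th0}$ (both orders
occur in trained networks; `neuron_config()` deliberately imposes no
ordering). A neuron spiking only through pathway 1 therefore evolves
exactly like a threshold-free leaky integrator — a property the test suite
checks directly. With $V_{th1} = V_{th0}$ the model collapses to plain LIF,
which anchors the baseline-equivalence tests.

A dual-threshold convolutional (DTC) layer with $c_{out}/2$ membrane maps
emits the pathway-0 maps concatenated with the pathway-1 maps along the
channel dimension (pathway-0 block first), giving $c_{out}$ SFmaps from
half the state.

## Forward pass conventions

* **Direct encoding.** The real-valued image is presented to the first
  (coding) layer at every timestep; the coding layer has the same neuron
  dynamics as every other layer but consumes real inputs, hence
  multiply-accumulate (MAC) operations.
* **Convolutions** are same-padding, stride 1, odd kernels. This is the
  only convention under which the operation-count formula below reproduces
  the published per-network totals, which is why it is fixed rather than
  configurable.
* **Pooling** is average pooling over $s \times s$ windows with stride $s$
  (max pooling is available via `pooling = "max"`). Averaged binary maps
  are fractional; since no re-binarisation rule is defined for them, they
  feed the next layer's weighted sum as graded inputs. Inputs whose extent
  is not a multiple of $s$ are cropped at the bottom/right.
* **Output layer.** The final fully connected layer is a non-spiking
  accumulator: it keeps the leak ($v(t) = \lambda v(t-1) + i(t)$, the same
  recurrence with the spike and reset terms removed) but never fires and
  never resets. The class with the largest membrane at the last timestep is
  the prediction, ties broken toward the lowest index.
* **Initial state** at $t = 1$ is all-zero membranes and spikes.

## Training: variant STBP with learned thresholds

The loss is softmax cross-entropy on the final-timestep output membranes
(the loss form is otherwise unconstrained; cross-entropy is the standard
choice consistent with the argmax readout). Gradients flow through space
(layer to layer, through the transpose of the synaptic connectivity, with
*both* pathway blocks of a DTC layer converging onto the shared membrane)
and through time.

The spike step function is non-differentiable, so the derivative of a spike
with respect to the normalised membrane $u = v / V_{th,k}$ is approximated
by the rectangular surrogate

$$h(u) = [\,|u - 1| < 1/2\,],$$

a width-1 window centred on the firing point, with strict inequality at its
edges. Each pathway contributes
$\partial L/\partial x_k \cdot h(v/V_{th,k}) / V_{th,k}$ to the membrane
gradient.

Two temporal-path details are fixed by explicit decisions:

* The temporal term of the spike gradient exists only for the
  reset-carrying pathway ($\partial v(t{+}1)/\partial x_0(t) = -\lambda
  v(t)$); pathway 1 has no influence on the future.
* The membrane-to-membrane chain is by default expanded exactly **one
  step**: the spikes of $t+1$ contribute through the leak-and-reset carry
  $\lambda(1 - x_0(t))$, deeper history does not. This follows the printed
  backward equations literally. `train_config(temporal_membrane_path =
  TRUE)` switches to the full recursion of standard STBP, in which the
  carry propagates the complete accumulated membrane gradient. At $T = 1$
  — where all headline results live — the two are identical and no
  temporal code runs at all, which the suite asserts.

Thresholds are per-layer scalars learned alongside the weights:

$$\frac{\partial L}{\partial V_{th,k}}
  = \sum_{i,t} \frac{\partial L}{\partial x_{i,k}(t)}\;
    h\!\left(\frac{v_i(t)}{V_{th,k}}\right)
    \left(-\frac{v_i(t)}{V_{th,k}^2}\right),$$

summed over neurons and timesteps (the batch average enters through the
mean loss), updated as $\Delta V_{th,k} = -\gamma\, \partial L / \partial
V_{th,k}$ and clipped to a floor of 0.01 so the division by $V_{th}$ stays
defined. The gradient correctness of all of this is checked against an
independent scalar expansion of the same chain rule, neuron by neuron, on
networks of at most ten neurons at $T \in \{1,2,3\}$, to $10^{-8}$.

### Two-stage strategy

Training at a single timestep from scratch starves the temporal gradient.
The two-stage recipe avoids it: **pre-train** from random weights at
$T = 5$, then **re-train** from the pre-trained parameters at $T = 1$.
`two_stage_train()` implements the hand-off (checkpoints make it
reproducible across processes); the resulting single-timestep network keeps
the pre-train accuracy on the synthetic benchmark to within the tested
5-point margin.

### Defaults and free choices

Published recipe, kept as defaults: leak $\lambda = 0.5$; all thresholds
initialised to 0.5; dropout probability 0.5; learning rate multiplied by
0.9 every 25 epochs ("dropped by 10%" is read as $\times 0.9$ — a drop *to*
10% every 25 rounds would collapse the rate by $10^{-8}$ over a 200-round
run, which cannot be meant). Free choices, declared not inferred: plain
mini-batch SGD (matching the bare threshold-update form; momentum exists
but is off), batch size 64, initial learning rate 0.05, dropout applied to
spiking fully connected outputs only (convolutional dropout is uncommon),
one dropout mask per batch shared across timesteps, inverted-dropout
scaling.

**Initialisation.** Weights are fan-in-scaled uniform,
$U(-g/\sqrt{n_{in}}, g/\sqrt{n_{in}})$ with gain $g = 3$ by default. The
gain matters more here than in conventional networks: with unit gain the
early currents sit far below the 0.5 thresholds, no membrane enters the
surrogate window, and a silent layer passes *zero* gradient — the network
is untrainable, not merely slow. $g = 3$ puts initial currents on the
threshold scale for the layer sizes this package targets.

## Operation, weight and membrane accounting

`profile_network()` reproduces the published accounting:

* a convolutional layer costs $h' w' \cdot c_{in} k^2 \cdot c_{out}$
  synaptic operations; a DTC layer halves this
  ($c_{out}/2$ membrane maps); a fully connected layer costs
  $n_{in} n_{out}$;
* only the coding layer needs MAC (real inputs); every other layer is ACC
  — including layers fed by fractional pooled values, matching the
  published table;
* "weights" counts convolutional kernel parameters only; "Vms" counts the
  membranes of all spiking layers plus the output accumulators; pooling,
  threshold comparisons and resets are free;
* operation totals scale with the timestep count; storage does not.

Under these conventions the profiler reproduces every printed cell of the
published three-network comparison within its rounding — except the ACC
count of the large CIFAR10 DT network, where the listed architecture yields
≈301M against a printed 315M. No convention we could find reproduces that
cell *and* all the others; the discrepancy is documented and that one cell
is excluded from the reproduction tests. The exact 50% halving of
convolutional weights and membranes holds for all three pairs, as the
"↓50%" annotations state. Per-layer counts are additionally validated
against a literal nested-loop enumeration of synaptic events.

The efficiency ratio $R = \text{accuracy}(\%) / \text{operations}(M)$
(operations of one full inference, already multiplied by $T$) summarises
the accuracy/cost trade-off.

## Synthetic data: what it stands in for

`generate_synthetic_dataset()` emulates the regime of the small grayscale
benchmarks: images in $[0,1]$, presented identically at every timestep,
with a fixed class-conditional structure. Two families exist:

* **oriented bars** — class $k$ is a bar through the image centre at angle
  $(k-1)\pi/K$, with a central disk blanked so the supports of different
  classes are pairwise disjoint (at zero noise the class means are exactly
  orthogonal, which the tests assert);
* **Gaussian blobs** at class-specific positions.

Per sample, a uniform intensity draw in $[0.7, 1]$ and additive Gaussian
pixel noise (default SD 0.1) perturb the pattern. Everything is
deterministic given the seed.

What this does *not* emulate: intra-class shape variability, translation,
clutter, and the scale of real benchmarks. Passing the training tests shows
the optimiser, the dual-pathway gradients and the two-stage hand-off work
end to end; it does not certify benchmark-level accuracy, which requires
the real datasets and long runs (the IDX reader accepts the standard MNIST
container files for exactly that use).

## Problem sizes used by the tests and the acceptance script

The desk-scale two-stage experiment uses a `4dtc3-p2-16fc-3fc` network on
3-class 16×16 oriented bars (80 samples per class, noise 0.1), pre-trained
30 epochs at $T = 5$ and re-trained 15 epochs at $T = 1$ with batch size
16 — sizes chosen so the full experiment is a sub-minute, single-CPU run
while still exercising every code path (dual pathways, pooling, dropout,
both stages). Gradient-oracle networks have at most ten neurons so the
scalar expansion stays exact and fast.

## Known limitations

* Strided/dilated convolutions, residual connections and event-driven
  sparse execution are out of scope; the forward pass is dense.
* Even kernels are rejected (same padding would be asymmetric).
* Only unsigned-byte IDX tensors are supported (images and labels).
* The backward pass follows the printed one-step temporal expansion by
  default; users wanting textbook STBP must opt in via
  `temporal_membrane_path`.
* Training is plain R linear algebra: comfortable at the desk scale used
  here, not at benchmark scale.
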