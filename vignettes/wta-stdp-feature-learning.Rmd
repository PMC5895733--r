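---
title: "Unsupervised feature learning with winner-takes-all binary STDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised feature learning with winner-takes-all binary STDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtastdp)
```

## The model

`wtastdp` trains convolutional feature banks from unlabelled images with a
spike-timing-dependent plasticity (STDP) rule adapted to static inputs. The
package rests on a chain of observations about leaky integrate-and-fire
(LIF) neurons driven by a constant input.

**LIF dynamics under constant drive.** A LIF neuron with time constant
$\tau$, reset potential $u_{res}$ and threshold $\theta$ obeys
$\tau\,du/dt = -(u - u_{res}) + v_{in}$ with $u(0) = u_{res}$, where
$v_{in} = \sum_i w_i x_i$ is the weighted input. Because an image is static,
$v_{in}$ is constant and the equation solves in closed form:
$u(t) = -v_{in}e^{-t/\tau} + u_{res} + v_{in}$. The neuron first crosses
threshold at

$$t_s = -\tau \log\!\left(1 + \frac{u_{res} - \theta}{v_{in}}\right),$$

which exists iff $b + v_{in} > 0$ with $b = u_{res} - \theta$, and decreases
monotonically in $v_{in}$: stronger drive, earlier spike. `lif_params()`,
`membrane_potential()`, `analytic_first_spike()` and the Euler oracle
`simulate_first_spike()` implement and cross-check this math.

**Equivalence with rectified-linear units.** As $t \to \infty$,
$u(t) - \theta \to b + \sum_i w_i x_i$ — a perceptron's weighted sum with
bias $b$. Its positive part (`relu_drive()`) is positive exactly when a
finite spike time exists, and sorting a population by descending activation
equals sorting by ascending spike time. A whole spiking pass therefore
reduces to one convolution (`conv_forward()`), with activation *magnitude*
encoding first-spike order. Activations are kept **signed**: a negative
value is read as the activity of the synaptically symmetric partner neuron
(the ON/OFF trick that `on_off_encode()` applies at the retina stage), so
rectification is deferred to inference-time presets.

**Three-stage winner-takes-all selection.** During learning, at most one
input patch per output channel and image is selected by composing:

1. `neighborhood_inhibition()` — magnitude max-pooling with kernel
   $k_{pool} \ge k_{conv}$ and stride $s_{pool} = k_{conv}$, sign preserved,
   pre-pool coordinates recorded (lateral inhibition within a region);
2. `channel_wta()` — the shape-preserving WTA operator (`wta()`) along
   channels: at each pooled position only the earliest-spiking neuron
   survives;
3. `spatial_wta()` — per image and channel, only the `n_keep` (default 1)
   strongest survivors remain, enforcing $m_k \le N$.

`extract_selection()` maps each surviving winner back to its exact input
receptive field; the identity $x \cdot W_{\cdot k} = y$ is checked in the
test suite and is the module's master self-test.

**Binary Hebbian update.** For a selected pair $(x, y)$ on channel $k$,
define the sign-corrected activation
$\hat x_i = x_i\,\mathrm{sign}(y)\,\mathrm{sign}(w_i)$ and an adaptive
threshold $T_l$. Each synapse moves by

$$\Delta w_i = \mathrm{sign}(\hat x_i - T_l)\,\mathrm{sign}(w_i) \in \{-1, +1\},$$

i.e. potentiation in the synapse's current direction when the input drove
the selected output through it more strongly than threshold, depression
toward zero otherwise. `delta_w()` implements this as a branch;
`delta_w_compact()` is the algebraically identical branch-free form. For any
$T_l \ge 0$ the rule reproduces the classic six-cell LTP/LTD table (strong
aligned input $\to \mathrm{sign}(x)\mathrm{sign}(y)$; sub-threshold input
$\to -\mathrm{sign}(w)$); writing both the condition and the update in
sign-corrected coordinates is the formulation that keeps the branch and
branch-free forms equal for *every* threshold value, including the negative
thresholds the adaptive strategy can produce, so that is the formulation
the package adopts.

Two threshold strategies are provided. `threshold_mean_correlation()`
(default) uses $T_l = \mathrm{mean}(\hat x)$, which makes the update
invariant to local contrast and needs no tuning.
`threshold_percentile()` fixes the potentiating fraction $p_n$ by magnitude
ranking; it exposes sparsity directly but requires a sort and manual tuning.

**Batch aggregation.** Updates for one channel are summed over the
mini-batch (`aggregate_batch()`), binarized with ties-to-depression
(`binarize_update()`: $-1$ where the summed evidence is $\le 0$), and
applied as a single $\pm\lambda$ step (`apply_update()`). A channel that
selected *no* patch in a batch receives no update at all: applying the
binarization rule to an all-zero accumulator would push every untouched
synapse by $-\lambda$ and make unlearned neurons drift, contradicting the
stability the method aims for. This is a deliberate interpretation choice,
applied uniformly.

**Homeostasis.** After each update phase, every updated column is
mean-centred, standardized to unit variance, and clipped to $[-2, 2]$
(`normalize_neuron()`). Equalizing the first two moments keeps competition
fair across neurons; clipping prevents a few extreme synapses from turning
neurons into near-duplicates. The learning rate starts at
$\lambda_0 = 0.1$ and halves each epoch (`lr_schedule()`).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `tau` | 20 (time units) | LIF membrane time constant; only ratios $t/\tau$ matter |
| `theta - u_res` | 1 | spiking threshold above rest; the ReLU bias is $u_{res} - \theta$ |
| `k_conv` | 5 | receptive field side; the learned template size |
| `k_pool`, `s_pool` | `k_conv`, `k_conv` | lateral-inhibition pooling; `k_pool >= k_conv` is required |
| `n_keep` | 1 | spatial winners per (image, channel); 1 enforces $m_k \le N$ |
| `threshold_strategy` | `mean_correlation` | adaptive LTP/LTD threshold; `hard_percentile` with `p_n` is the fixed-sparsity alternative |
| `lambda0` | 0.1 | weight step per batch; halved each epoch |
| `batch_size` | 64 | update aggregation granularity (Eq.-level majority vote) |
| `epochs` | 3 | few epochs suffice; the rate decays geometrically |

## What the synthetic generator emulates — and what it does not

`generate_pattern_bank()` draws $k$ zero-mean, unit-variance templates with
pairwise $|\cos| \le 0.5$, and `generate_images()` embeds them in Gaussian
noise. Two placement modes exist, and the difference is scientifically
load-bearing:

* **`scatter`** (default): templates at uniform random non-overlapping
  positions on a noise background. This is the natural reading of "repeated
  patterns in noise", but for a *translation-equivariant* learner it makes
  exact template recovery ill-posed: every shifted fragment of a template,
  padded with clean noise, is itself a perfectly consistent repeating
  stimulus, and filters may lock onto fragments. In our experiments they
  regularly do, matching templates well only up to a spatial shift.
* **`tile`**: every template-sized cell of the canvas receives a template
  with uniformly random identity. A misaligned window then overlaps two
  cells whose contents change independently from image to image, so the
  aligned templates are the *only* consistently repeating stimuli. This is
  the placement used for the recovery experiments.

The study conditions frozen for the recovery experiments are: 4 templates
of 5×5, a 10×10 canvas tiled 2×2, noise $\sigma = 0.2$ (a fifth of template
variance), 2,000 images, 8 filters, 3 epochs, $\lambda_0 = 0.1$, batch 64.
These sizes keep a full five-seed recovery experiment within a couple of
minutes on one CPU while leaving each condition non-trivial (multiple
templates per image, more filters than templates, real noise).

What passing these tests shows: the update rule, competition, and
homeostasis jointly recover *planted, aligned, repeating* structure from
noisy data, and the learned features carry class information that frozen
random filters of the same architecture do not. What they do not show:
recovery of structure at unknown scale or rotation, behaviour on natural
image statistics (no 1/f spectrum, no occlusion, no correlated background),
or classification performance on real datasets — the architecture presets
(`arch_preset()`) encode what is known of the reference experiment
geometries for users who wish to try, with user-supplied data and a
stronger readout than the built-in linear one.

## Numerical choices

* **Euler oracle**: forward Euler with `dt = 1e-3 * tau` and horizon
  `t_max = 50 * tau` ($e^{-50}$ is far below double precision); the
  closed-form and simulated spike times agree to `2 * dt` for drives of
  moderate latency. A `dt >= tau` warning marks the unstable regime.
* **"No spike" is `NA`**, not an infinite sentinel — it propagates honestly
  through order statistics.
* **Ties** in any WTA stage resolve to the lowest index in (channel, row,
  col) priority; exact zeros never win (a zero drive means "no spike").
* **`sign(0)` is 0** inside the update rules: a zero input or weight
  carries no Hebbian evidence and contributes nothing to the accumulator.
* **Population variance** in `normalize_neuron()` — the column *is* the
  population of that neuron's synapses. The normalization divides by the
  standard deviation (not the variance): unit variance of the result is
  the stated goal of the homeostatic step, and dividing by the variance
  would not scale correctly away from $\sigma = 1$.
* **Degenerate constant columns** re-initialize from the standard-normal
  init distribution, with a warning.
* **Valid convolution, stride 1, no padding**, cross-correlation
  convention, 1-based top-left coordinates: patch extraction must map every
  output back to a complete input window.
* Weight banks flatten filters in (channel, row, col) order, column
  fastest; every patch, template, and kernel in the package uses the same
  order.

## Design decisions taken where the design was open

* **Multi-layer training without greedy phases**: `train_network()` gives
  every layer one update step per mini-batch, each layer reading the batch
  propagated through the weights the lower layers held at the start of
  that batch. With one layer this reduces exactly to `train_layer()` (the
  test suite asserts identity).
* **Spatial WTA competes per image**, not across the batch: the invariant
  $m_k \le N$ (at most one selection per channel per image) forces this
  reading.
* **`n_keep` is a count, not a percentage**; a percentage of retained
  activities conflicts with $m_k \le N$, and the constraint wins.
* **Per-batch normalization touches updated columns only**, consistent
  with the no-update rule for channels with $m_k = 0$.
* **Serialization is JSON** (weights as full-precision `%.17g` strings,
  restored bit-exactly) and image fixtures travel as IDX files; both are
  plain, dependency-light formats with exact round-trips, checked in the
  tests.

## Known limitations

* The binary $\pm\lambda$ dynamics drive converged filters toward a
  *thresholded-template* structure: synapses above the adaptive threshold
  sit at a common large magnitude, the rest near zero. With unit-variance
  columns the large weights land near $\sqrt{n/m}$ for $m$ of $n$ synapses
  selected — around 1.5–2 under the study conditions — so an appreciable
  minority of trained weights sits outside $[-1.5, 1.5]$; the acceptance
  script reports the measured fraction, and it falls short of the
  ninety-five percent sometimes quoted for unit-variance weight
  distributions. The clip range $[-2, 2]$ always bounds the weights by
  construction.
* Recovery of *exactly aligned* templates requires the tiled placement for
  the reasons above; scatter-placed patterns are recovered only up to
  translation.
* One spike per neuron, no refractory period, no membrane noise; the
  percentile threshold strategy is $O(n \log n)$ per patch where the mean
  threshold is $O(n)$.
* Training deeper stacks is harder than training one layer: competition
  needs enough spatial extent to be effective, and upper layers see small
  maps under aggressive pooling.

## A complete run

```{r, eval = FALSE}
bank <- generate_pattern_bank(4, c(1, 5, 5), seed = 0)
train_ib <- generate_images(bank, 2000, noise_sigma = 0.2,
                            canvas = c(10, 10), placement = "tile", seed = 11)
spec <- layer_spec(1, 8, 5)
tl <- train_layer(train_ib, spec, learning_config(epochs = 3, seed = 1))
filter_pattern_similarity(tl, bank)$pattern_best
weight_interval_fraction(tl, -1.5, 1.5)
```
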