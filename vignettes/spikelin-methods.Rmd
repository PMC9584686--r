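---
title: "Adaptive lateral inhibition and evolving spiking networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive lateral inhibition and evolving spiking networks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikelin)
```

spikelin implements a recognition pipeline for grayscale images and
neuromorphic event streams built from three components: an adaptive
lateral-inhibition (LIN) front-end that suppresses smooth backgrounds, leaky
integrate-and-fire (LIF) neurons whose membrane time constants evolve with
the training error, and a parallel multi-scale convolutional spiking network
trained with a windowed, supervised STDP-style rule. This vignette states
each model precisely, lists the tunable parameters with their defaults and
why those defaults were chosen, and records the design decisions made where
the underlying formulation was genuinely open.

## Lateral inhibition

The traditional model subtracts from each pixel a weighted sum of its
neighbourhood inside a square field of radius $N$:

$$G(u,v) = F(x,y) - \sum_{m=-N}^{N}\sum_{n=-N}^{N} k(m,n)\, F(x+m,\,y+n),$$

with one experience-chosen coefficient $k$. The adaptive model makes two
changes. First, the centre image is pre-filtered with a frequency-domain
Butterworth low-pass, $1/(1 + (D/D_0)^{2n})$, where $D$ is the Euclidean
distance to the centred spectrum origin in index units; this suppresses
pixel noise that plain inhibition would amplify. Second, the coefficients
decay exponentially with both distance and the image's two-dimensional pair
entropy $H$:

$$k(m,n) = A \exp(-d_{mn}\, H), \qquad d_{mn} = \sqrt{m^2+n^2}.$$

$H$ is the Shannon entropy of the joint distribution of feature tuples
$(x, y)$, where $x$ is a pixel's quantised gray value and $y$ the rounded
mean gray value of its neighbourhood (3x3 by default, centre excluded).
Smooth regions concentrate the tuple distribution (low $H$, large $k$,
strong inhibition); textured regions spread it (high $H$, small $k$, weak
inhibition). This is the mechanism by which a low-information background is
suppressed more than a high-information target.

Design choices where the formulation is open:

- **Raw vs filtered neighbours.** The adaptive formula subtracts
  neighbourhood values of the *raw* image from the *filtered* centre value.
  We implement exactly that, with an `inhibit_filtered` switch (default
  `FALSE`) for users who prefer denoised neighbours too.
- **Centre tap.** The printed summation bounds $m,n=-N..N$ include the
  offset $(0,0)$, so `include_center = TRUE` is the default. Note that the
  centre coefficient is $A\exp(0) = A$ regardless of $H$, i.e. the centre
  tap subtracts a fixed multiple of the pixel's own intensity; analyses of
  *lateral* (neighbour-driven) suppression should set
  `include_center = FALSE`, and the background-suppression analyses in the
  test suite do.
- **Entropy sign and base.** Shannon entropy is implemented with the
  conventional minus sign (non-negative $H$) and base-2 logarithms; the
  base is configurable.
- **Neighbourhood mean at borders.** Border pixels average over their
  in-image neighbours only. A zero-padded mean would assign a constant
  image several distinct tuples along its borders and hence nonzero
  entropy, which contradicts the definition of an information-free image.
  The inhibition sum itself *is* zero-padded outside the image, which is a
  statement about missing receptors rather than about information content.
- **Global vs windowed entropy.** One global $H$ per image is the simplest
  reading and is the default in `apply_lin()`. A global $H$, however,
  applies the same kernel everywhere and therefore cannot inhibit the
  background *more* than the target within one image; the spatially
  resolved behaviour requires the sliding-window entropy map
  (`window = 9`), which drives per-pixel coefficients. The default
  image-classification pipeline (`snn_fit_images()`) uses the windowed
  form.
- **Unstated constants.** $A = 1$, $D_0 = \min(h, w)/4$, filter order 2,
  radius 2, traditional $k = 0.02$. None of these are given in the source
  formulation; they were fixed once at round values that keep the
  traditional kernel's total inhibition below 1 for radius 2.

Intermediate LIN output may leave $[0, 255]$; clamping is explicit
(`clamp_output`), and unclamped output can be dumped as float64 NPY.

## The evolving LIF neuron

The membrane obeys $\tau_m \dot V = -V + R_m I(t)$ with
$\tau_m = R_m C_m$. Under constant current from the reset potential,

$$V(t) = R I_0 \left(1 - e^{-t/\tau_m}\right),$$

giving the interspike interval $T = \tau_m \ln\!\frac{RI_0}{RI_0 - V_{th}}$
and firing rate $f = 1/T$ for supra-threshold drive. The rate is strictly
decreasing in $\tau_m$, which makes the time constant an effective
per-neuron rate control. `lif_simulate()` integrates the same equation with
explicit Euler (default `dt = tau_m/100`; a warning fires above
$\tau_m/10$), the simplest scheme consistent with the first-order dynamics;
the suite verifies the simulation against the closed forms to 1% at
`dt = tau_m/1000`.

**Time-constant evolution.** After each epoch with output error $E$, every
neuron's time constant is rescaled by $e^{aE}$ and clipped to bounds. The
recurrence as printed ($\tau^k = \tau^{k-1} e^{aE}$) grows $\tau$
monotonically while $E > 0$ for $a > 0$, which contradicts the behaviour it
is supposed to produce (decreasing $\tau$ during training, recovery to the
initial value as $E \to 0$). We therefore provide both semantics behind
`tau_rule(mode=)`: `"recurrent"` as printed, and `"anchored"`
($\tau^k = \tau_{\mathrm{init}} e^{aE}$), which literally satisfies
"$E \to 0$ returns $\tau$ to its initial value". Anchored with the default
`rate = -0.1` is the package default: the time constant dips while the
error is large (faster firing, larger gradients-by-analogy) and relaxes
back as training converges, damping late-stage rate oscillation. A
parameter controlling the "degree of change" separate from $a$ appears in
the surrounding discussion but not in the recurrence; we treat it as the
same quantity and expose the single `rate`.

Per-neuron initial values are jittered uniformly in
$[0.9, 1.1]\cdot\tau_{\mathrm{init}}$ with a seeded generator, so the
neuron population is diverse and reproducibly so; the across-neuron sd of
$\tau$ stays positive through training. Whether the evolution step should
run per batch, per sample or per epoch is unspecified; we fix per-epoch,
the only granularity at which $E$ is defined.

## Encoding

Static images are rate-coded: pixel $v$ emits a Bernoulli spike per step
with probability $(v/255)\cdot\texttt{max\_rate}$, over `timesteps = 20`
steps by default — rate coding is the natural counterpart of the
firing-rate analysis above; latency coding is out of scope. Event streams
are binned into `timesteps` frames; polarity maps to two channels with
binary OR semantics within a bin. Coordinates are row-major with origin at
the top-left and $x$ indexing columns. The encoding window length is not
specified by the source formulation; 20 steps keeps a sample presentation
short while leaving room for the 5-step plasticity window.

## The parallel convolutional spiking network

Per time step, each branch convolves incoming binary spikes with its
kernels (valid convolution, no bias — the LIF equation has none), updates
the LIF membranes, emits spikes on threshold crossing with reset, and
max-pools the spike maps 2x2 (preserving the binary alphabet; average
pooling is available as a graded-current option). Branch outputs are
concatenated channel-wise and feed fully connected spiking layers; class
scores are output spike counts accumulated over all steps. Membrane state
persists across time steps within a sample and is reset between samples,
so a forward pass is a pure function of the input and weights.

The branch structure realising "parallel" is not recoverable from the
source description beyond the schematic; the default is the minimal
two-branch form, 3x3 and 5x5 kernels with 8 channels each. The default
neuron for network use is `lif_params(resistance = 1, tau_m = 10,
threshold = 0.1, dt = 1)`: with seeded uniform weights in $[-0.1, 0.1]$,
initial conv currents are a few hundredths to ~0.2, so a threshold of 0.1
yields sparse but nonzero initial activity — silent networks cannot
bootstrap a spike-count learning rule, and a lower threshold saturates the
binary maps. Prediction is the argmax of output counts with ties broken
toward the lowest class index; an all-silent output predicts class 0 with
a warning.

## Training

The desired output is one-hot per time step: the target class should spike
at every step, the others never. The output error is

$$E = \frac{1}{N}\sum_j \sum_i (d_{ji} - o_{ji})^2,$$

with $o$ the spike counts normalised by the number of steps (counts,
rates and final potentials are all defensible readings of the "actual
output"; normalised counts commit to the rate view used throughout). The
weight change for synapse $i \leftarrow h$ at step $t$ is the windowed
STDP-style rule

$$\Delta w_{ih}(t) = \eta\, \alpha_i(t) \sum_{f=t-\varepsilon}^{t} s_h(f),$$

a teaching signal times the presynaptic spike count in the trailing window
($\varepsilon = 5$ steps by default). Changes accumulate per time step and
apply per sample (online), with weights clipped to $[-1, 1]$ to keep the
spiking dynamics bounded.

**The gating decision.** Read literally, $\alpha_i(t)$ is $+1$ wherever
the desired spike is 1 and $-1$ wherever it is 0 — a signal that never
consults what the network actually did. Implemented that way, the update
is a pure class-prototype accumulator: weights converge to (clipped)
differences of class-conditional mean spike counts, training accuracy
plateaus near what a difference-of-means classifier achieves, and $E$ does
not reliably decrease — while the surrounding account of the method is
explicitly error-driven ("backpropagation", $E \to 0$, time constants
stabilising late in training). The package therefore applies the signal
only at steps where the actual output spike differs from the desired one:
$\alpha_i(t) = +1$ when the neuron should have spiked and did not, $-1$
when it spiked and should not have, and $0$ otherwise — which is also the
only reading that gives the rule's third case ("0, otherwise") meaning at
the output layer. This is a perceptron-style mistake-driven rule; on the
linearly separable synthetic task it converges to ~100% training accuracy
across seeds, and updates vanish as $E \to 0$, exactly the claimed
behaviour. The literal semantics remain available as
`train_config(gating = "none")`.

**Hidden-layer credit assignment** is unspecified beyond "STDP-based
backpropagation". Decision: downstream teaching signals are pushed through
the transposed forward weights and thresholded to $\{-1, 0, +1\}$ by sign,
then each layer applies the same windowed presynaptic-count rule. This
stays inside the spike-count formalism (no surrogate gradients). Conv
neurons inherit the signal of their pooled unit; because a kernel is
shared across all spatial positions, its per-position contributions are
averaged (not summed) so that conv and dense updates live on the same
$\eta$ scale — without this, conv updates are two orders of magnitude
larger and saturate the clip range within one sample.

Defaults: $\eta = 10^{-3}$, $\varepsilon = 5$, 30 epochs, all layers
plastic (`train_conv = TRUE`). $\eta$ was fixed from pilot runs of the
default pipeline on the synthetic task before the acceptance suite was
written: large enough that 30 epochs suffice, small enough that one
sample's update (at most $\eta(\varepsilon+1)T \approx 0.12$) cannot
dominate the clip range.

## Evaluation

Classification accuracy comes with the score-type confidence interval

$$l,u = \frac{2np + z^2 \mp z\sqrt{z^2 + 4np(1-p)}}{2(n + z^2)},$$

which contains $p$, stays inside $[0,1]$ even at $p \in \{0,1\}$, and
shrinks as $O(1/\sqrt n)$. The typeset form of this interval in the source
is ambiguous (the extent of the radical is lost); the form above is fixed
by verifying that it reproduces all twelve reported (accuracy, interval)
pairs of the static and neuromorphic comparison tables at $n = 10000$,
$z = 1.96$, to the printed four decimals — that numerical pinning is the
authoritative disambiguation, and the acceptance suite re-checks every
row. The lower bound carries the minus sign (the accompanying text swaps
the words "upper" and "lower").

## Synthetic data

`make_images()` generates the study fixture: a near-uniform background
(level 40, Gaussian noise sd 0.5) plus one 12x12 shaped patch of
high-variance texture (level 128, sd 40) at a location jittered up to 3
pixels, with the shape (bar, cross, square, ring) carrying the class
label. The variance contrast operationalises the premise the adaptive LIN
rests on: measured windowed pair entropy is ~1.3 in the background and
~5 inside the target. The background sd matters: after 8-bit quantisation,
sd 1 already yields mid-range background entropies (~2.7) and visibly
weakens the suppression contrast, so 0.5 — a realistic sensor-noise floor
— is the default. Classes are separable by a linear probe on raw pixels,
so the training-convergence tests exercise the trainer rather than an
impossible task.

`make_events()` emulates saccade-driven neuromorphic capture: the scene
translates along a three-segment path on a padded constant canvas, and
intensity changes beyond 10 gray levels between consecutive positions emit
ON/OFF events with microsecond timestamps (`dwell` per step). A static
scene emits nothing; the background noise sits far below the contrast
threshold, so events trace the moving target's edges.

What the generator does *not* emulate: correlated (non-white) textures,
illumination gradients, occlusion, multiple targets, sensor-refractory
effects in the event camera, and photorealistic medical image structure.
Passing tests on this fixture show the pipeline's mechanisms behave as
specified — background suppression, convergence on separable shape
classes, parallel-vs-single ordering — not that benchmark-level accuracy
on real datasets is reproduced; those require the external datasets and
are out of scope.

## Problem sizes and numerical notes

The suite and the acceptance script run the study conditions at desk
scale: 200-sample training sets, 30 epochs, 5 seeds, two architectures
(the parallel default and a single-branch ablation with a matched
parameter budget: one 3x3 branch with 15 channels, 5205 vs 5280
parameters); oracle equivalence uses 200 random images up to 16x16 for
the inhibition double-loop and 50 8x8 images for the explicit-DFT
Butterworth check, at 1e-9 per pixel. All randomness flows from explicit
seeds; training is bit-deterministic given them (the per-epoch sample
order is drawn in R from the training seed). Ties in `predict()` and the
all-silent degenerate case are documented above; empty images, empty
event streams and zero-sample generator specs return well-formed empty
structures rather than errors.

## Known limitations

- The error-gated teaching signal is an interpretation (documented above);
  the literal ungated rule is provided but does not converge beyond
  prototype matching.
- Hidden-layer credit assignment is sign-based; deep fully connected
  stacks will train slowly since magnitude information is discarded.
- The LIN layer is defined for static images only and is bypassed for
  event input.
- Average pooling emits graded values, leaving the strictly binary spike
  alphabet; it is provided as an option but the binary max-pool is the
  analysed configuration.
- 23-bit AER timestamps wrap at ~8.4 s; longer streams are rejected
  rather than silently wrapped.
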