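# spikelin

Spiking neural networks for object recognition on grayscale images and
neuromorphic event streams, with an adaptive lateral-inhibition front-end
and evolving leaky integrate-and-fire neurons.

Recognition pipelines that feed raw images into a spiking network inherit
whatever the background contributes — and in realistic scenes (medical
imaging especially) the background competes with the target. spikelin
addresses this with three coupled pieces:

- **Adaptive lateral inhibition (LIN).** Each pixel is suppressed by a
  weighted sum of its neighbours,
  `G(u,v) = F_B(x,y) − Σ k(m,n) F(x+m, y+n)`, where `F_B` is the image
  after Butterworth low-pass denoising and the coefficients
  `k(m,n) = A·exp(−d·H)` decay with both distance `d` and the
  two-dimensional *pair entropy* `H` of the region — the Shannon entropy of
  joint (pixel gray, neighbourhood-mean gray) tuples. Smooth,
  information-poor backgrounds have low `H`, hence large coefficients,
  hence strong suppression; textured targets survive.
- **Evolving LIF neurons.** Membrane dynamics `τ_m dV/dt = −V + R·I(t)`
  with closed-form interspike interval `T = τ_m·ln(RI₀/(RI₀ − V_th))`; the
  firing rate falls strictly with `τ_m`. After each training epoch every
  neuron's time constant is rescaled by `exp(a·E)` with `E` the output
  error, and per-neuron jittered initial values keep the population
  diverse.
- **A parallel convolutional SNN** — side-by-side 3×3 and 5×5 spiking-conv
  branches, 2×2 max pooling on binary spike maps, channel concatenation and
  a fully connected spiking readout — trained with a windowed supervised
  STDP rule, `Δw_ih(t) = η·α_i(t)·Σ_{f=t−ε..t} s_h(f)`, plus Wilson-score
  confidence intervals for the resulting accuracies.

Everything runs on seeded synthetic data shipped with the package (textured
shapes on smooth backgrounds, plus saccade-style event streams), so the
full pipeline is testable end to end without downloading datasets.

## Worked example

```r
library(spikelin)

spec <- synth_spec(seed = 42, samples_per_class = 30)   # bar vs cross shapes
dataset <- make_images(spec)
fit <- snn_fit_images(dataset$images, dataset$labels,
                      network_config(num_classes = 2, seed = 1),
                      train_config(epochs = 10, seed = 1))
glance(fit)
#> # A tibble: 1 × 6
#>   epochs final_error final_train_acc tau_mean tau_sd n_parameters
#>    <int>       <dbl>           <dbl>    <dbl>  <dbl>        <dbl>
#> 1     10      0.0777           0.967     9.92  0.578         5280
```

Ten epochs on 60 images take a few seconds: the quadratic output error has
fallen to 0.08, training accuracy is 97%, and the time constants sit just
below their initial mean of 10 (the anchored evolution rule pulls them down
while the error is nonzero) with a positive spread across neurons — the
population stays diverse. `tidy(fit)` returns the full per-epoch history,
`autoplot(fit)` plots it.

```r
evaluate_fit(fit)$ci
#>    lower  upper     p  n     z
#> 1 0.8630 0.9829 0.950 60  1.96
confidence_interval(0.95, n = 10000)
#>    lower  upper     p     n     z
#> 1  0.946  0.954  0.95 10000  1.96
```

The same 95% accuracy that gives a wide interval on 60 held-in samples
pins down to (0.9456, 0.9541) at n = 10000 — the score interval shrinks as
1/√n and stays inside [0, 1] even at extreme accuracies.

Closed-form neuron quantities and the simulator agree:

```r
p <- lif_params(resistance = 1, tau_m = 10, threshold = 1, dt = 0.01)
interspike_interval(p, 2)   # 6.931472  (= 10·ln 2)
firing_rate(p, 2)           # 0.1442695 spikes per time unit
```

A command-line interface wraps the same functions
(`inst/cli/spikelin.R`): subcommands `enhance`, `simulate-neuron`,
`synth`, `train`, `evaluate` and `ci`, reading and writing PNG/PGM images,
IDX archives, 5-byte address-event binaries and CSV event files.

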