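---
title: "Self-attention-augmented encoding models of V1: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-attention-augmented encoding models of V1: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Neural system identification fits a model per neuron that maps an arbitrary
stimulus image to that neuron's firing rate. For primary visual cortex the
classical receptive field (the central patch that directly drives the
neuron) explains most of the response, but responses are also modulated by
the image *surround* through horizontal and feedback circuits. `sacnn`
implements a family of small convolutional encoding models in which each of
the three candidate mechanisms for surround integration — successive
convolutions, a single-headed spatial self-attention (SA) layer, and a fully
connected readout — can be switched on or off independently, together with
the stage-wise ("incremental") training procedure, evaluation metrics, and
attribution tools needed to compare them.

## Architecture family

Every model is assembled from the same blocks, in order
`alpha1, alpha2, [sa], beta1, beta2, readout`:

* **alpha blocks**: valid 5×5 convolution (ReLU) followed by 2×2 max pooling
  with stride 2. Two alpha blocks map a 1×50×50 image to a c×9×9 feature
  tensor (the unique simple valid-convolution/floor-pooling convention that
  yields 9×9 from 50 pixels). One spatial position of this tensor — a
  *hypercolumn* — has a 16×16-pixel theoretical input support at the center;
  the half-height extent of its empirical gradient profile is smaller
  (~13 px), which is the number a physiologist would report as the RF size.
* **sa block** (optional): single-headed spatial self-attention over the
  81 hypercolumns. Queries and keys are full-width (d = c) linear maps;
  similarity logits are scaled by 1/sqrt(c) and row-softmaxed. With
  `gamma = TRUE` the values are linearly transformed and an output
  projection follows the aggregation (channel mixing allowed); with
  `gamma = FALSE` values are the raw features, so every channel receives the
  identical spatial reweighting. The attended output enters through a
  residual with a learnable scalar gain `s` initialized at 0, so an SA model
  is exactly its feedforward trunk at initialization.
* **beta blocks**: valid k×k convolution (ReLU), no pooling. k = 3 adds
  post-attention spatial integration; k = 1 (the `*` variants and the
  receptive-field models) performs channel mixing only.
* **readout**: linear, one scalar output per image. `FCL` is dense over all
  hypercolumns; `CTL` reads only the center hypercolumn, confining the model
  to the classical receptive field.

Six named families cover the design space: `ff` (3, FCL), `ff_sa`
(3, FCL, SA with gamma), `rf` (1, CTL), `rf_sa` (1, CTL, SA without channel
mixing), `rf_sa_star` (1, CTL, SA with gamma) and `ff_sa_star` (1, FCL, SA
with gamma). Attention models use c = 30 channels against c = 32 for their
convolution-only baselines, which matches total parameter counts within
10% (5.4% for the receptive-field pair, 3.8% for the feedforward pair);
the full-width query/key maps are what makes this matching work — with a
c/8 bottleneck the SA layer would be too small to compensate the channel
reduction.

### Numerical choices

* ReLU after every convolution; no normalization layers. The readout is
  linear and trained unclipped (predictions may be clipped at zero for
  display only).
* Weights are fan-in-scaled uniform, with the He gain (sqrt(6)) for ReLU
  convolutions, gain 1 for the SA projections, and gain 0.1 for the readout.
  A near-zero readout matters in practice: with hundreds of readout inputs,
  a large random readout dominates early training and visibly slows the
  fully connected models at small step budgets.
* Pixel intensities live on a [0, 1] scale and are shifted by −0.5 at the
  network input. Zero-centered inputs roughly double the correlation
  reachable in a fixed number of optimization steps in our experiments;
  a constant shift changes no gradient or receptive-field measure.
* Coordinates are row-major, 0-based conceptually (R indexing is 1-based);
  the center hypercolumn of an h×w map is (h %/% 2, w %/% 2) 0-based.
  Max-pool ties resolve to the first element in column-major order.
* The smallest legal input side is 16 (the valid chain gives
  16 → 12 → 6 → 2 → 1).

## Training and the incremental procedure

`train_config()` defaults are the reference settings: batch size 50,
Adam, learning rate 0.001, MSE loss, 50 epochs, one model per neuron.
Training is bit-reproducible given (data, config, seed), and frozen blocks
are verified bit-identical after every run.

Incremental plans decompose learning: `incr` trains the receptive-field
model first, then the SA model with the alpha blocks inherited and frozen
(the stricter reading of "taken from" — a config switch allows fine-tuning
instead); `incr_fc1` / `incr_fc2` then expand the center readout into a
fully connected readout whose center column is initialized from the CTL
weights and whose surround weights start at zero, so the expanded model
reproduces its parent's predictions exactly at initialization. FC1 freezes
the center column and bias (only surround contributions can be learned);
FC2 trains the whole readout. Pre-readout blocks stay frozen in both FC
stages so they isolate readout effects, and the optimizer state is reset at
stage boundaries so no momentum leaks across architectures.

## Metrics

* **Pearson correlation** between predictions and (repeat-averaged)
  responses; undefined-variance inputs raise errors rather than returning 0.
* **Peak tuning (PT)**: the threshold t is the smallest of the top-1%
  recorded responses; PT is the percentage of "top predictions" at or above
  t. PTJ ranks candidates jointly (the images with the top *recorded*
  responses); PTS ranks them separately (the images with the top *predicted*
  responses). PTS ≥ PTJ always. The candidate set uses k = ceiling(f·n) with
  inclusive ties; a second joint-mode reading ("prediction also ranks in the
  top 1%") is available as `joint_rule = "rank"`.
* **CCnorm**: correlation against the repeat mean divided by the noise
  ceiling sqrt(SP / Var(mean)), with the signal power SP estimated from
  repeat variance as (Var(rowSums) − sum(per-repeat Var)) / (R(R−1)). With
  identical repeats it reduces to the plain correlation; with pure noise the
  estimator is undefined and errors.

## The synthetic V1 scene

Real recordings of this kind (two-photon calcium imaging, ~300 neurons per
site, 30–50k single-trial training images, ~1k validation images × 10
repeats) are not redistributable, so every experiment here runs against a
generator with known ground truth:

* **Stimuli**: seeded pink-noise images (1/f amplitude spectrum, the
  canonical natural-image second-order statistic), or scattered oriented
  Gabor textures, in [0, 1], nominally 50×50 at 15 px/degree (the working
  resolution after 2× downsampling of 100×100, 30 px/deg stimuli).
* **Neurons**: quadrature-pair Gabor energy cells,
  `rate = A · E_c^p · max(0, 1 + beta_f·F/f0 − beta_s·S/s0)`, with `E_c` the
  center energy (filters truncated to the central patch so that with zero
  surround gains the response depends on the center *exactly*), `F` the
  collinear flank energy (flanks at 14 px along the bar axis), and `S` the
  omnidirectional energy on a 16-px surround annulus. All contextual
  filters are zeroed inside the central 16×16-pixel box — the theoretical
  input support of the models' center hypercolumn — so contextual
  modulation originates strictly outside anything a center-readout model
  can see; without this the "surround" signal leaks into the classical RF
  and a center-only model can track it, which defeats the purpose of a
  dissociation experiment. The expansive exponent p ∈ [1.5, 2.5] yields the
  sharp selectivity characteristic of V1 (median fraction of pink-noise
  images above half peak < 2%).
* **Calibration**: each neuron's output gain and its flank/surround energy
  normalizers are fixed once against an internal seeded probe set, keeping
  responses deterministic. Full-strength modulation gains
  (`beta_f ~ U(0.4, 0.8)`, `beta_s ~ U(1.0, 1.8)`) were chosen — from the
  generator's own energies, before any model was trained — so that an ideal
  center-only predictor is capped near r ≈ 0.65 against the true rate:
  a dissociation experiment is only informative if the surround genuinely
  shapes responses. At `modulation_strength = 0` all gains vanish.
* **Trial noise**: Gaussian with variance growing with the rate,
  `sd = 0.1·sqrt(rate + 0.01)`, clipped at zero — a pragmatic stand-in for
  calcium-signal variability (noise ceilings around 0.95–1.0 for 10-repeat
  means).

What the generator does **not** emulate: natural-image phase structure and
higher-order statistics, eye movements, temporal dynamics, correlated noise
across neurons, and the diversity of real V1 cell types. Passing synthetic
experiments therefore demonstrates that the machinery works and that the
qualitative orderings hold when the ground truth contains (or lacks)
surround structure — not that the same effect sizes would be measured in
cortex.

## Desk-scale experiment sizes

The package's experiments run on a single CPU; problem sizes are the
package's defaults, stated here once: dissociation benchmarks use 50×50
images, c = 8 channels, 4–5 neurons per bank, training sets of 2,000–3,000
images, 12–15 epochs at learning rate 0.003 (roughly 500–900 Adam steps per
fit), and 500 validation images with 10 repeats. Full-size fits (c = 30–32,
30k+ images, 50 epochs) follow the same code paths but take orders of
magnitude longer.

Two honest caveats about what these budgets can show. First, families with
more contextual machinery (SA, fully connected readouts) converge more
slowly than the bare receptive-field model, so small-step comparisons
partly reflect optimization speed rather than architecture; near-zero
readout initialization and the incremental plans mitigate but do not
remove this. Second, the peak-tuning comparison is intrinsically
high-variance at desk scale: with 500 validation images the top-1% set has
five members, so a single neuron's PTS moves in 20-point steps, and with a
handful of neurons a paired sign test at α = 0.05 requires a clean sweep.
In our runs the contextual models capture ground-truth surround structure
on some neurons (PTS 25–50 where the center-only model scores 0) but not
uniformly across neurons at c = 8, so the population-level peak-tuning
ordering is not statistically resolvable at these sizes — resolving it
needs the full-size regime (tens of neurons, 30k+ images), which is exactly
the regime the original comparisons were run in.

## Known limitations

* No multi-head attention, no shared-core multi-neuron readouts, no
  normalization layers or dropout — deliberately outside scope.
* The dataset container is RDS-based; interoperability with HDF5 tooling
  would require an external converter.
* CCnorm's signal-power estimator can be negative for neurons whose
  repeat-mean variance is dominated by noise; the package raises an error
  for such neurons rather than reporting a fabricated ceiling.
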