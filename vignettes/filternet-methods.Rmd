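---
title: "filternet: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{filternet: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the exact conventions the package implements, in
the places where a design choice had to be pinned down. The worked
example lives in the README; here we document semantics.

## The layer module

Every hidden layer is one module (`flm_config()`): channel dropout →
a 1-D convolution with ReLU **or** a bidirectional LSTM → average pooling
with kernel = stride = `s` → batch normalization. Conventions:

* Convolutions use symmetric zero padding so a stride-1 layer preserves
  length; output length is `ceiling(L / s)` (`flm_output_length()`), with
  the last pooling bin zero-padded on the right.
* A convolution followed by batch normalization carries **no** additive
  bias — the BN shift makes it redundant. The output module (component G)
  has a bias and no BN.
* Dropout zeroes whole channels per series (not individual samples) and
  rescales by `1/(1-p)` so the expectation is preserved; it is identity at
  evaluation time.
* The bidirectional LSTM runs one pass per direction at the incoming rate
  and concatenates hidden states, so `w_out` must be even (half per
  direction).

Parameter accounting (`flm_param_count()`) counts conv weights plus BN
scale/shift, or for the LSTM `2(4h(w_in + h) + 4h)` plus BN with
`h = w_out/2`. The tests verify the closed form against an enumeration of
every trainable array in an instantiated layer.

## Region of influence

`roi_after_stack()` implements the stride-cumulative recurrence

    ROI_i = ROI_{i-1} + (k_i - 1) * prod_{j<=i} s_j,  ROI_0 = 1,

which counts kernel taps at each layer's *output* rate. Two caveats,
both deliberate:

* For stride-1 stacks the recurrence is the exact receptive field, and
  the tests confirm this by single-sample perturbation probing of
  random-weight networks.
* For strided conv-then-average-pool layers with `k >= 2` the realized
  field is smaller (the module convolves *before* decimating), so the
  analytic value is a strict **upper bound**. The probing tests assert
  the bound and that the realized field still grows with depth.

An upper bound is the correct polarity for inference: `roi_trim`
discards half an ROI from each window edge, so an overestimate can only
discard extra valid samples, never keep contaminated ones. Any layer
stack containing an LSTM has unbounded ROI (`Inf`), and ROI-trimmed
windowing refuses it.

## Architecture and the width schedule

A spec (`filternet_spec()`, `build_reference()`) is the component graph:
full-rate layer A, a pooling stack B (stride 2 each), a second pooling
stack C whose widths follow `ceiling(w_prev / 2)` with the final C layer
at stride 1, a resampling step D that linearly resamples every C
intermediate to the B rate and concatenates them with the B output
(`resample_concat()`; at reference widths 100 + 50 + 25 + 13 + 7 = 195
channels), a `k = 1` bottleneck E, optional LSTM layers F, and the
`k = 1` output module G. Resampling aligns the first and last samples of
each series (`approx` over a common unit grid).

The network's output rate is the B-stack rate; `output_stride()` returns
the input-samples-per-output-step ratio, and `width_scale` scales every
hidden width (rounded, LSTM widths kept even).

## Labels, loss and binning

Labels are integers `0..n_classes-1` with 0 the null class, one per input
sample. Because the network emits one distribution per *output* step,
targets are binned: each stride-`s` bin takes the **mode** of its labels,
ties resolved toward the smaller class id. The loss is mean cross-entropy
over output steps.

## Training schedule and the checkpoint metric

`filternet_fit()` uses Adam with the control's learning rate, decayed by
a fixed factor on epochs with no improvement of the checkpoint metric,
and stops after `patience` non-improving epochs, restoring the best
checkpoint. The per-epoch raw score is `loss_val / F1w_val` (lower is
better; F1w is the support-weighted F1 over non-null-inclusive classes).
The checkpoint metric (`checkpoint_metric()`) is

* an exponentially weighted moving average of the raw score with a
  half-life of 3 epochs, plus
* an instability penalty: the population standard deviation of the last
  up to 5 raw scores.

A constant history therefore has metric equal to the raw value, and a
two-epoch history has a hand-computable EWMA — both are unit-tested.

## Windowed inference

`plan_windows()` tiles a series with fixed-length windows at stride
`window_len * (1 - overlap_fraction)`, the last window right-aligned so
coverage is complete. Per-window logits are stitched by `reconstruct()`:

* `overlap_add` weights each window with a Hanning taper (renormalized by
  the summed taper mass per output step). Edge-contaminated samples sit
  where the taper is quadratically small, so the reconstruction error
  decays rapidly with window length; with windows long relative to the
  ROI it is numerically indistinguishable from the unsegmented pass.
* `roi_trim` keeps only the central region of each window, discarding
  `ceiling(ROI/2)` input samples' worth of output per side; with window
  overlap of at least one ROI it reproduces the unsegmented forward pass
  exactly (to floating-point roundoff).

Both methods return logits on the full output grid; global series edges
are inherently edge-padded in either case.

## Ensembling

`make_folds()` splits the training series into `n` contiguous,
near-equal segments (remainder to the leftmost folds).
`filternet_fit_ensemble()` trains one model per fold (fold held out for
validation/checkpointing) and `predict()` on the ensemble averages
**logits** across members before a single softmax — averaging
probabilities is a different operator and the tests pin the distinction.

## Event-based evaluation

`extract_events()` segments each non-null class's probability track at a
strict threshold (`p > 0.5`, half-open runs). `ward_categorize()` matches
detected against actual events by temporal overlap within class and
assigns the Ward categories — Correct, Deletions, Fragmented, Merged,
Fragmented-and-Merged on the actual side; Correct, Insertions,
Fragmenting, Merging, Fragmenting-and-Merging on the detected side —
with the conservation laws (categories partition both event sets)
verified against an independent brute-force matcher. The event F1 is
`f1e(TP, FP, FN) = 2 TP / (2 TP + FP + FN)` with TP the correct matches,
FP all spurious detections and FN all missed actuals.

## The synthetic generator

`generate_sensor_series()` draws unit-variance Gaussian background and
superimposes, per non-null class, a sinusoid of class-specific frequency
plus DC offset on a fixed channel subset during events of random
duration. Design points:

* Class signatures are drawn from the config's `signature_seed`, not the
  realization seed: series generated from the same `synth_config()` share
  class definitions, as train/validation/test splits of a real deployment
  would.
* Events never overlap and are separated by at least one null sample, so
  label runs and events correspond one to one.
* Missingness is drawn as contiguous bursts (geometric lengths) and
  recorded in a mask; `preprocess_series()` fills it by per-channel
  linear interpolation and standardizes with training-set statistics.

The generator is a *statistical regime* stand-in — dominant null class,
sporadic variable-length events, band-limited signatures, burst
missingness — not a simulator of any particular sensor suite; results on
it demonstrate the pipeline, not deployment accuracy.
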