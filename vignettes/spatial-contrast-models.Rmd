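---
title: "Modeling nonlinear spatial integration in retinal ganglion cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nonlinear spatial integration in retinal ganglion cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A retinal ganglion cell (RGC) pools signals from many bipolar cells. If
that pooling were linear, a classical linear–nonlinear (LN) model — one
spatiotemporal filter followed by a static output nonlinearity — would
capture the cell's responses. Many RGCs, however, pool *rectified* bipolar
inputs: fine spatial structure inside the receptive field (RF) that a
linear filter averages away still drives spikes. The classical signature is
frequency doubling under contrast-reversing gratings.

`retinasc` implements a compact model family for this phenomenon and the
full analysis chain around it:

* the **LN model**, `lambda_t = f(x_t)` with
  `x_t = sum_s u_s h_st`, where `h_st` is the stimulus convolved per pixel
  with the cell's temporal filter `v` and `u` is the spatial filter;
* the **spatial-contrast (SC) model**, which augments the LN drive with a
  local spatial contrast channel:
  `Imean_t = sum_s u_s h_st / sum_s u_s`,
  `LSC_t = sqrt(sum_s u_s (h_st - Imean_t)^2 / sum_s u_s)`, and
  `lambda_t = f(z(Imean_t) + w * z(LSC_t))` — a single extra parameter `w`
  measuring how much high-frequency spatial contrast inside the RF drives
  the cell (`w = 0` reduces the SC model to an LN model);
* a **subunit (LNLN) model**,
  `lambda_t = f_sub(sum_i p_i ReLU(q_i . h_t))`, whose spatial filters
  `q_i` are obtained from spike-triggered covariance (STC) analysis
  followed by a logical-OR transformation into localized subunits.

The output nonlinearity is the parameterized softplus
`f(x) = a log(1 + exp(b x + c))` (the subunit model drops `b`, which is
redundant with the weights `p`). All models are fitted by Poisson maximum
likelihood, `L = -sum n_t log lambda_t + sum lambda_t`, on responses
binned at the 85 Hz stimulus update rate.

## Stimuli and the synthetic world

Everything in the package can be exercised on synthetic data; no recordings
are required. The generators emulate the standard experimental stimuli:

* **Checkerboard white noise** (`gen_white_noise()`): binary squares at
  Weber contrast ±1, redrawn each frame. The reference configuration is
  30 µm squares (4 monitor pixels of 7.5 µm) at 85 Hz.
* **Reversing gratings** (`gen_reversing_grating()`): ±1 vertical stripes
  reversing every 500 ms, over a range of widths and phases.
* **Surrogate naturalistic movies** (`gen_surrogate_movie()`): spatially
  correlated frames built by frequency-domain filtering of Gaussian white
  fields with amplitude ∝ f^(−exponent/2), so the radially averaged power
  spectrum follows 1/f² as in natural scenes; slow temporal correlation
  (AR(1) with periodic scene refresh); affine mapping to an intensity range
  with a mean level at 76% of the white-noise level and a space-time RMS
  contrast of 45%, clipped at zero intensity; simulated gaze shifts; and a
  final per-pixel Weber conversion (subtract and divide by the pixel's
  temporal mean). The surrogate reproduces the second-order statistics of a
  naturalistic movie — not its objects, occlusions or motion streaks — so a
  green test establishes correct handling of 1/f² inputs, not performance
  on real movies. The realized RMS contrast is reported *before* gaze
  shifts; on small test canvases the gray border fill of shifted frames
  would otherwise dominate the statistic, and offsets are clamped to half
  the canvas (full-size frames are unaffected).
* **Gaze traces** (`simulate_gaze_trace()`): saccade amplitudes
  ~ Exponential(scale 200 µm), directions uniform, durations of 2–4 frames
  with probabilities (0.35, 0.4, 0.25); fixation durations of a 100 ms
  refractory period plus an Exponential(200 ms) tail; fixational jitter
  per frame update with 2-pixel per-axis SD; 10 s chunks with the offset
  reset to zero and chunks drifting beyond 200 pixels rejected (capped at
  1000 attempts). Offsets are rounded to whole pixels because frames can
  only shift by whole pixels; fixation durations round to at least one
  frame.

## Ground-truth cells

`make_model_cell()` builds an LNLN cell used as ground truth in every
recovery test: Gaussian subunits tiling a disc, a Gaussian pooling
envelope (3 σ equal to the RF diameter, matching the RF size convention),
a shared biphasic temporal kernel, ReLU or identity subunit nonlinearities,
and a softplus output whose gain is calibrated so the white-noise mean rate
hits a target (default 5 Hz). Two deliberate choices:

* **Subunit centers snap to the stimulus-square lattice.** A subunit
  integrates whole checkerboard squares. With fractional centers, a
  pixel-scale subunit smears across squares and roughly half of its
  squared-drive variance moves into pixel–pixel cross terms that no local
  contrast statistic can capture; the snapped geometry is both the
  physically sensible reading (the square is the resolution unit) and the
  one in which the SC model's advantage on rectified cells is expressed.
* **Default operating point** `(a, b, c) = (1, 2.5, −2)` before
  calibration: sparse, strongly stimulus-locked firing, typical of RGC
  responses to full-contrast checkerboards. Weakly modulated cells leave
  the STA below the 6-robust-SD pixel-selection threshold at desk-scale
  recording lengths.

The default temporal kernel keeps a sustained component (its taps sum to a
positive value). `biphasic_kernel(balanced = TRUE)` rescales the second
lobe so the taps sum to zero — a fully transient, parasol-like filter.
The reversing-grating analyses use the balanced kernel: frequency doubling
is a transient phenomenon, and a model cell without adaptation otherwise
responds to a grating with sustained, phase-asymmetric levels whose
fundamental swamps the doubled harmonic.

## Receptive-field estimation

`compute_sta()` computes the spike-triggered average over the last 30
frames (353 ms at 85 Hz), excluding spikes in the first 29 bins of each
trial. `extract_components()` selects pixels whose absolute temporal peak
exceeds the median by six robust standard deviations
(`1.4826 × MAD`, `robust_std()`), takes the temporal component as the mean
time course of selected pixels, projects the STA onto it for the spatial
component, crops 40 × 40 squares around the maximum-variance pixel, and
unit-normalizes both. `fit_gaussian_rf()` fits an elliptical Gaussian
(amplitude, center, σx, σy, rotation; no offset; moment initialization
from the positive part), zeroes the fit beyond the 3-σ ellipse, and
reports RF size as the diameter of the circle with the area of the 1.5-σ
ellipse. Upsampling to monitor resolution is nearest-neighbour.

## Fitting conventions

* **Z-scoring** uses training-segment statistics, stored with the fitted
  parameters and reused at prediction time; predicting without stored
  statistics is an error, which prevents silent train/test leakage.
* **LN/SC optimization**: L-BFGS-B with analytic gradients, inits
  `a = max(n_t)`, `b = 1`, `c = −2`, `w = 0`, bound `a ≥ 0`. The
  convolution-invalid bins (the first `M − 1` of each trial) are excluded
  from likelihoods and correlations.
* **Logical-OR / subunit training**: mini-batch Adam (batch 512) written
  in plain R with hand-derived gradients; learning rates 5e-3 and 1e-3;
  learning rate × 0.8 after 5 validation epochs without improvement; at
  most 500 epochs, early stop after 50 stale epochs; the lowest-validation
  state is kept. The plateau rule uses strict improvement (the reference
  scheduler's threshold is not stated). The validation split is the
  contiguous last 20% of training bins, which avoids temporal leakage.
  The Group-Lasso penalty `1e-4 × N_f / 400` on `sum_i ||q_i||_2` applies
  after a 50-epoch warm-up; because the STC basis is orthonormal,
  `||q_i|| = ||A_i||` and the penalty acts directly on the weight matrix.
  Subunits below 10% of the maximum norm are pruned and survivors
  unit-normalized, their pre-normalization norms seeding the subunit
  weights `p`; the subunit model then trains in two stages (ℓ1 on `p`
  with strength 1e-4, prune below 10% of the maximum weight,
  reinitialize, retrain unpenalized), with `p` clamped non-negative after
  each update.

A practical note on subunit counts: with a 16-subunit initialization the
first epochs inflate the norms of eventually-unused subunits (all subunits
initially chase the informative subspace before their thresholds
saturate), and the stated Group-Lasso strength does not reclaim them
within the epoch budget. The subunit *number* is therefore determined by
the subunit-model stage — exactly as in the stated workflow, where the
number of functional subunits is a hyperparameter optimized by the
subunit-model training — and the planted-cell recovery tests count
survivors there. Planted cells in those tests use sharply thresholded
subunits (logistic gain 16), the regime in which the 10% pruning rule
separates real from spurious subunits at desk scale.

## The spatial-scale scan

`scan_smoothing_scales()` refits the SC model after smoothing `h_st` with
a circular Gaussian before the LSC computation only (`Imean` is
unaffected; with a unit-sum kernel it is invariant anyway). Twenty filter
SDs from 0.8 to 12 pixels are scanned (scale defined as 3 σ, i.e.
18–270 µm at 7.5 µm pixels); performance per scale is the test-set Pearson
r relative to the unsmoothed fit; the optimum is located by interpolating
through the three points bracketing the discrete maximum at 0.1 µm
resolution. Three points underdetermine a cubic spline, so the unique
parabola is used; ties break toward the smaller scale. Smoothing uses
reflect padding and a kernel truncated at a six-SD support diameter. On a
simulated cell with 60 µm rectified subunits the profile peaks near
50 µm; under 1/f² surrogate movies it is flat (no scale improves the fit
by more than a few percent) — small in amplitude at desk scale (a percent
or two, versus tens of percent in real recordings) but reliably located.

## Statistics

* `reversing_grating_index()`: Fourier amplitudes of 1 s PSTHs at 1 Hz
  (F1) and 2 Hz (F2); the index is the largest F2 over conditions divided
  by the largest F1. The model-cell ordering test restricts the battery to
  stripe widths at or below the subunit scale: without adaptation the
  full-field fundamental dominates both cell types and the index stops
  discriminating; fine gratings are the classical probe of nonlinear
  summation.
* `rate_histogram_2d()` + `fit_softplus_family()` + `lsc_sensitivity()`:
  60 equal-count bins per axis with the first and last dropped; a joint
  least-squares fit of `f_i(x) = a log(1 + exp(b (x − c_i)))` with shared
  `(a, b)` (deterministic multi-start over log-scale offsets; analytic
  gradients); the LSC level of a row is its bin center; Local Outlier
  Factor (5 neighbours, score > 1.5) removal; ordinary least squares of
  `l_i` on `c_i`; sensitivity `= −1/m`. Estimation noise in `c_i` dilutes
  the regression slope and inflates `−1/m` for *any* cell, so the
  linear-vs-rectified ordering is validated on noiseless rate histograms,
  with a smooth-Gaussian-RF linear control.
* `rapsd()`: per-frame 2D DFT with 1/N normalization, power averaged in
  unit-width radial bins (bin = floor of the distance from DC), averaged
  over frames.
* `build_features_and_cluster()`: features = 30 temporal-filter taps, RF
  size, and 10 PCA scores of the per-entry Z-scored autocorrelograms;
  entries Z-scored across cells, PCA to 90% variance, KMeans++ (in-package
  seeding, 10 restarts, best inertia). Labels are a starting point for
  manual curation, which is out of scope.

## Numerical choices and degenerate inputs

Softplus is evaluated in the overflow-safe split form and is exact to
|bx + c| ≈ 1e3. `poisson_nll()` refuses zero rates with observed spikes.
`bin_spikes()` uses half-open `[t_i, t_{i+1})` bins. Autocorrelograms
exclude zero-lag self-pairs. Constant channels (zero SD) and all-zero
spatial filters are errors, not NaNs. All generators and trainers are
deterministic given their seed, and restore the caller's RNG state.

## What a green test establishes — and what it does not

The test suite demonstrates parameter and structure recovery on data
generated *by the model family itself* (plus Poisson noise), at recording
lengths of minutes. It establishes the correctness of the estimators and
the internal consistency of the pipeline. It does not establish that real
marmoset RGCs are described by these models, how large SC-over-LN gains
are in real recordings, or cell-type identities — those depend on
recordings this package does not ship. Two quantitative caveats recur:
at ~1,500 spikes the ML estimate of the softplus gain `a` carries ~10%
sampling noise, so the 10% recovery criterion sits at the edge of the
Fisher information; and desk-scale scan/index effect sizes are an order of
magnitude smaller than in hour-long recordings, so the tests assert
locations and orderings, not magnitudes.
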