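# retinasc

Spatial-contrast encoding models for retinal ganglion cells (RGCs), with a
fully synthetic test bench.

Many RGCs integrate visual space nonlinearly: rectified subunits (putative
bipolar-cell inputs) let fine spatial structure inside the receptive field
drive spikes even when it averages to nothing under a linear filter. This
package implements a minimal model family for that phenomenon and the
complete analysis chain around it, exercisable end-to-end on simulated
data:

* **Stimuli** — binary checkerboard white noise, contrast-reversing
  gratings, and surrogate naturalistic movies with 1/f² spatial power
  spectra and simulated gaze shifts (exponential saccade amplitudes,
  2-pixel fixational jitter).
* **Ground-truth cells** — LNLN model cells (Gaussian subunits, ReLU or
  linear, Poisson spiking) for parameter-recovery tests.
* **Receptive fields** — spike-triggered averages, spatial/temporal
  component extraction, elliptical Gaussian fits, autocorrelograms.
* **Encoding models** — the linear–nonlinear (LN) model
  `λ_t = f(Σ_s u_s h_st)` and the spatial-contrast (SC) model
  `λ_t = f(z(Imean_t) + w·z(LSC_t))`, where `h_st` is the temporally
  convolved stimulus, `Imean` its weighted mean over the receptive field,
  `LSC` the weighted standard deviation of pixel intensities (local
  spatial contrast), `f(x) = a·log(1 + exp(bx + c))`, fitted by Poisson
  maximum likelihood (L-BFGS-B, analytic gradients).
* **Subunit inference** — spike-triggered covariance, the logical-OR
  model `P_t = 1 − Π_i [1 − g_i(A_i·U h_st)]` trained with Adam and a
  Group-Lasso penalty, and the two-stage LNLN subunit model
  `λ_t = f_sub(Σ_i p_i ReLU(q_i·h_st))`.
* **Response statistics** — reversing-grating index (F2/F1), 2D firing
  rate histograms over (Imean, LSC), LSC sensitivity (−1/slope of the
  threshold-vs-contrast line, with Local-Outlier-Factor cleanup), the
  spatial-scale-of-nonlinearity scan, radially averaged power spectra,
  and cell-type feature clustering (PCA + KMeans++).

## Worked example

Simulate a midget-like rectified-subunit cell (seven 30 µm subunits in a
90 µm receptive field), estimate its receptive field from 300 s of
checkerboard white noise, fit LN and SC models, and compare them on a
frozen test segment:

```r
library(retinasc)

cell <- make_model_cell(n_subunits = 7, subunit_diameter_um = 30,
                        rf_diameter_um = 90, pixel_size_um = 30,
                        subunit_nl = "relu", mean_rate_target_hz = 10,
                        seed = 3)
wn   <- gen_white_noise(300 * 85, c(12, 12), pixel_size_um = 30, seed = 4)
rate <- cell_rate(cell, wn)
spk  <- sample_spikes(rate, 85, seed = 5)

sta   <- compute_sta(wn, spk)
comps <- extract_components(sta, crop_squares = 12)
gfit  <- fit_gaussian_rf(comps$spatial, pixel_size_um = 30)

conv  <- temporal_convolve(wn, comps$temporal)
fit_ln <- fit_encoding_model("LN", conv, gfit$filter, spk$counts[1, ])
fit_sc <- fit_encoding_model("SC", conv, gfit$filter, spk$counts[1, ])

# frozen test: 60 s repeated over 20 trials
wnt  <- gen_white_noise(60 * 85, c(12, 12), pixel_size_um = 30, seed = 6)
rt   <- cell_rate(cell, wnt, rate_scale = attr(rate, "rate_scale"))
psth <- colMeans(sample_spikes(rt, 85, n_trials = 20, seed = 7)$counts)
convt <- temporal_convolve(wnt, comps$temporal)
vi   <- 30:length(rt)
r_ln <- evaluate_prediction(predict_rate(fit_ln, convt)[vi], psth[vi])
r_sc <- evaluate_prediction(predict_rate(fit_sc, convt)[vi], psth[vi])
round(c(w = unname(fit_sc$params["w"]), r_ln = r_ln, r_sc = r_sc,
        ratio = r_sc / r_ln), 4)
```

Output (printed by this code):

```
     w   r_ln   r_sc  ratio
0.4429 0.6893 0.7392 1.0723
```

The SC model assigns the local-contrast channel a clearly positive weight
(`w ≈ 0.44`) and predicts the held-out response ~7% better than the LN
model — the signature of nonlinear spatial integration. Rebuilding the
same cell with `subunit_nl = "linear"` drives `w` to ~0.02 and the ratio
to ~1.00. A smoothing-scale scan (`scan_smoothing_scales()`) on a cell
with 60 µm subunits peaks at ≈ 50 µm, between half and twice the subunit
diameter.

## Command line

A thin CLI is installed as `exec/retinasc`:

```sh
retinasc simulate whitenoise --config cfg.json --seed 1 --out stim.txt
retinasc simulate cell --cell-config cell.json --stimulus stim.txt \
         --trials 5 --seed 2 --out spikes.csv
retinasc fit --model sc --stimulus stim.txt --spikes spikes.csv --out fit.json
retinasc analyze rapsd --stimulus stim.txt --out rapsd.json
```

Stimulus containers are plain text (JSON metadata line + one
full-precision frame per line); spike files are CSV with columns
`trial,time_s`.

See the vignette (`vignettes/spatial-contrast-models.Rmd`) for the model
definitions, fitting protocols, design decisions and the limits of what
the synthetic tests establish.
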