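---
title: "Pixel-wise perfusion quantification with surface-coil intensity correction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-wise perfusion quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(perfquant)
```

This vignette documents the models behind `perfquant`, the tunable
parameters and their defaults, what the synthetic phantom does and does not
emulate, and the numerical and design choices a maintainer would want
explained.

## 1. The pipeline

A first-pass perfusion study consists of a dynamic saturation-recovery SSFP
series (one short-axis frame per heartbeat, about 60 frames), a
proton-density-weighted (PD) reference frame acquired without saturation
preparation at a low flip angle, and a separate low-resolution series for
arterial input function (AIF) sampling. Quantification proceeds:

1. **Surface-coil intensity correction** (`run_scic()`): estimate the
   multiplicative receive-coil gain and divide it out, or perform baseline
   normalization only.
2. **AIF extraction** (`extract_curve()`, `detect_foot()`,
   `signal_to_concentration()`): mean blood-pool signal over time,
   contrast-arrival detection, linear conversion to concentration.
3. **Pixel-wise deconvolution** (`mbf_map()`): per-pixel tissue curves are
   converted to concentration and fit by Fermi-model-constrained
   deconvolution; flow is the fitted impulse response's initial height.
4. **Regional statistics** (`sectorize()`, `heterogeneity()`,
   `remote_ischaemic_difference()`, ...): AHA sectors, coronary
   territories, and the comparison statistics.

## 2. Bias-field estimation

The coil gain is modelled as a smooth multiplicative field. Following
standard practice, it is estimated from a reference image in which tissue
of similar intrinsic intensity covers the thorax: the myocardial ROI plus a
body ROI restricted, by an intensity band, to pixels between
`lo_frac = 0.5` and `hi_frac = 2` times the myocardial median — excluding
lung (too dark) and fat (too bright), whose inclusion would drag the fit
and amplify noise where sensitivity is low.

A full third-order 2D polynomial (10 coefficients) is fit by unweighted
ordinary least squares on coordinates affinely normalized to `[-1, 1]^2`
(for conditioning; the normalization is invertible and recorded). The
fitted surface, evaluated on the whole grid, is floored at `1e-3` of its
mask-union mean — the fit is an extrapolation outside the fitted tissue and
may dip toward zero; without the floor, division could amplify background
noise unboundedly. The field is then normalized to unit mean over the
myocardium, so correction never rescales mean myocardial signal; any
consistent scalar would do because baseline normalization follows.

Two reference choices are supported. The PD frame (`mode = "pd"`) has high
signal and little tissue contrast, giving the cleanest gain estimate. The
first pre-contrast saturation-prepared frame of the perfusion series itself
(`mode = "ssfp"`, frame index configurable, default the first baseline
frame) requires no extra acquisition but carries lower signal and
saturation-weighted tissue contrast (T1 differences between myocardium,
blood and body leak into the fit), so its correction is systematically
noisier — the behaviour the mode comparison is designed to expose. Fitting
is done on raw intensities (not log), matching the multiplicative-gain
model only to first order but avoiding bias from low-signal pixels.

## 3. Signal model and concentration conversion

The conversion from signal to concentration is linear
(`C = (S - S_baseline) / scale`, clipped at zero): appropriate when the
readout operates in its near-linear regime and standard in pixel-wise
perfusion work. The calibration `scale` maps baseline-normalized signal
change to mmol/L. For a saturation-recovery readout
`S = s0 (1 - exp(-TS (R1_0 + r C)))`, the slope at `C = 0` of the
baseline-normalized signal is

```
scale = TS * r * exp(-TS * R1_0) / (1 - exp(-TS * R1_0))
```

(`sr_linear_calibration()`), independent of `s0` and coil gain. The
pipeline computes one constant for tissue (myocardial `R1_0`, perfusion
`TS`) and one for the AIF series (blood `R1_0`, short AIF `TS`); in a real
deployment both follow from the sequence parameters and literature
relaxation rates, exactly as here. Tissue curves are baseline-subtracted
per pixel but *not* per-pixel normalized — per-pixel normalization would
itself be a (rough) coil correction and would confound the mode
comparison.

The per-pixel tissue foot is taken from the mean myocardial curve
(per-pixel detection would be noise-limited); the foot rule is
`baseline_mean + max(3 * baseline_SD, 0.05 * (peak - baseline_mean))` over
the first `n_baseline = 4` frames.

## 4. Fermi-constrained deconvolution

The tissue model is `Ct(t) = (Ca * R)(t)` with the Fermi impulse retention
function `R(t) = F / (1 + exp(k (t - td - w)))` for `t >= td` (0 before),
the standard constrained model for first-pass CMR. MBF is the initial
height `R(td) = F / (1 + exp(-k w))`, converted to mL/min/g by x60 (per
second to per minute) and /1.05 (myocardial density g/mL). The package
reports mL/min/g, the conventional unit for the magnitudes involved.

Numerics, all deterministic:

* The discrete convolution is trapezoidal on the uniform frame grid
  (`conv_matrix()`), so the model is a matrix-vector product; a double-loop
  summation oracle verifies it exactly in the tests.
* The amplitude is profiled out analytically (linear least squares, clamped
  to `[0, 0.5] s^-1`), leaving a 3-parameter problem in `(k, w, td)` with
  bounds `k in [0.02, 5] s^-1`, `w in [0, 30] s`, `td in [0, 10] s`.
* A coarse 7 x 7 x 6 parameter grid is evaluated for every pixel at once
  (one matrix product); the best `multistart = 6` cells seed bounded
  Nelder-Mead refinements (clamped-box, run twice to escape collapsed
  simplices; C++ core). Ties are broken by lowest residual, then lowest
  delay. There is no random restart, so identical inputs give identical
  maps.
* Convergence uses a relative tolerance (`1e-12`) plus an absolute floor
  scaled by the data's sum of squares, so exact (zero-residual) fits
  terminate cleanly.
* The least squares is restricted to a **first-pass window**: frames up to
  `fit_window_s = 15` s past the detected foot. This is the classical
  restriction of Fermi deconvolution (in vivo it avoids recirculation).
  It also matters numerically: on one-compartment (mono-exponential
  washout) curves, fitting the full 60-s window lets the tail dominate the
  residual, the fitted shoulder collapses to `w = 0`, and the initial
  height reads roughly 12% low; the first-pass window keeps the
  cross-model bias within about 10% across the 0.5-3 mL/min/g range.

One identifiability caveat: with the hard cutoff at `td` and frames every
`dt`, all delays within one frame interval that keep `td + w` constant
yield *identical* discrete models, so `td` is only determined to within a
frame and the readout `F / (1 + exp(-k w))` varies a few percent along that
ridge. Exact-recovery tests therefore generate with `td = 0`, where the
model is fully identifiable; with measured data the ambiguity is one more
contributor to pixel-level noise, not a bias.

## 5. The phantom: what it emulates, what it does not

`generate_phantom()` produces the dual-sequence study on a 128 x 128 grid
(annulus radii 28/40 px, LV pool 24 px, body ellipse with lung-like dark
regions), 60 frames at a 1-s R-R interval. The bolus is a gamma-variate
(`t0 = 8 s`, `alpha = 2.5`, `beta = 4 s`) peaking at 4 mmol/L in blood,
typical of a compact 0.05 mmol/kg injection. Tissue kinetics follow the
one-compartment Kety model `R(t) = f exp(-f t / vd)` with
`vd = 0.15 mL/g` and stress-level flow defaults of 2 mL/min/g —
**deliberately a different model family from the Fermi quantifier**, so
recovery tests measure honest cross-model error rather than
self-consistency. Tissue concentration is expressed per mL of tissue
(x1.05 g/mL) so the generator and the quantifier's density convention
agree.

Signals pass through a generic saturation-recovery stand-in
(`signal_model_params()`): `TS = 0.05 s` (tissue readout), `TS = 0.005 s`
for the AIF series — short enough that its signal is effectively linear up
to the 4 mmol/L peak (<4% compression), consistent with the low-resolution
dual-sequence design in which the AIF readout is kept in the linear
regime. Relaxation defaults are 1.5-T literature scale (R1_0: myocardium
1.0, blood 0.625, body 1.4, lung 0.8 s^-1; relaxivity 4.5 L/mmol/s); the
PD frame is `0.25 * s0 * gain`. These are stand-in values, exposed so
users can substitute their own protocol.

The coil gain is a sum of exponential lobes (`coil_gain_field()`). The
`anterior_coil_preset()` places one lobe above the top edge, offset toward
the anteroseptal side, giving sector-mean gain ratios of about 2.1:1
anterior:inferior and 1.55:1 LAD:remote — strong enough that, with a 30%
LAD flow deficit, uncorrected quantification *reverses* the apparent
remote-ischaemic contrast. With this preset the uncorrected
septal-lateral difference is positive but small; a large septal inflation
would require a different coil layout, and the preset prioritizes the
territory-level phenomenon. Noise is Rician (magnitude images), with SNR
defined as baseline myocardial signal over the Gaussian sigma, default 20;
the PD frame shares the noise sigma and so has proportionally higher SNR,
as in practice.

Not emulated: cardiac or respiratory motion (the real pipeline's
registration steps are out of scope; the phantom is motion-free),
dark-rim/Gibbs artifacts, parallel-imaging noise structure, AIF
saturation (the linear AIF regime removes the need for its correction),
multi-slice coverage, and rest imaging. Passing tests therefore validate
the estimation chain — bias fitting, conversion, deconvolution, statistics
— under a controlled forward model, not robustness to motion or artifact.

## 6. Regional statistics

Sectorization assigns each myocardial pixel by polar angle about the
cavity centre into six 60-degree sectors, clockwise from the anterior RV
insertion angle (default -60 degrees in the anterior-up display), in the
order anterior, anterolateral, inferolateral, inferior, inferoseptum,
anteroseptum; territories group sectors {1,6} = LAD, {2,3} = LCX,
{4,5} = RCA. Design choices, each made where the convention was genuinely
open: sample (n-1) standard deviations throughout; territory means are
unweighted means of sector means (so unequal pixel counts do not bias
territories); septal = mean(anteroseptum, inferoseptum) and lateral =
mean(anterolateral, inferolateral); the paired t-test is the closed form
on differences with `df = n - 1`, reported to full precision with a
3-decimal display value, and no multiple-testing correction is applied.
A territory assignment must leave at least one non-diseased territory —
with all three diseased there is no remote reference and the difference is
undefined.

## 7. Validation problem sizes

The replicate experiments in the test suite and `scripts/acceptance.R` use
a 48 x 48 phantom (annulus radii 10/16, ~490 myocardial pixels, 60
frames): large enough for stable sector statistics, small enough that 100
replicates x 3 modes of full pixel-wise quantification run in a few
minutes on one CPU. Bias-recovery studies use 64 x 64 with an in-model
cubic gain. The defaults of `phantom_spec()` itself (128 x 128) are the
acquisition-scale geometry. The noise-bias property uses a 52 x 52 annulus
(>500 pixels).

## 8. Known limitations

* The linear conversion understates tissue concentration by a few percent
  at peak enhancement with the default `TS = 0.05 s`; with the first-pass
  window this partially offsets the Fermi-on-Kety readout bias. Users
  fitting other protocols should check the regime or supply their own
  calibration.
* Delay is only frame-resolved (Section 4).
* The SSFP reference-frame index is a convention (first baseline frame);
  a study with contrast arriving during the first frames would need it
  adjusted.
* One slice per run; multi-slice studies loop at the caller level.
* The t-test utilities compare modes across studies; no subject-level
  covariates or mixed models are provided.
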