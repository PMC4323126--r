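# perfquant

Pixel-wise myocardial blood flow (MBF) quantification for first-pass
contrast-enhanced cardiac MR perfusion imaging, with surface-coil intensity
correction (SCIC) and a digital perfusion phantom for validation.

## The problem

Quantitative perfusion CMR estimates myocardial blood flow (mL/min/g) at
every myocardial pixel by deconvolving the arterial input function (AIF)
from tissue contrast-enhancement curves. Phased-array surface coils,
however, impose a smooth multiplicative gain on the images — typically
brighter anteriorly, darker inferiorly. Because one AIF serves the whole
myocardium, this spatial gain maps directly into spatial MBF error: flow
appears inflated where the coil is sensitive and depressed where it is not,
to the point of inverting the apparent contrast between a stenosed coronary
territory and remote myocardium. `perfquant` implements the quantification
pipeline together with three correction strategies and the statistics used
to compare them:

* **PD-SCIC** — a third-order 2D polynomial surface is fit by ordinary
  least squares to myocardial + body-tissue intensities of a
  proton-density-weighted reference frame; the fitted bias field `B(x, y)`
  (unit mean over the myocardium) is divided out of the dynamic series.
* **SSFP-SCIC** — the same fit applied to a pre-contrast baseline frame of
  the saturation-prepared SSFP perfusion series itself.
* **No-SCIC** — baseline normalization only (division by the mean
  myocardial signal of the first pre-contrast frames).

After correction, per-pixel signal curves are converted to contrast
concentration (linear model, baseline subtraction), and pixel-wise MBF is
estimated by model-constrained deconvolution with the Fermi impulse
retention function

```
R(t) = F / (1 + exp(k (t - td - w))),   t >= td,
MBF  = R(td) = F / (1 + exp(-k w))      (x 60 / 1.05 -> mL/min/g)
```

fit by bounded nonlinear least squares of `tissue(t)` against
`(AIF * R)(t)` over the first pass of the bolus, with the amplitude
profiled out analytically and a deterministic multistart Nelder-Mead
search (C++ core) over the remaining parameters.

The package also provides AHA sectorization (six 60-degree mid-ventricular
sectors anchored at the anterior RV insertion point), coronary territory
mapping (anterior + anteroseptum = LAD, anterolateral + inferolateral =
LCX, inferior + inferoseptum = RCA), myocardial signal CoV, MBF spatial
heterogeneity (100 x SD/mean of pixel MBF), septal-lateral and
remote-ischaemic differences, and paired t-tests.

Because no patient data ship with the package, a **digital phantom**
(`generate_phantom()`) emulates the dual-sequence acquisition: a 60-frame
saturation-recovery SSFP series (one frame per R-R interval), a
proton-density reference frame, a low-resolution near-linear AIF series, a
gamma-variate bolus, one-compartment Kety tissue kinetics (deliberately a
different model family than the Fermi quantifier), an anterior-weighted
coil gain field, and Rician noise — all with known ground truth.

## Worked example

Simulate a stress study with a 30% LAD-territory flow deficit
(LAD 1.4, LCX/RCA 2.0 mL/min/g) under an anterior coil gain
(~2:1 anterior:inferior), then quantify with and without correction:

```r
library(perfquant)

spec <- phantom_spec(grid_shape = c(48, 48), myo_radii_px = c(10, 16),
                     lv_radius_px = 8, snr = 20, seed = 7,
                     territory_mbf = c(LAD = 1.4, LCX = 2, RCA = 2))
study <- generate_phantom(spec)

assn <- territory_assignment("LAD")
for (mode in c("none", "pd")) {
  q  <- quantify_study(study, mode)
  sm <- sector_stats(q$map, q$labels)
  ri <- remote_ischaemic_difference(sm, assn)
  cat(sprintf("%-5s heterogeneity %5.1f%%  remote %.2f  ischaemic %.2f  diff %+.2f mL/min/g\n",
              mode, heterogeneity(q$map), ri$remote, ri$ischaemic, ri$difference))
}
```

```
none  heterogeneity  20.7%  remote 1.71  ischaemic 1.88  diff -0.18 mL/min/g
pd    heterogeneity  17.8%  remote 2.03  ischaemic 1.43  diff +0.59 mL/min/g
```

Without correction the diseased LAD territory *appears better perfused
than the remote myocardium* (difference −0.18 mL/min/g — the wrong sign),
because the anterior gain inflates the anterior/anteroseptal sectors.
PD-based correction restores the true contrast (+0.59 vs a ground truth of
+0.60 mL/min/g) and lowers pixel-wise heterogeneity. The fitted map prints
as:

```
<mbf_map_result> 496 myocardial px, 496 converged, MBF 1.83 +/- 0.33 mL/min/g
```

The same pipeline runs end to end from the shell:

```sh
exec/perfquant run-all --config inst/extdata/demo_config.json --out out/demo
```

writing the simulated study, per-mode bias fields, corrected series, MBF
maps, diagnostics and `report.json`.

## Layout

* `R/` — domain types and I/O (`core-types.R`, `io.R`), phantom
  (`phantom.R`), correction (`scic.R`), deconvolution (`kinetics.R`),
  statistics (`regional-stats.R`, `report.R`), orchestration
  (`pipeline.R`)
* `src/` — compiled Fermi-deconvolution fitting core
* `vignettes/perfusion-quantification.Rmd` — methods and design notes
* `exec/perfquant` — command-line interface
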