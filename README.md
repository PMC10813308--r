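# specklegram

Simulation, correlation demodulation and CNN quantification of multimode
fiber specklegram biosensor data for label-free measurement of the tumor
biomarker CEACAM5.

## The problem

A tapered multimode fiber carries a few dozen guided modes whose
interference at the output face forms a granular intensity image — a
specklegram. When the taper waist is functionalized with antibodies,
binding of CEACAM5 antigen shifts the refractive index sampled by the
evanescent field, perturbing the modes' phases and powers. The speckle
pattern decorrelates from its 0 ng/mL baseline, and the amount of
decorrelation encodes the antigen concentration.

This package implements the complete analysis chain:

1. **Forward simulator** — seeded, physically motivated specklegram
   generator: orthonormal surrogate mode basis, coherent mode
   superposition `I = |Σ aₘ ψₘ exp(iφₘ)|²`, Hill-type dose response
   driving per-mode phase shifts and one power-conserving mode-coupling
   step, shot + read camera noise, 16-bit quantization.
2. **Preprocessing** — grayscale, unit-range normalization, block-mean
   downsampling (1280×1024 → 320×256 → 80×64).
3. **ZNCC demodulation** — zero-mean normalized cross-correlation of each
   probe against the baseline reference; dose-response curves of mean
   ZNCC per concentration.
4. **Calibration** — four-parameter logistic fit over the full
   1–1000 ng/mL panel, ordinary-least-squares fit over the quasi-linear
   1–50 ng/mL sub-range (its |slope| is the *surface sensitivity* in
   (ng/mL)⁻¹), and closed-form inversion of either fit back to
   concentration.
5. **CNN quantifier** — a compact 2D convolutional network (3 conv
   blocks, 16/32/64 filters) classifying specklegrams into the
   9-concentration panel `{1, 5, 10, 20, 30, 50, 100, 500, 1000}` ng/mL
   and decoding a continuous estimate as the probability-weighted mean of
   class concentrations. Implemented in vectorized base R (no framework
   dependency), gradient-checked against finite differences.
6. **Pipeline** — one-call orchestration `run_all()` with YAML
   configuration, CSV manifests, JSON metrics and full seed fan-out, plus
   a CLI front end in `inst/scripts/specklequant.R`.

## Worked example

Measure the surface sensitivity over the 1–50 ng/mL sub-panel (10 frames
per concentration at the default desk-scale 320×256 resolution) and invert
a measured ZNCC back to a concentration:

```r
library(specklegram)

cfg <- default_config()
run <- surface_sensitivity_run(cfg, seed = 1, n_per_conc = 10)
run$curve
#>   concentration_ng_per_ml mean_zncc      sd_zncc  n
#> 1                       1 0.9996558 1.554489e-05 10
#> 2                       5 0.9984576 8.811254e-05 10
#> 3                      10 0.9948700 1.637815e-04 10
#> 4                      20 0.9835972 2.242343e-04 10
#> 5                      30 0.9682914 4.279940e-04 10
#> 6                      50 0.9332524 6.024217e-04 10

run$sensitivity
#> [1] 0.00137809            # (ng/mL)^-1

invert_concentration(run$fit, 0.975)
#> $estimate
#> [1] 22.73471
#> $extrapolated
#> [1] FALSE
```

The full pipeline — 900-image dataset (100 per class, stratified
50/25/25% train/validation/test), correlation curve over all 9 classes,
4PL + linear calibration, CNN training and evaluation — runs in about
7 minutes on one CPU:

```r
report <- run_all(default_config(), seed = 1, verbose = TRUE)
report
#> <metrics_report>
#>   dataset: 900 images (train 450 / validation 225 / test 225)
#>   surface sensitivity: 0.0013799 (ng/mL)^-1 over [1, 50] ng/mL
#>   CNN: max rel. error 2.9240%, decoded~true slope 0.99991
```

The network reaches 100% classification accuracy on all three splits
within the 30-epoch budget and its decoded-vs-true regression slope is
within 10⁻⁴ of 1. The *maximum* per-image relative error, however, is a
few percent rather than sub-percent: expected-value decoding turns
residual softmax leakage directly into concentration error, and the fixed
epoch budget leaves worst-case confidence near 0.95 (see the methods
vignette, `vignettes/methods.Rmd`, for the analysis).

Datasets can also be written to disk as 16-bit TIFF plus a CSV manifest
and regenerated bit-identically from the same seed:

```r
ds <- generate_dataset(default_config(), seed = 1, dir = "dataset")
```

## Configuration

All study conditions live in one nested list (`default_config()`),
serializable to YAML. `default_config(desk_scale = TRUE)` (the default)
renders directly at 320×256; `desk_scale = FALSE` renders the native
1280×1024 and downsamples ×4. Unknown or invalid keys are rejected by
name. The single calibrated generator parameter is
`dose$response_max = 0.93`, set by `calibrate_response_max()` so that the
simulated surface sensitivity lands at 0.0012 (ng/mL)⁻¹; everything else
is fixed a priori.
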