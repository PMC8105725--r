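# myddoquant

Quantification of Myddosome assembly dynamics from live-cell single-molecule
TIRF imaging, as a tidy, tested R pipeline.

## What this is for

Myddosomes — oligomers of the adaptor MyD88 with the IRAK4/IRAK1 kinases —
assemble at the plasma membrane downstream of IL-1 receptor activation and
appear in TIRF movies as diffraction-limited GFP puncta. Deciding whether a
punctum is a transient few-monomer assembly or a grown, stable,
signalling-competent oligomer, and relating size to lifetime, kinase
recruitment, molecular turnover and NF-κB/p38 activation, is an image
quantification problem. This package implements that quantification for
anyone analysing single-molecule assembly data of this kind:

- **Preprocessing** — dark-frame subtraction, disk-median rolling-background
  subtraction (radius 25 px), illumination correction for wide-field
  fixed-cell images (radius 100 px median blur of the mean image).
- **Puncta tracking** — Laplacian-of-Gaussian spot detection at the PSF
  scale with noise-scaled thresholds and sub-pixel localisation, greedy
  mutual-nearest-neighbour linking with gap closing, 3×3-pixel intensity
  measurement, minimum-length filtering, cell assignment.
- **Stoichiometry** — single-GFP unit-intensity calibration (robust
  mean/SD after a median ± 5 MAD screen); the N-mer intensity model
  `I_n ~ Normal(n·μ, n·σ²)`; closed-form threshold-capture probabilities;
  classification of puncta as small/large at a maximum intensity of 4.5×
  GFP (inclusive).
- **Track analytics** — lifetimes (`frames × Δt`, short/long at 50 s),
  normalized growth `(max − initial)/μ` for tracks starting below 2.5×
  GFP, Spearman lifetime–growth correlation, per-cell summaries.
- **Colocalization** — two-channel track pairing at ≤ 0.25 µm over ≥ 2
  consecutive frames, one-to-one assignment, recruitment delays from
  nucleation.
- **FRAP** — the standard double-normalization
  `(I(t) − I(0)) / (I(pre) − I(0))`, recovery statistics, trace averaging.
- **Fixed-cell scoring** — DAPI/marker watershed segmentation, the
  radius / eccentricity / crowding / border quality screens, nuclear and
  nuclear:cytoplasmic stain readouts, normalization to unstimulated cells.
- **Synthetic data** — a TIRF-movie generator with exhaustive ground truth
  (two-population assembly kinetics, per-fluorophore brightness, Poisson +
  read-noise camera, partner channel, calibration stacks, FRAP traces,
  fixed-cell fields), used to validate every stage.

All user-facing functions take data frames first and return tibbles, so the
stages chain with the pipe; results have `ggplot2` plot helpers and the
calibration model has broom-style `tidy()`/`glance()` methods.

## The core model

Copy number is intensity in single-GFP units. A punctum of `n` fluorophores
has intensity `I_n ~ Normal(n·μ, n·σ²)` where `μ`, `σ` come from single
GFP fluorophores on glass measured with the *identical* pipeline (same
filters, same 3×3 window — so the window's capture fraction cancels). At
calibration CV 0.25, a 4.5× maximum-intensity threshold captures

```
P(I_6 ≥ 4.5 μ) = 1 − Φ((4.5 − 6) μ / (√6 σ)) = 99.3 %
```

of hexamers while passing essentially no dimers (tail at z ≈ 7), which is
what makes the small/large dichotomy usable.

## Worked example

Simulate a calibration stack and a live-cell movie, then run the full
pipeline:

```r
library(myddoquant)

# 1. calibrate the single-GFP unit on a simulated glass stack
cal <- simulate_calibration_stack(
  sim_config(image_shape = c(128, 128), n_frames = 10, seed = 3),
  n_emitters = 60)
model <- calibrate_stack(cal$movie)
model
#> <calibration_model> mu = 67.88 ADU, sigma = 16.60 (CV 0.244), n = 572

# 2. simulate and track a movie of assembling puncta
cfg <- sim_config(image_shape = c(128, 128), n_frames = 120,
                  nucleation_rate = 0.5, seed = 11)
sim <- simulate_puncta_movie(cfg)
tracks <- track_movie(sim$movie)

# 3. classify sizes, compute lifetimes and growth, summarise
metrics <- track_metrics(tracks, model, frame_interval_s = 1)
summarize_cells(metrics)
#> # A tibble: 1 × 8
#>   cell_id n_tracks pct_large pct_small pct_large_short pct_large_long ...
#> 1       0       31      16.1      83.9            13.3            100

lifetime_growth_correlation(metrics)
#> # A tibble: 1 × 3
#>   spearman_r  p_value n_tracks
#> 1      0.723 0.000690       18

fraction_above_threshold(model, n = 6, k = 4.5)
#> [1] 0.9938713
```

The numbers mean: the measured unit intensity is ~68 ADU (the 3×3 window
captures ~0.68 of a spot rendered at 100 ADU — the fraction cancels in
normalized units, note the recovered CV ≈ 0.25); 16 % of tracked puncta
ever reach 4.5× GFP, but 100 % of the long-lived (≥ 50 s) ones do while
only 13 % of short-lived ones do; growth and lifetime are strongly rank
correlated (R = 0.72) — the small/transient vs growing/stable
two-population picture the classifier is built around.

## Package layout

```
R/                  implementation (simulators, preprocess, tracking,
                    stoichiometry, metrics, coloc, FRAP, fixed-cell, plots)
src/                Rcpp disk-median filter
tests/testthat/     unit + property + acceptance tests
scripts/acceptance.R
vignettes/myddosome-quantification.Rmd   methods and design rationale
```
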