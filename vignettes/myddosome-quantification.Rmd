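---
title: "Quantifying Myddosome assembly from single-molecule TIRF imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Myddosome assembly from single-molecule TIRF imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myddoquant)
library(dplyr)
```

## The scientific problem

Innate-immune signalling through IL-1 family receptors proceeds via the
Myddosome, a defined oligomer of the adaptor MyD88 and the IRAK4/IRAK1
kinases. In live-cell TIRF microscopy of cells on ligand-functionalised
supported lipid bilayers, MyD88-GFP appears as diffraction-limited puncta at
the plasma membrane. Two behaviours are observed: most puncta are small
(one to a few monomers) and transient, while a minority grow, persist and
recruit downstream kinases. Deciding which class a punctum belongs to — and
relating size, lifetime, partner recruitment, molecular exchange (FRAP) and
downstream NF-κB/p38 activation — is entirely an image-quantification
problem. This package implements that quantification as a tidy, tested R
pipeline, together with a synthetic-movie generator with exhaustive ground
truth so that every stage can be validated without the original imaging
data.

## The measurement model

### From photons to copy numbers

A punctum containing $n$ fluorophores has integrated intensity
$I_n = \sum_{j=1}^n b_j$ where each fluorophore brightness $b_j$ is
approximately $\mathcal N(\mu, (c\mu)^2)$ with unit intensity $\mu$ and
coefficient of variation $c$. Consequently

$$I_n \sim \mathcal N\!\left(n\mu,\; n (c\mu)^2\right),$$

i.e. mean **and variance** scale $n$-fold, and the relative noise shrinks
as $1/\sqrt n$. The unit $\mu$ is calibrated from single GFP fluorophores
adsorbed to clean glass, measured with *exactly the same* pipeline as
cellular puncta (dark-frame subtraction, rolling-median background
subtraction, LoG detection, tracking, and a 3×3-pixel intensity sum). The
3×3 window captures only a fraction of the PSF (about 0.68 for a centred
spot at `psf_sigma_px = 1.1`; the exact value is the Gaussian integral over
the window), but because the same window is applied to the calibration
emitters the capture fraction cancels in normalized units. This is also why
the intensity readout is a **sum**, not a mean.

`calibrate()` estimates $\mu$ and $\sigma$ by a plain mean/SD after
discarding samples outside median ± 5×MAD (scaled MAD, so the screen sits
at ≈5 Gaussian SDs and removes aggregates and hot pixels without truncating
a Gaussian sample). At least 30 retained samples are required.

### The 4.5× classification threshold

Crystal structures contain 6–8 MyD88 protomers, so a "large oligomer" is
operationally a punctum whose maximum intensity reaches $4.5\mu$
(`classify_tracks()`, boundary inclusive). Under the model above the
captured fraction of hexamers is the closed-form Gaussian tail

$$P(I_6 \ge 4.5\mu) \;=\; 1-\Phi\!\left(\frac{(4.5-6)\mu}{\sqrt6\,c\mu}\right),$$

which `fraction_above_threshold()` evaluates: 99.3 % at $c = 0.25$ and above
98 % for every $c \le 0.29$, while dimers are essentially never captured
(tail at $z \approx 7$). The threshold therefore excludes monomers through
trimers while keeping essentially all hexamers; tetramers and pentamers are
partially selected, which is inherent to any single-threshold rule.

### Lifetimes, growth, and their coupling

Track lifetime is `n_frames_observed × frame_interval_s`. With the
three-frame minimum track filter at 1 s intervals the shortest observable
lifetime is 3 s, which fixes the convention (not `(n-1) × dt`). Lifetimes
are classed short/long at 50 s (inclusive on the long side). Growth is
`delta_norm = (max − initial)/μ`, computed only for tracks whose initial
normalized intensity is strictly below 2.5: brighter starts are likely
fission products of pre-existing assemblies whose nucleation time is
unknown, and are excluded rather than mis-scored. Coupling between growth
and lifetime is summarised by Spearman rank correlation with average ranks
for ties and a large-sample t approximation for the p-value (track counts
are in the thousands in a typical experiment). Tracks still present in the
final movie frame are flagged right-censored and retained.

### Two-channel colocalization and recruitment timing

A MyD88 track is partner-positive when some IRAK track stays within
0.25 µm (inclusive) for at least two *consecutive* frames observed in both
channels; a gap in either channel breaks the run — the strictest reading of
"consecutive". Distances are computed on sub-pixel physical coordinates
because 0.25 µm is under two pixels. Assignment is one-to-one: each
partner track serves at most one reference track, longest qualifying run
first, ties resolved in favour of the earlier-nucleating reference track.
Recruitment time is the delay from reference-track nucleation to partner
appearance; a partner that pre-dates its reference track yields a negative
value that is flagged and excluded from recruitment-time distributions.

### FRAP normalization

Traces are normalized as
$(I(t) - I(0)) / (I(\text{prebleach}) - I(0))$ with $I(\text{prebleach})$
the mean of the prebleach samples and $I(0)$ the single first post-bleach
sample. The normalized trace is 1 before the bleach and 0 at the floor;
negative values are allowed (no clipping), so an immobile structure can
legitimately report a slightly negative recovery. `frap_average()` aligns
traces at the bleach and reports a pointwise mean ± SD, interpolating
linearly when sampling grids differ.

### Fixed-cell nuclear-translocation scoring

Fixed-cell fields are corrected in the order dark → illumination →
background. Nuclei come from the DAPI channel (Otsu threshold, touching
objects split by a watershed on the distance map); cell bodies are grown
from the nucleus seeds over the thresholded marker channel by
marker-controlled propagation; cytoplasm is the body minus the nucleus.
Debris and aggregates are screened by: nucleus equivalent-circle radius in
5.5–10 µm; cytoplasm radius < 15 µm; ellipse axis ratios ≤ 1.66 (nucleus)
and ≤ 2.25 (cytoplasm); at most 5 nuclei within 16 µm of the nuclear
centroid; and no contact with the image border. "Radius" is the
area-equivalent circle radius, the standard scalar for non-circular
watershed regions, and the neighbour count includes the cell itself —
under that convention a cluster of six nuclei within 16 µm is rejected in
its entirety, which is the behaviour the screen is designed for. Each rule
is individually toggleable and `pass_filters` is their conjunction. The
readouts are the nuclear mean stain (e.g. phospho-p38), the
nuclear:cytoplasmic ratio (e.g. RelA translocation), and normalization of
per-cell values to the median of the day's unstimulated cells.

## The synthetic generator

`sim_config()` defines the study conditions: 150 nm pixels, 1 s frame
interval, a Gaussian PSF of 1.1 px SD (slightly above the diffraction
limit, absorbing residual defocus and camera blur), single-GFP unit
intensity 100 ADU with CV 0.25, camera offset 100 ADU, Gaussian read noise
2 ADU, Poisson shot noise, and a uniform cytosolic background of 20 ADU.
Oligomer kinetics are a two-population birth–death walk on monomer count:
nucleation at 1–3 monomers, per-frame gain/loss probabilities 0.10/0.25
while unstable (death when the count hits zero), stabilisation at 4
monomers, then growth at 0.15 per frame up to a cap of 12 (`Inf` emulates
the unbounded super-oligomer regime seen without downstream kinases).
Under these defaults roughly one punctum in five stabilises, matching the
minority-stable phenomenology the analysis is designed around. Partner
recruitment targets puncta that reach 6 monomers, after a
Normal(15, 5²) s delay from nucleation truncated at zero.

Choices worth flagging:

- **Brightness noise is static per fluorophore.** Each fluorophore's
  brightness is drawn once and a punctum's intensity is the running sum,
  which reproduces the $\mathcal N(n\mu, n(c\mu)^2)$ marginal exactly
  while keeping a given punctum's brightness stable across frames, as a
  physical sum of fluorophores is. Per-frame-independent multiplicative
  noise would instead inflate maximum-intensity statistics with track
  length and break size-recovery linearity.
- **Puncta are stationary by default** (`diffusion_step_um = 0`), with an
  optional Gaussian per-frame step. Punctum mobility is not quantified in
  the system being emulated, so the stationary default is a stand-in, not
  a claim about real data.
- **Calibration stacks use a clean-glass background** (2 ADU) — adsorbed
  fluorophores in buffer see far less background than the cytosol. This
  matters: at the cytosolic background a single GFP sits at ≈2.7σ of the
  LoG response and is *below* any honest detection threshold. Single-GFP
  photometry is a glass measurement in reality for the same reason.
- Rendering integrates the PSF over pixels analytically (error is pure
  Gaussian truncation at ±5σ, < 0.5 %), camera noise is
  offset + Poisson + Gaussian read noise, and every random draw descends
  from one seed in documented order, so identical configs and seeds give
  bit-identical movies and ground truth.

What the generator does **not** emulate: blinking and other photophysics
beyond single-step bleaching, 3-D PSFs and defocus, cell morphology and
membrane topology in live movies, spatially structured background, and
punctum fission/fusion. Tests passing on synthetic data therefore validate
the *computational* contract of each stage — they do not certify
performance on real movies where those effects exist.

## Numerical choices

- **Detection threshold.** The LoG quality threshold defaults to 4× the
  total background noise (estimated as the MAD about zero of a
  background-subtracted frame) propagated through the kernel,
  `4 · noise_sd · ||K||₂`. Scaling by read noise alone would ignore shot
  noise on the cytosolic background, which dominates it several-fold and
  floods the linker with spurious maxima; scaling by total noise keeps the
  false-positive rate at the 4σ level regardless of background. A small
  floor keeps the threshold positive on noise-free synthetic input.
- **Sub-pixel localisation** uses a parabolic fit of the log response
  (exact for a Gaussian-shaped peak; worst-case bias ≈ 0.01 px at
  half-pixel offsets), falling back to a plain quadratic when a neighbour
  response is non-positive, and clamping offsets to ±0.5 px.
- **Linking** is greedy mutual-nearest-neighbour per frame pair
  (assignment in order of increasing distance, one-to-one), with defaults
  `max_disp_um = 0.5` and `max_gap = 1` — appropriate for mostly
  stationary puncta at 1 s intervals. Detections are processed in a
  canonical coordinate order, so linking is invariant to input order.
  There is no merge/split handling: fusion and fission appear as track
  ends/starts, and the growth analysis screens them out via the < 2.5×
  initial-intensity rule.
- **Median filters** use a true disk footprint with reflect padding
  (implemented in C++; no installed package provides a disk-shaped
  float median). Background subtraction (radius 25 px) is evaluated at
  every pixel. The illumination estimate (radius 100 px) is evaluated on a
  stride-4 grid and bilinearly interpolated: the illumination function
  varies over ~100 px scales, so the interpolation error is far below a
  percent while the cost drops ~16-fold. The illumination image is
  rescaled to unit mean before division so corrected intensities stay on
  the camera scale.
- **Filter outputs are floating point and never clipped at zero**;
  clipping would bias dim-punctum intensities used for stoichiometry.
- **Degenerate inputs.** A zero-variance calibration makes the N-mer tail
  a step function; an empty DAPI field segments to an empty table; a
  zero-depth FRAP trace (prebleach equal to post-bleach) is rejected
  rather than normalized to 0/0.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: Gaussian
integrals for rendering and window capture, closed-form Poisson/geometric/
exponential laws for the generator, a Monte-Carlo check of the hexamer
tail, an rle-based brute-force scan for colocalization runs, hand-ranked
Spearman tables, and constructed fixed-cell fields with known filter
violations. End-to-end stoichiometry is validated by simulating fields of
known N-mers (500 hexamers and 500 dimers at default noise for the
classification bounds; 120 puncta per N ∈ {1, 2, 4, 6, 8, 12} at glass
background for size linearity, the condition under which single
fluorophores are themselves measurable). Tracking is validated for exact
ground-truth equivalence on noise-free, well-separated movies and for
recall ≥ 0.95 / RMSE ≤ 0.5 px on default-noise movies, where recall is
assessed over puncta that present at least two monomers for at least three
frames — monomer-only stretches are below the detection limit by
construction. Recruitment-time recovery (n > 500 events) and
lifetime–growth coupling (n > 1000 tracks) run on ground-truth-derived
track tables from the kinetic simulation, which isolates the analytics
from detection error; the rendered path is covered by the end-to-end
stoichiometry and tracking checks. The decoupled null for the
lifetime–growth statistic is a permutation of growth values across tracks
— the standard null for a rank correlation — because any generative model
with temporal growth mechanically couples (max − initial) to observation
span.

These sizes keep the full suite at a few minutes on one CPU while leaving
every statistical bound several standard errors away from its pass
threshold.

## Known limitations

- The LoG detector with a single scale assumes diffraction-limited,
  roughly isotropic puncta; very large assemblies that exceed the PSF
  scale will be localised but their 3×3-sum intensity saturates the
  window, biasing extreme sizes downward.
- One-to-one colocalization cannot represent a partner punctum genuinely
  shared by two adjacent reference puncta.
- Lifetime statistics include right-censored tracks without survival
  modelling; censoring is flagged but not corrected.
- The fixed-cell segmentation is validated on synthetic disk-geometry
  ground truth; real fields with irregular morphology will need their
  thresholds and the watershed behaviour checked per dataset.
- FRAP analysis applies no correction for observational photobleaching
  during acquisition.
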