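---
title: "Methods: models, estimators and design choices in ehtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in ehtkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehtkit)
```

`ehtkit` implements the desk-side analysis half of an engineered-heart-tissue
("cardiopatch") characterization workflow: optical-mapping
electrophysiology, isometric contractile mechanics, intravital
vascularization quantification, GCaMP calcium analysis, and the scalar
calculators (morphometry, ΔΔCt, densitometry) that accompany them. Because
the real measurements require living tissue, every estimator ships with a
synthetic-data generator whose ground truth is known in closed form; this
vignette records the models, the tunable parameters that matter, and the
design choices that were genuinely open.

## Optical mapping

### Signal model and conditioning

A voltage- or calcium-sensitive fluorescence movie is an array `[t, row,
col]` with sampling interval `dt` (ms) and pixel size (mm). Two acquisition
geometries are built in: a photodiode array (504 sites, modelled as a 21 × 24
grid at 1 mm, 1.2 kHz) and an EMCCD camera (80 µm at 125 Hz). The true
photodiode array layout is not published; `read_photodiode_csv()` therefore
accepts any channel → (row, col) table and the full grid is only a default.

`condition()` applies, per pixel: optional linear detrend; optional centered
moving-average low-pass (window in ms); robust normalization to [0, 1] using
the 2nd/98th percentiles (robust to single-frame spikes, then clipped);
and SNR-based mask pruning. The SNR statistic is the robust peak-to-peak
amplitude divided by a noise estimate, `sd(diff(trace))/sqrt(2)`. The default
threshold of 8 sits between the value a pure-noise trace attains (its robust
amplitude is ≈ 4.1 σ, giving SNR ≈ 4) and what clean action-potential pixels
attain (≳ 15). Every step is affine-equivariant, so gain/offset changes in
the raw fluorescence change no downstream measurement — a tested invariant.

### Activation, APD, conduction velocity

Activation is, by default, the last upward crossing of 50% normalized
amplitude before the pixel's peak, linearly interpolated between frames
(searching backward from the peak rejects early noise excursions). The
original analysis software's criterion is not stated, so a
maximum-derivative alternative is exposed and the method used is recorded in
the result. APD at level `p` (default 0.8) is the time from activation to
the first downward crossing of `1 − p` after the peak. Whether the original
measured APD from activation or upstroke onset is unstated; measuring from
the 50% crossing makes the two geometries commensurable and matches the
closed form `upstroke/2 + plateau + 0.8·ramp` of the synthetic template.

Conduction velocity offers two estimators, both labelled, neither claimed as
the original:

* **local_plane** (default): fit `T(x, y)` to a plane in a `k × k`
  neighbourhood of every fully-defined pixel; local speed is `1/|∇T|`
  (ms/mm → cm/s); the mean is over interior pixels excluding a 1.5-pixel
  radius around the stimulus (electrode artifact, near-field curvature).
* **radial_fit**: least-squares slope of activation time against Euclidean
  distance from the stimulus; speed is the reciprocal slope.

Noise propagation drives the per-geometry defaults in
`cv_analysis_settings()`. At 1.2 kHz the upstroke spans many frames: a 4 ms
moving average and the default 3 × 3 plane window recover noisy (σ = 5% of
amplitude) speeds to well under 1%. At 125 Hz the upstroke is barely
sampled: temporal smoothing would flatten it, and activation-time jitter
(≈ 0.5–1 ms) rivals the 0.2 ms/pixel gradient at 40 cm/s. Because
`E[1/|∇T|]` is convex in the gradient, jitter biases speed upward; the
camera settings therefore skip temporal smoothing, use a 7 × 7 plane window,
and pre-smooth the activation map with a strict 5 × 5 box filter (a
symmetric mean leaves any planar map exactly unchanged, so the noiseless
case stays exact). These settings were fixed from this analysis, not tuned
to test outcomes; worst-case recovery error in the acceptance suite is
≈ 5–6% at σ = 5%, against a 10% criterion.

The synthetic wave generator is purely kinematic — activation time equals
source-to-pixel travel time (projected distance for plane sources, Euclidean
for point sources) and each pixel plays back one template. No ionic model or
reaction–diffusion integration is attempted, so green tests establish that
the *estimators* are correct, not that any biophysics is. The template
upstroke is geometry-matched (10 ms for the photodiode, 25 ms for the
camera): a 125 Hz acquisition cannot represent a 10 ms upstroke, and optical
upstrokes at that sampling are blur-broadened in practice; with ≥ 3 frames on
the ramp, linear interpolation of the 50% crossing is exact for noiseless
data.

### Arrhythmia classification and coupling

Post-pacing episodes are classified by the 60 s rule: no ectopic
threshold-crossing events → `none`; activity self-terminating within 60 s of
the pacing offset → `unsustained`; activity persisting ≥ 60 s → `sustained`
(the boundary itself is assigned to `sustained`). Records shorter than 60 s
past the offset are flagged `capped`. The burst protocol enumerates 2 Hz and
6–20 Hz in 2 Hz steps — nine episodes. Graft–host coupling is scored from
paired event lists: a host event is coupled when a graft event follows
within a latency window (50 ms default); the verdict is `coupled` when the
coupled fraction reaches 0.8.

## Contractile mechanics

Twitches are segmented from stimulus markers when available (window: 100 ms
baseline before each marker up to the next marker), else by
prominence-based peak detection. Kinetics follow the 10–90% convention: rise
= upward 10% → 90% crossing interval; decay = downward 90% → 10%; total =
upward 10% to downward 10%-remaining (i.e. 90% relaxation — the phrasing "10%
activation to 90% relaxation" is implemented as this interpretation and
flagged here). Crossings are linearly interpolated; flat segments at a
threshold resolve to the earliest sample. The double-exponential generator
(`A(e^{−t/τ_d} − e^{−t/τ_r})`, rescaled to peak amplitude) provides truth via
a 0.01 ms dense-grid scan independent of the trace-analysis path; a
triangular override gives exact closed forms (rise = 0.8·T_r).

Passive stiffness is the least-squares slope of passive tension against
strain *as a fraction of culture length* over the three highest levels
≥ 112%, divided by cross-sectional area; 1 mN/mm² ≡ 1 kPa. Strain units are
a choice (the source plots % but states no slope units) and are recorded in
the output. CSA is always an input — how it was measured is not stated, so
no internal estimation is attempted. The FFR normalizes twitch amplitude to
the 1 Hz value and reports a regression slope (%/Hz); whether the original
slope was regression- or endpoint-based is unstated, but for the three
equispaced test frequencies the two coincide.

## Vascular imaging

The phantom forward model is Beer–Lambert transmission:
`I(λ) = I₀·10^{−(ε_HbO2(λ)c₁ + ε_Hb(λ)c₂)}` over rasterized vessel
segments, background `I₀` elsewhere. Extinction coefficients at the 11
acquisition wavelengths (500–600 nm, 10 nm steps) are a versioned CSV asset
adapted from the standard compiled tabulation; forward and inverse models
share it, and only relative concentrations (molarity × pathlength) are
claimed — scattering and pathlength are absorbed into the units. The default
vessel `c_thb = 1.5 × 10⁻⁵ M·cm` puts peak absorbance near 0.8, typical of
superficial microvessels.

`unmix_hemoglobin()` computes `A(λ) = −log₁₀(I/I_ref)` and solves a
non-negative least-squares fit onto the two extinction spectra (optional
free offset for wavelength-flat loss). With at most two sign-constrained
coefficients the NNLS optimum is found exactly by enumerating active sets,
vectorized across pixels. `I_ref` defaults to the stack's recorded reference
and can be a per-wavelength background estimate; the exact hemoglobin
mapping algorithm of the cited prior method is not restated in the source,
so this standard Beer–Lambert reduction is a documented stand-in.

Contrast enhancement is CLAHE (8 × 8 tiles, clip limit 0.01 — no parameters
are published, so these are config-exposed and logged), implemented with
clipped per-tile histogram CDFs and bilinear blending; `interpolate = FALSE`
gives the blockier but exactly rank-preserving per-tile mapping, which is
what the rank-order property test checks. Segmentation thresholds within
the ROI only (Otsu by default; the source says only "thresholded"), removes
objects below `min_object_px` (8-connectivity), and BVD is vessel pixels
over ROI pixels. BVD is invariant to global illumination gain because the
gain cancels in `I/I_ref` — a tested invariant.

## Calcium transients

`dF/F = (F_peak − F_base)/F_base`. `F_base` is the mean of the
lowest-decile samples — the source does not define it, and a pre-event
window mode is provided when timing is known. `F_peak` averages all detected
transient peaks rather than taking the single maximum, for robustness; the
choice is recorded. Analysis ROIs default to three non-overlapping
400 × 400 µm squares placed by maximal temporal variance with top-left
tie-breaking (deterministic on uniform movies). dF/F is gain-invariant and
deliberately *not* offset-invariant (an offset `b` shifts it to
`(F_peak − F_base)/(F_base + b)`); both behaviours are tested. The flash
generator places peaks exactly on frames so noiseless recovery is exact.

## Quantification calculators

Relative cell count (`100·(cells·thickness)_test/(cells·thickness)_ref`),
percent difference, pooled percentages, ΔΔCt (`2^{−ΔΔCt}` with GAPDH
housekeeping, triplicates averaged as arithmetic mean of Ct — already a log
scale), protein/DNA ratio, and loading-control densitometry (reference-group
mean pinned at 1). Percentages are reported unrounded alongside the
nearest-percent value that prose conventions use. The source's "71% volume"
and "~30% cell size" figures are not exactly reproducible from the printed
means by simple rounding; the calculators report unrounded values and do not
attempt to match those two numbers.

## Reproducibility and I/O

All randomness flows through explicit seeds scoped with a save/restore
helper; generators are bit-stable for a fixed seed. Movies and hyperspectral
stacks are stored as plain CSV matrices with JSON sidecars (no binary TIFF
dependency exists in the supported R stack; the sidecar carries `dt_ms`,
`pixel_size_mm`/`pixel_size_um` and masks, and missing metadata is a hard
error, never a silent default). `run_stage()` writes a provenance JSON
(package version, seed, parameters, and an md5 hash of the
location-independent part of the configuration) with every artifact;
deterministic stages are byte-identical across reruns, and no timestamps
enter outputs.

## Known limitations

* Waves are kinematic; no rotors, re-entry geometry, or restitution.
* No motion-artifact correction (recordings assume an uncoupler), no
  bleaching or ratiometric correction, no absolute Ca²⁺ or hemoglobin
  calibration.
* The synthetic generators use idealized templates (piecewise-linear APs,
  double-exponential twitches, synchronous flashes); they validate
  estimator arithmetic, not tissue biology.
* Tissue-level measurements (forces, CVs, APDs of real cardiopatches)
  require the physical preparation and are outside what a green test can
  establish.
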