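---
title: "Quantifying IPL stratification in OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying IPL stratification in OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iplstrat)
```

## The measurement problem

The inner plexiform layer (IPL) of the retina is the synaptic layer between
the ganglion cell layer (GCL) and the inner nuclear layer (INL). It is
conventionally divided into five sublaminae, S1–S5, which segregate the ON
and OFF visual pathways along the depth axis. On ultrahigh-resolution
(visible-light) OCT, this stratification appears as a subtle pentalaminar
reflectivity pattern: three hyper-reflective strata (S5, S3, S1) separated
by two hypo-reflective ones (S4, S2). `iplstrat` turns B-scans into a
quantitative description of this pattern: per-segment reflectivity profiles
on a normalized depth axis, 14 morphometric parameters, their topography
across the macula, and subject-level statistical models.

The contrast of the hypo-reflective bands against the hyper-reflective ones
is small (on the order of 5–40%), while two noise sources are large:
speckle, the multiplicative interference noise of coherent imaging whose
fully developed form has intensity contrast (SD/mean) of exactly 1, and
additive sensor noise, which contributes a positive intensity bias. The
pipeline's structure follows directly from this: average many decorrelated
frames to suppress speckle, subtract the additive background, normalize away
thickness and brightness, then fit and constrain peak detection so that the
weak pattern is extracted robustly.

## Pipeline stages and their models

**Registration and averaging** (`register_frames`, `average_frames`).
Repeated fast frames are aligned axially by integer-pixel cross-correlation
of their laterally averaged depth profiles, then intensity-averaged.
Averaging `N` decorrelated speckle realizations reduces speckle contrast as
`1/sqrt(N)`; with the default 30 frames the residual contrast is about 18%.
Registration is axial-only: frames sit at distinct slow-axis positions by
design, and the dominant inter-frame motion is axial. Intensities are
averaged on a linear scale, consistent with the speckle-contrast argument
(log-domain averaging would bias the mean).

**Background correction** (`subtract_background`). Additive noise biases
OCT intensity upward. The bias is estimated as the mean intensity in a
vitreous window 10–40 px above the ILM (the vitreous scatters essentially
nothing) and subtracted, flooring at zero. The operation is idempotent and
records the estimated level in the image provenance.

**Layer segmentation** (`detect_boundaries`). Layer edges are zero
crossings of the second derivative of the smoothed depth profile: a
dark-to-bright edge is a crossing with positive slope, bright-to-dark the
converse. Crossings are assigned to the ILM, IPL–GCL, IPL–INL and IS/OS
boundaries using the expected ordering of bright bands (NFL, IPL, OPL,
IS/OS): the IS/OS is the brightest outer band, and the IPL is the second
bright run between the ILM and the IS/OS. Columns where this assignment
fails — notably the foveal center, where the inner layers vanish — are
masked invalid rather than guessed. Smoothing before differentiation is
Gaussian with sigma 2 px axially and 2 columns laterally. The lateral sigma
is deliberately small: on the foveal pit wall the ILM depth changes by more
than a pixel per column, and stronger lateral smoothing biases the detected
ILM by over a pixel, while 2 columns keeps all four boundaries within one
pixel of truth on noise-free phantoms. Sub-pixel positions come from linear
interpolation of the second-derivative zero crossing. All thresholds are
relative (quantile-based), making segmentation equivariant to a global
intensity scale.

**Foveolar localization** (`find_foveal_center`). The foveola is the
lateral position minimizing the ILM–IS/OS distance, after interpolating the
distance trace across invalid columns and smoothing it over 15 columns.
Ties break toward the image center; a minimum on the image edge (no pit in
view) raises a warning instead of failing. This global eccentricity
correction absorbs fixation error.

**Percent-axis profiles** (`extract_column_profile`, `segment_profiles`).
Each A-scan's IPL intensity is linearly interpolated onto a 101-point
percent-thickness axis: 0% at the IPL–GCL boundary (S5 side), 100% at the
IPL–INL boundary. For a 50 µm IPL the sampling interval is 0.5 µm. Columns
are grouped into contiguous 450 µm (1.5°) transverse segments anchored at
the left image edge (the anchoring phase is arbitrary but deterministic);
invalid columns are dropped from the segment mean rather than interpolated,
with equal weight on the valid columns. Each segment profile is normalized
to mean 1, so values read as contrasts relative to the mean IPL
reflectivity, and every segment carries equal weight in later averaging.
Segments whose mean IPL thickness is below 24 µm are flagged excluded: thin
foveal profiles cannot support five resolvable strata at ~1 µm axial
resolution.

**Stratification** (`fit_profile`, `find_extrema`,
`stratum_boundaries_midpoint`, `transition_widths`,
`segmental_extrema_with_template`). A 14th-order polynomial is fitted by
least squares to each 101-point profile (orthogonal polynomial basis
internally; a raw degree-14 Vandermonde on 0–100 is numerically
treacherous). Feature extraction operates on the fitted curve *sampled back
on the 101-point grid*, not on analytic roots of the degree-13 derivative:
the grid is the native resolution of the data and avoids root-finding
pathologies. Local extrema are found by neighbor comparison on the open
interior (the endpoints 0% and 100% are never extrema); consecutive maxima,
and consecutive minima, must be separated by more than 25% of the IPL
thickness, encoded as at least 26 grid points, with lower peaks (shallower
valleys) suppressed first, ties broken by location. No separation
constraint links a maximum to a minimum. A result is accepted only if the
surviving extrema form the peak–valley–peak–valley–peak template; otherwise
it is invalid with a machine-readable reason. The 14 parameters are the 5
extrema contrasts, 5 stratum thicknesses and 4 transition widths.

Stratum boundaries use the midpoint rule: between each adjacent
peak–valley pair the boundary is the first crossing of the fitted curve
through the mean of the two extremum values, scanning from the inner
extremum outward (wiggle-induced multiple crossings resolve to the first).
With 0% and 100% as outer boundaries this yields exactly 6 boundaries and 5
thicknesses summing to 100 by construction. Transition widths are the four
distances between adjacent extrema locations; they measure the sharpness of
the inter-stratum transitions and cross-check the thickness estimates.

For segment-level analysis, the image-average profile acts as a template:
each segmental extremum is searched only between the template's previous
and next extrema (clipped to the open interval (0, 100)). An extremum
landing on the edge of its search window is invalid ("edge"), as are
adjacent valid pairs violating peak > valley ("pattern"); if the template
itself shows no clear pentalaminar pattern, all segments of that image are
discarded ("template"). Validity is tracked per extremum, so one bad
extremum costs at most its own value and the two adjacent transitions —
which is why transition discards naturally outnumber extremum discards.
A constant profile gets R² = 1 by convention (zero total variance) and is
flagged degenerate.

**Topography** (`average_profiles`, `eccentricity_bin_image`,
`rolling_summary`, `cohort_counts`). Three averaging tiers trade noise for
alignment: raw segments (least averaging), image averages, and
cohort-by-eccentricity or by-thickness averages (most averaging). All
averaging is over normalized 1.5° segment profiles, so segments weigh
equally. Because patterns do not align perfectly across subjects and
eccentricities, the heavily averaged tiers lose some peak-to-valley
contrast relative to segment-level estimates — a property the test suite
checks on deliberately misaligned profiles. Eccentricity bins are
equal-width over the observed range of eccentricity magnitude (eccentricity
is stored signed, analyzed unsigned). Rolling summaries use a rank-space
window of 21 consecutive sorted observations (mean ± SD/√n), advancing one
observation at a time; a window in observations rather than predictor units
keeps the variance of each window point comparable.

**Statistics** (`fit_fixed_effects`, `fit_mixed_effects`,
`vertex_eccentricity`, `compare_strata_anova`, `compare_models_aic`,
`residual_diagnostics`, `exclude_outliers`, `fit_all_models`). Each of the
14 parameters is modeled against eccentricity magnitude or IPL thickness.
The fixed-effects variant gives every subject free OLS coefficients (fitted
jointly with one residual variance; the coefficients equal per-subject OLS)
and tests the 16 subject slopes against zero with a two-tailed t-test,
reporting the mean subject slope. The mixed-effects variant fits population
coefficients plus independent (diagonal-covariance) zero-mean normal random
intercept/slope(/quadratic) terms per subject via `lme4`, REML for
estimation, refit by ML when models are compared by AIC; p-values for fixed
coefficients are normal-approximation Wald tests. The S5 peak versus
eccentricity is the one relation requiring a quadratic term; its
per-subject vertex, `-b/(2c)`, estimates where S5 contrast peaks (subjects
with a non-negative quadratic coefficient are flagged, not imputed). The
predictor is centered before quadratic fits to reduce collinearity; vertices
are reported in original units, and the estimator is invariant to adding a
constant to the response. Rows with IPL thickness below 24 µm are excluded,
then a single pass removes points whose residual from the initial
per-subject fit exceeds 5 SD; the screen is applied per model (the
alternative — one global screen — differs only in pathological cases).
Strata are compared by one-way ANOVA with Tukey's HSD. Homoscedasticity is
screened with a Breusch–Pagan-type statistic (squared residuals on fitted
values, n·R² against χ²₁), and Wald confidence intervals are reported for
all estimated coefficients; flags are raised, never silently dropped. The
driver `fit_all_models` enumerates 14 parameters × 2 predictors × 2 model
types = 56 models. No multiple-testing correction is applied across them.

## The synthetic phantom: what it emulates, and what it does not

With no raw human data available, the generator (`phantom_config`,
`render_frame_stack`, `render_cohort`) provides ground truth for every
stage. It emulates:

* **Macular geometry.** IPL thickness is zero at the foveola, rises over
  the pit by a smoothstep, reaches its maximum (default 40 µm) at 1.5 mm
  via a raised-cosine shoulder, and declines linearly (3 µm/mm) beyond.
  NFL, GCL and INL scale with local IPL thickness; OPL, ONL and the bright
  IS/OS band are constant, with the IS/OS flat in depth — so the ILM–IS/OS
  distance is minimal exactly at the foveola, which is what foveolar
  localization exploits.
* **The pentalaminar profile.** The true profile interpolates the five
  extremum contrasts with piecewise power-cosine easing. This construction
  is monotone between extrema (so the template always holds), places
  extrema exactly at the stratum-fraction midpoints, has mean exactly 1,
  and the easing exponent of each transition is set so the half-way
  crossing falls exactly on the configured stratum boundary — making the
  midpoint rule's target the configured fractions themselves, independent
  of contrast amplitudes. Default fractions (S5..S1) are 0.18, 0.17, 0.24,
  0.23, 0.18, giving S3/S4 the 21–25% share reported for real IPL. The S5
  contrast follows a downward parabola in eccentricity with vertex (2.4 mm,
  1.2) passing through 1.05 at 0.75 mm; inside the fovea the parabola is
  clipped just above the valley level so the template survives (those
  segments are below the 24 µm threshold anyway). Valley contrasts default
  to 0.88 and 0.90.
* **Noise.** Each frame is the mean reflectance image (layer stack
  convolved axially with a 1.0 µm FWHM Gaussian PSF, rendered on a 4×
  oversampled grid) multiplied by unit-mean exponential speckle — the
  squared modulus of a filtered circular complex Gaussian field, whose
  pointwise contrast is exactly 1 regardless of correlation — redrawn
  independently per frame, plus Gaussian additive noise with a positive
  mean (the noise floor that background correction must remove), floored at
  zero, with an integer axial jitter per frame (SD 1.5 px).
* **Cohort structure.** Per-subject peak thickness (SD 3 µm), S5 plateau
  (SD 0.03), S5 vertex (SD 0.2 mm) and stratum fractions (SD 0.01,
  renormalized) are drawn from normal between-subject distributions; each
  image gets a fixation-error offset of the scan center along its spoke
  (SD 0.1 mm). Six spokes at 30° intervals with 16 subjects reproduce the
  reference 96-image, 960-segment design. All randomness flows from one
  master seed; per-stack streams are derived deterministically, and reruns
  are bit-identical.

It does **not** emulate: wavelength-dependent scattering, blood-vessel
shadows, curved retinal geometry, lateral or torsional eye motion,
depth-dependent resolution loss, or real histological variability of
stratum shapes. Passing recovery tests on the phantom therefore
demonstrates that the *algorithms* are correct and well-calibrated under
the stated noise model — not that the defaults describe any particular
human cohort. Because the default noise is milder than clinical data (no
vessel shadows, no residual motion), the phantom's segment discard rate is
lower than the roughly 17%/26% extrema/transition exclusion rates seen in
practice; the discard bookkeeping (`threshold`, `empty`, `edge`, `pattern`,
`template`) is designed to reproduce that accounting style on harder data.

## Numerical choices

* Extrema on the 101-point grid of the fitted polynomial; endpoints
  excluded; ">25% of IPL thickness" implemented as a separation of at
  least 26 grid points between same-type extrema (25 would allow exactly
  25%).
* Suppression order: by extremum prominence (height for peaks, depth for
  valleys), ties by location — mirroring standard minimum-peak-distance
  peak finding; the test suite proves exact agreement with brute-force
  enumeration on 1000 random degree-14 profiles.
* Midpoint crossings: first crossing scanning inner→outer, sub-grid
  position by linear interpolation.
* Boundary sub-pixel refinement: linear interpolation of the
  second-derivative zero crossing nearest the seed, slope-sign matched.
* The degree-14 fit uses `stats::poly` (orthogonal); R² is 1 by convention
  for zero-variance profiles.
* TIFF stacks are stored as 32-bit float pages with a JSON metadata
  sidecar (TIFF tags are fragile across dialects); doubles survive to
  single precision, and a second roundtrip is bit-identical.

## Problem sizes in the test suite

The suite validates the full pipeline at the sizes the checks demand while
staying quick: unit tests run on 128 × 500 px phantoms (2 µm axial, 9 µm
lateral pixels); the structural-count check runs the full 16 × 6 reference
design at that reduced size; parameter-recovery runs 16 subjects × 2
spokes at full 256 × 1000 px resolution, noise-free and with default
noise; statistical calibration uses 1000 null replicates (16 subjects × 40
segments) for the type-I error and 100 replicates for mixed-model
coverage; oracle equivalence uses 1000 random degree-14 profiles; speckle
physics uses 10 seeds. These sizes are the package's validation choices
and are stated here so they can be scaled up for more stringent checks.

## Known limitations

* Boundary assignment assumes the canonical bright-band ordering; severely
  pathological retinas (or phantoms with inverted contrast) will mask most
  columns invalid rather than adapt.
* Integer-pixel registration leaves sub-pixel axial blur; at 1 µm pixels
  this is negligible against the 1 µm PSF but would matter for coarser
  sampling.
* The template-guided search inherits the template's biases: if the
  image-average profile is distorted, segment extrema windows shift with
  it. The standard remedy — discarding images whose template fails the
  pentalaminar test — is implemented, but subtler template distortions
  pass through.
* Mixed-model p-values are Wald approximations; for small cohorts they are
  mildly anti-conservative compared to Satterthwaite or likelihood-ratio
  approaches.
* The 24 µm exclusion threshold and the 5 SD outlier screen are applied as
  stated, not tuned; changing them changes which foveal segments enter the
  topographic analyses.
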