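---
title: "Quantifying cortical actin dynamics, architecture and pavement-cell shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical actin dynamics, architecture and pavement-cell shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actomorph)
```

## Scope

`actomorph` quantifies three aspects of the cortical actin system of plant
epidermal cells from fluorescence microscopy:

1. **Dynamics** — how quickly the cortical filament pattern inside a region
   of interest (ROI) decorrelates over time, measured as the decay of the
   pairwise Pearson correlation between frames (frame-correlation decay).
   A more dynamic cytoskeleton (faster filament turnover) decorrelates
   faster.
2. **Architecture** — four frame-wise metrics of the segmented filament
   network: occupancy (density), structure-tensor anisotropy (alignment),
   and intensity skewness and coefficient of variation (both bundling
   proxies).
3. **Cell shape** — pavement-cell morphometrics (area, circularity
   `4*pi*A/P^2`, solidity `A / convex-hull area`) from label masks, with a
   plant-level group comparator.

Because no public raw imaging data accompany this kind of experiment, the
package ships a synthetic-microscopy generator with exact ground truth
(filament birth/death times, bundling flags, analytic cell polygons).
Every analysis stage therefore has a recovery test: the tests simulate
data with known turnover, bundling, alignment or lobedness and check that
the corresponding estimator ranks or separates the conditions correctly.

## The synthetic generator

### Filament movies

`simulate_filament_movie()` renders `n_frames` frames (default 149 at
0.4 s, matching a typical spinning-disc acquisition) of a fixed number of
cortical filaments:

* **Geometry.** Each filament is a persistent random walk: unit pixel
  steps whose heading is perturbed by a von Mises increment with
  concentration `persistence_px` (default 40; larger means straighter).
  Contour lengths are uniform on `length_range_px` (default 40-120 px,
  i.e. 8-24 µm at 0.2 µm/px — plausible for cortical bundles spanning a
  pavement cell's cortex).  Initial headings are isotropic unless
  `orientation_kappa > 0`, which concentrates them von Mises-style around
  one direction and lets tests verify that the anisotropy metric recovers
  network alignment.
* **Turnover.** A filament lives for an exponential time with rate
  `turnover_rate_per_s` and is replaced *at the instant of death* by a
  freshly sampled filament.  The filament count is therefore stationary,
  so correlation decay reflects turnover alone rather than density drift.
  Death times are recorded uncensored in the ground truth, which is what
  the lifetime-law tests (mean lifetime, Kolmogorov-Smirnov against the
  exponential) consume.
* **Bundling.** Exactly `round(bundling_fraction * n_filaments)` slots
  (default 30%) carry an intensity multiplier `bundling_factor`.  A
  brighter subpopulation raises the skewness and CV of masked
  intensities, which is precisely the interpretation of those metrics as
  bundling proxies.  The fraction is deterministic rather than Bernoulli
  so that the bundled:unbundled mixture — and hence the direction of the
  skewness response — does not fluctuate between seeds.
* **Optics and noise.** Rendering order per frame: sum of PSF-blurred
  (Gaussian, `psf_sigma_px`, default 1.5) filament images; multiplication
  by `exp(-bleach_rate_per_frame * t)`; additive Gaussian noise
  (`noise_sd`, default 0.02 on the 0-1 scale, giving a peak filament
  signal-to-noise around 8, typical of mildly exposed sCMOS imaging);
  clipping to `[0, 1]`, the package's canonical intensity scale.
* **Reproducibility.** One root seed is split hierarchically: one stream
  per filament slot, one per frame for noise.  Adding a filament does not
  reshuffle the others, and toggling bleach changes neither geometry nor
  noise — the bleach-robustness comparison is exact apart from the bleach
  itself.

What the generator does *not* emulate: filament elongation/severing and
lateral sliding, 3D cortex curvature, defocus, camera gain structure, or
photokinetic artefacts.  Passing recovery tests therefore demonstrate
that the estimators respond correctly to turnover, bundling, alignment
and lobedness *as modelled*; they do not calibrate absolute values for
real tissue.

### Lobed-cell mosaics

`generate_lobed_cells()` places non-overlapping cells with boundary
`r(theta) = R (1 + a sin(m theta + phi))` — base radius `R`
(default 15 µm), lobe count `m` (default 6), relative amplitude
`a in [0, 0.9]`, random phase per cell — on a grid whose pitch guarantees
disjoint rasterization.  The exact 720-vertex polygon of every cell is
stored, so raster morphometrics can be compared against shoelace/segment
oracles.  `a = 0` yields discs; `a` around 0.35 yields strongly lobed
outlines whose circularity (~0.4) is far from the disc value, emulating
the difference between lobe-suppressed and wild-type-like pavement cells.

## Preprocessing

Operations are applied in the fixed order background subtraction →
contrast enhancement → bleach correction (`preprocess_stack()`):

* `subtract_background()` — grayscale opening with a flat disc (default
  radius 50 px) subtracted from each frame (the opening form of
  rolling-ball correction).  It removes any flat offset exactly, passes
  sub-disc features through, is offset-invariant and idempotent.  The
  ImageJ paraboloid variant is deliberately not replicated bit-for-bit.
* `enhance_contrast()` — one affine map from the *global* stack min/max
  onto `[0, 1]`.  Per-frame stretching would itself remove photobleaching
  and confound the dedicated correction step, so it is not offered.
* `correct_bleaching()` — monotone quantile matching of every frame onto
  the reference frame (default frame 1, the least-bleached).  With equal
  pixel counts the corrected frame is an exact rearrangement of the
  reference values: per-frame means and histograms match the reference
  exactly, and within-frame rank order is preserved.  Under pure
  multiplicative decay the original frame is recovered exactly.

  A limitation worth understanding: Pearson correlation is invariant to
  per-frame affine maps, so exponential bleaching *by itself* does not
  bias the correlation traces, and quantile matching neutralizes what
  little non-affine distortion remains.  What no histogram operation can
  restore is the signal-to-noise lost when noise is added on top of an
  already-bleached signal: late frames genuinely carry less pattern
  information, which attenuates long-lag correlations.  With the
  generator's default noise this residual effect on the normalized decay
  curve reaches roughly 0.1; it vanishes as the noise level goes to zero.
* `make_roi_grid()` — a square-ROI grid of pitch `spacing_um`
  (20 µm in typical use) with the origin drawn uniformly in one grid
  cell, which removes selection bias in ROI placement.  Manual exclusion
  of out-of-focus regions is modelled as the `kept` flag.  Only the
  origin is randomized; the paper-style overlay leaves the orientation
  axis-aligned.

## Frame-correlation dynamics

Per ROI, `correlation_matrix()` computes all pairwise Pearson r between
frames; `trace_from_matrix()` averages each superdiagonal (lag k has
T − k pairs; lag 0 is excluded as trivially 1).  By default the raw r
values of a lag are averaged and the *mean* is Fisher-z transformed
("trace-then-transform"); averaging the per-pair z values instead is
available via `aggregate = "mean_z"` and differs only slightly.

`normalize_trace()` divides the Fisher z at every lag by the value at
the smallest lag, making ROIs with different baseline correlations
comparable; the normalized trace starts at exactly 1.  Correlations are
clamped to ±(1 − 1e-7) before `atanh` (each clamping is reported); an
ROI whose lag-1 z is zero cannot be normalized and is excluded with a
message, as is any ROI containing a zero-variance frame.

`compare_groups()` runs a two-tailed Welch t-test on `z_norm` across
ROIs at every lag and applies Benjamini-Hochberg correction *jointly
across the lags of the comparison* (the multiplicity family is the one
comparison; flags are returned at 0.05 and 0.01 by default).  Group
means and pointwise 95% CIs are also returned back-transformed through
`tanh` for plotting on the familiar correlation scale.  The package
deliberately implements this per-lag test rather than a mixed-effects
model: trace tables carry `plant_id`/`replicate_id` columns so
hierarchical models can be fitted externally with `lme4`/`glmmTMB` when
the experimental design requires them.  Consequently the per-lag test is
only valid when the traces it receives are exchangeable units.
`simulate_group_traces()` therefore samples each group's ROIs from
several independent movies ("plants"), because many ROIs from a single
movie share one filament realization and would pseudo-replicate it; and
when a movie still contributes several ROIs, `aggregate_traces()`
averages them to one trace per movie before testing — the same
unit-of-analysis principle as the plant-level aggregation in the shape
module.  In simulation, testing raw ROIs from shared movies inflates the
family-level false-positive rate several-fold, while movie-level units
restore the nominal 5% bound.

## Actin architecture

* `enhance_filaments()` — multiscale Hessian ridge response: at each
  scale (default σ ∈ {1, 2, 4} px) the frame is smoothed, the Hessian
  computed by central differences, and the bright-ridge lineness taken as
  `max(0, -σ² λ_min)`; the response is the maximum over scales.
* `segment_actin()` — global Otsu threshold on the **square-root
  compressed** response, removal of components below `min_object_px`
  (default 20 px), Guo-Hall thinning, branch decomposition at skeleton
  branch points, and Euclidean branch path lengths (diagonal steps √2).
  The square-root compression is load-bearing: on the raw response,
  Otsu's between-class variance criterion chases the gap between faint
  and bright (bundled) filaments, so the mask would shrink as bundling
  increases; on the compressed response it splits background from
  filaments and the mask stays stable across bundling levels, which is
  what makes occupancy comparable and skewness/CV monotone in the
  bundling factor.
* `anisotropy()` — per skeleton branch, the Gaussian-windowed structure
  tensor (window σ default 8 px) is averaged over branch pixels and
  summarized as the coherence `(λ1 − λ2)/(λ1 + λ2 + ε)`, bounded in
  [0, 1] by construction; branch scores are combined weighted by branch
  path length.  The guard ε (1e-12) is applied relative to the maximum
  tensor trace so that the score is exactly invariant under intensity
  rescaling.  Parallel-line fixtures score above 0.9; dense isotropic
  line fields score below 0.2 provided the window exceeds the line
  spacing — with a window comparable to the spacing, single lines
  dominate their window and the score rises, so the window should be
  chosen against the expected filament density.
* `intensity_skewness()` / `intensity_cv()` — Fisher-Pearson sample
  skewness and SD/mean of intensities inside the mask (zero-variance
  masks return 0 by convention; masks under 3 px return `NA`).
* `summarize_structure()` — the four metrics per frame, arithmetically
  averaged over time per ROI; frames with empty masks are excluded and
  counted out of `n_frames_used`.

## Pavement-cell shape

`measure_cells()` measures each label: area as pixel count × pixel area;
perimeter as the length of the sub-pixel 0.5 iso-contour of the lightly
smoothed mask (Gaussian σ = 1.25 px), floored by the convex-hull
perimeter; circularity `4πA/P²` clamped to ≤ 1 (clamping reported);
solidity as area over the hull area of boundary-pixel corners; and a
border flag that excludes edge-touching cells from statistics.

The perimeter estimator deserves a note, because the obvious candidates
both fail a basic sanity check.  A pure marching-squares boundary on the
binary mask overestimates curved boundaries by ~6% (staircase metric);
the 4-direction Crofton estimator is excellent on curves but undershoots
axis-aligned straight edges by ~5.8%, so a rasterized square would
measure circularity 0.89 instead of π/4 ≈ 0.785.  Tracing the iso-contour
of a slightly smoothed mask fixes the staircase bias but rounds sharp
corners; flooring the result by the convex-hull perimeter — legitimate
because a region's boundary can never be shorter than its hull's —
restores straight-edged convex shapes exactly.  With the combined
estimator a rasterized square measures circularity π/4 exactly, a
radius-100 px disc 0.989, and the raster-versus-polygon error on lobed
cells falls from 0.018 to 0.001 as the pixel size shrinks from 0.6 to
0.15 µm.  Crofton remains available as
`measure_cells(perimeter = "crofton")` for comparability with tools that
use it.

`measure_polygon()` is the exact oracle (shoelace area, segment-sum
perimeter, convex hull) used to validate the raster path; it rejects
self-intersecting polygons.

`compare_shape_groups()` aggregates to per-plant means first (the plant
is the experimental unit), runs pairwise Welch tests with BH adjustment,
and reports a compact letter display (insert-and-absorb algorithm);
groups sharing a letter do not differ at the chosen α.  Groups with a
single plant fall back to per-cell units with an explicit warning.  The
beta-regression / mixed-model machinery often used for bounded shape
metrics is intentionally out of scope; the tidy output carries the IDs
needed to fit those models externally.

## Numerical choices and degenerate inputs

* Intensities live on `[0, 1]`; stacks are clipped there after noise.
* Gaussian smoothing uses a separable kernel with replicate padding
  (radius 3σ), well-defined on images smaller than the kernel.
* Correlations are clamped to ±(1 − 1e-7) before `atanh`.
* Zero-variance situations are explicit: constant stacks refuse contrast
  stretching; zero-variance ROI frames name the offending frame;
  constant masked intensities give skewness 0 / CV 0; empty enhanced
  frames yield an empty flagged mask, not an error.
* Welch tests between two zero-variance samples return p = 1 when the
  means agree and p = 0 otherwise (relevant at lag 1, where `z_norm` is
  identically 1 in both groups).
* Connected components use 8-connectivity throughout (via an igraph
  backend); labels below the minimum size are removed before
  skeletonization.

## Problem sizes used in the test suite

The automated checks run simulation studies at reduced but
representative scale, chosen so the whole suite completes comfortably on
one CPU: turnover recovery uses three rates × 20 replicates of 176 px
movies with 149 frames and ≥ 20 ROIs; type-I/power checks use groups of
5 independent 112 px movies × 5 ROIs (20 null and 10 power replicates);
bundling recovery uses 10 seeds × 4 bundling factors of 160 px movies;
shape discrimination uses 20 replicates of 2 × 4 plants × 20 cells.
`scripts/acceptance.R` re-runs the same studies with slightly fewer
replicates and writes the headline numbers as JSON.

## Known limitations

* The enhancement/segmentation recipe (Hessian ridge + compressed Otsu +
  thinning) is a documented, parameterized stand-in for the various
  published actin-segmentation pipelines in this lineage; absolute metric
  values depend on it, rank comparisons much less so.
* The per-lag Welch/BH comparison ignores within-plant correlation; use
  the recorded IDs for mixed models when plants contribute many ROIs.
* Anisotropy depends on the tensor window relative to filament spacing
  (see above).
* The bleach correction cannot restore SNR lost to noise applied after
  bleaching (see preprocessing); strongly bleached, noisy series will
  show residual long-lag attenuation in either direction.
* The generator's filaments are static while alive; motile filament
  models (treadmilling, sliding) would decorrelate frames even without
  turnover and are out of scope.
* The longest lags of a trace average very few frame pairs (a single
  pair at lag T − 1), and once two conditions have both decorrelated to
  the noise floor their curves can cross there by realization noise —
  for example, even at a fast turnover rate a single filament
  occasionally survives the whole movie and lifts the far tail.
  Conclusions about rate differences should rest on the lag range where
  the curves are resolvably separated, not on single-pair tail lags;
  comparisons between decay curves are most meaningful at lags up to
  roughly half the movie duration.
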