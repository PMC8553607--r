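---
title: "Analysing grid-cell firing fields in volumetric space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing grid-cell firing fields in volumetric space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volgrid)
```

## The scientific problem

Grid cells of the medial entorhinal cortex fire in multiple spatial fields
that, on horizontal surfaces, form a strikingly regular hexagonal array. What
becomes of that array when an animal forages through a genuinely
three-dimensional volume -- for example a cubic climbing lattice of roughly
one cubic metre? Theory offers concrete candidates: fields could stack into
one of the two optimal sphere packings, face-centred cubic (FCC, layers
repeating ABC) or hexagonal close packing (HCP, layers repeating ABA), could
extend into vertical hexagonal columns, or could scatter without global
order. `volgrid` implements the full analysis chain needed to ask this
question of recorded (or simulated) spike trains: volumetric firing-rate
maps, masked 3D spatial autocorrelation, gridness scoring of every oblique
plane through the autocorrelation, close-packing structure scores, field
detection and morphology, and the shuffle-based null distributions that
calibrate each statistic.

Because raw recordings are not required for any of the package's logic, a
first-class synthetic-data module generates the study conditions: field
arrangements with exact close-packed geometry, lattice-constrained foraging
trajectories with horizontal-movement and floor-dwell biases, and
inhomogeneous-Poisson spike trains drawn from the resulting rate maps.

## Synthetic arrangements: the geometry the analysis assumes

`make_arrangement()` tiles a hexagonal point layer (x-spacing `S`, row
spacing `sqrt(3)/2 S`, alternate rows offset `S/2`) and stacks it along z in
steps of `sqrt(6)/3 S` (about `0.816 S`). HCP alternates two lateral layer
placements (offset `sqrt(3)/3 S` in y); FCC cycles three (`0, +sqrt(3)/3 S,
-sqrt(3)/3 S`); columnar arrangements repeat a single layer continuously in
z; random arrangements draw the matching HCP point count uniformly. Layers
are tiled from the volume's origin: anchoring at the origin (rather than
centring the pattern) keeps large-spacing arrangements from losing most of
their points to cropping. `arrangement_ratemap()` rasterises an arrangement
by assigning every voxel `exp(-0.5 (d / sigma)^2)` of its distance `d` to
the nearest field centre (`sigma` = 2 voxels by default), optionally rotating
the volume about an arbitrary axis -- simulations used for classification
draw the spacing uniformly from 200-600 mm and rotate 30 degrees about a
random axis, so nothing in the pipeline can rely on axis alignment.

```{r arrangement, eval = FALSE}
arr <- make_arrangement("FCC", spacing = 400)        # mm
map <- arrangement_ratemap(arr, voxel_mm = 970 / 21) # 21^3 voxel map
ses <- synthetic_session("FCC", spacing = 400, duration = 1200, seed = 1)
```

## Rate maps

Two estimators are provided, both operating on speed-filtered data
(`speed_filter()`, 5 cm/s threshold, since slow epochs carry non-spatial
firing).

**Adaptive maps** (`adaptive_ratemap()`) expand a sphere at every voxel until
`r > alpha / (n sqrt(s))`, with `r` the radius in voxels, `n` the occupancy
samples and `s` the spikes inside; the rate is `(s/n)` times the 25 Hz
tracking rate. `alpha = 1600` with 2.5 cm voxels reproduces the published
analysis scale. The criterion is read as `alpha / (n * sqrt(s))` -- the
standard adaptive-binning grouping; spheres are clipped at the volume
boundary, expansion proceeds in 1-voxel steps, and a voxel whose sphere
reaches half the volume diagonal without containing a spike is assigned rate
zero. **Histogram maps** (`histogram_ratemap()`) bin dwell time and spikes
and smooth both with a Gaussian before dividing; 10 cm voxels with a 2.5-bin
s.d. are used for map-stability comparisons (where voxel counts must stay
modest), 2 cm with 2-2.5 bins for information and field-order statistics,
and 2.5 cm with a 1-bin s.d. for planar projections (`project_ratemap()`,
occupancy-weighted collapse).

## Autocorrelation and its derived statistics

`autocorrelation()` computes the per-lag Pearson correlation over the
overlapping visited voxels of the map and its shifted copy. Unvisited voxels
are excluded pairwise, never zero-filled, and lags with fewer than 20
contributing pairs are undefined. Two execution paths give identical results
(verified to 1e-10 in the tests): a direct per-lag evaluation and an
FFT-based evaluation of the same masked sums, which is the default above
20,000 voxels. The normalisation uses the per-lag overlap count; with a
whole-map voxel count the masked statistic would not be bounded by 1.

From the autocorrelation the package derives: the average field radius
(`central_peak_radius()`, the sphere-equivalent radius of the central region
above 0.25); the grid spacing (`grid_spacing()`, the first prominent local
maximum of the median correlation over expanding 2-bin-thick shells,
excluding radii under 5 bins -- validated to recover the generator spacing
within 10% for FCC and HCP, rotated or not); midline self-similarity
profiles (`midline_profiles()`); and the vertical self-similarity curve
(`vertical_self_similarity()`), the correlation of the map with z-shifted
copies of itself in units of the grid spacing `d`. Close-packed layers
repeat every `0.816 d` of height, so an HCP map re-correlates with itself at
`2 x 0.816 d` and an FCC map at `3 x 0.816 d`, while a columnar map stays
near 1 at every shift -- this periodicity is, in this package, the most
reliable discriminator between the two close packings (see *Limitations*).

`anisotropy_correct()` rescales the autocorrelation per axis so its central
peak becomes a sphere (sampling factors limited to [0.5, 2], trilinear
resampling), undoing global field elongation before planar scoring.

## Gridness scores and the planar-symmetry analysis

`grid_score()` is the classical annulus method: threshold the 2D
autocorrelogram at 0.3, find the seven most central peaks (8-connected
components), isolate the annulus containing the six non-central peaks (ring
radius plus/minus the central-peak radius), and correlate it with rotated
copies of itself. HGS = min(60, 120 degrees) - max(30, 90, 150); SGS =
min(90, 180) - max(45, 135, 225). Cells or slices with fewer than seven
peaks are unscorable and propagate as NA rather than zero.

`sample_planes()` extracts the central oblique slice of the 3D
autocorrelation for every plane normal on a 65 x 65 grid of pitch [0, 90]
and azimuth [0, 360) degrees -- 4,225 planes -- and scores each slice. Two
sampling choices matter. First, azimuths span the full circle: planes with
normals at azimuth `a` and `a + 180` are genuinely different planes, and the
three oblique hexagonal planes of an FCC arrangement are 120 degrees apart
in azimuth, which a half-circle domain cannot represent. Second, each slice
is sampled on a grid covering the full central cross-section of the volume
(`sqrt(3)` times the side): truncating the slice at the autocorrelation side
clips the peak ring of steeply tilted planes at large grid spacings and
leaves them unscorable.

For an axis-aligned FCC arrangement the geometry on the score sphere is
sharp, and `plane_geometry()` measures it: three maximal-HGS planes on the
nominal 72-degree pitch ring (ideal geometry: arccos(1/3) = 70.5 degrees),
pairwise 120 degrees apart in azimuth, and three maximal-SGS planes on the
square ring (default `acos(1/sqrt(3))` = 54.7 degrees) offset 60 degrees in
azimuth from them. High-score planes form plateaus on a ring profile, so
plane azimuths are estimated as circular centroids of the super-threshold
segments rather than single grid maxima.

## Structure scores

`structure_scores()` condenses the score sphere into four contrasts. All
rings are measured *relative to the best plane* (the maximum-HGS plane;
ties resolve to the lowest pitch): directions at a fixed angle from the
best-plane normal are sampled at 128 ring angles by spherical nearest
neighbour (planes are unoriented, so proximity uses the absolute dot
product). Sampling rings on the un-rotated score sphere proved markedly more
accurate than rotating the autocorrelation volume and re-slicing, which
loses peaks to interpolation and NA wedges; `best_plane_correct()` still
provides the explicit volume rotation. With `hex` the 120-degree-spaced ring
triple maximising summed HGS at the 72-degree ring:

* `chi_cp` = median of the 72-degree-ring HGS values pooled with the
  square-ring SGS values (overall close-packing quality);
* `chi_fcc` = median SGS at `hex + 60` minus median SGS at `hex`, on the
  square ring;
* `chi_hcp` = median SGS at `hex` on the square ring minus median SGS at
  `hex` on the 72-degree ring;
* `chi_col` = median HGS within 60 degrees of the best plane minus the
  median of the remaining HGS values.

The square ring defaults to 57 degrees. The literature on this analysis quotes both 50
(operationally) and 57 (descriptively) for this angle; ideal close-packing
geometry puts the square planes at 54.7 degrees, and on simulated
arrangements the 50-degree ring demonstrably reads past the square planes
(sampled SGS near zero where the 57-degree ring reads 0.5-1.0), so the
geometrically consistent printed value is the default and the alternative
remains one argument away.

`classify_configuration()` labels a cell from its score triple. The default
`"region"` method assigns the nearest reference-simulation cloud centroid in
(chi_fcc, chi_hcp, chi_col) space -- the reference clouds ship with the
package (`default_reference_scores()`, 10 seeded simulations per kind,
reproducible via `reference_scores()`) -- with undefined contrasts treated
as zero. A convex-hull membership method (Frank-Wolfe distance test) and a
simple argmax with a random floor of 0.1 are also provided. The argmax
variant should be read with care: an ideal FCC arrangement carries
`chi_hcp` near +1 as well, because the hexagonal oblique planes contribute a
strongly negative SGS to that contrast's subtrahend, so argmax separates FCC
from HCP only marginally; region classification is the recommended method,
as field-region membership is the standard way such configurations are
categorised.

## Fields and their statistics

`detect_fields()` finds 26-connected regions above 30% of the map peak with
more than 64 voxels (at 2.5 cm resolution), a peak rate above 1 Hz and more
than five visits (a visit = a run of in-field samples separated from the
next by at least 1 s). Field shape comes from the eigen-decomposition of the
voxel second central moments (`field_axes_voxels()`, solid-ellipsoid
convention with a 1/12-voxel term); the elongation index is
`P1 / (0.5 (P2 + P3))` in 3D and `P1/P2` on the planar arena. The
elongation null (`elongation_shuffle()`) resprays the field's spikes from an
isotropic Gaussian at the field centroid, assigns them to the nearest
trajectory points, rebuilds the adaptive map and re-extracts the elongation;
a field is nonspherical when its observed elongation exceeds the null by
z > 1.96. The respray width is `sigma = radius / 1.8`, where the radius
comes from the equivalent diameter `(6 vf / pi)^(1/3)` of the field's convex
volume `vf`: a Gaussian field thresholded at 20% of its peak extends to
`sqrt(2 ln 5)` (about 1.8) standard deviations, so this width re-creates a
field of the observed size. (This factor is sometimes worded as the s.d.
being 1.8 times the radius; with that reading the respray cloud is about
three times wider than the field it models and the test loses both
calibration and power, so the threshold-consistent reading is implemented.)
Convex volumes are Monte-Carlo estimates with a Frank-Wolfe
distance-to-hull membership test, matching the voxelised convex-image
convention (the hull dilated by half a voxel); no computational-geometry
dependency is required.

Distribution statistics: `orientation_axis_test()` counts field axes within
30-degree caps around each Cartesian axis against a uniform-axis
Monte-Carlo band (the analytic chance fraction is `1 - cos 30` = 13.4% per
axis); `vmf_density()` renders a spherical kernel density of axis vectors;
`layer_distribution_test()` compares per-lattice-layer field proportions
with uniform draws (chance centred on 1/6); `fields_per_m3()` normalises
field counts by the volume sampled for more than 0.1 s per voxel;
`field_size_cv()` tests within-cell field-volume consistency against
identity shuffles; `interfield_cv()` measures local order as the CV of
deduplicated 3-nearest-neighbour interfield distances, with a
field-count-matched circular-shift null (shuffles are accepted only when
they produce a field count within 3 of the observed).

`field_shuffle()` randomises field *positions* while preserving everything
else: the oversmoothed map (3-bin Gaussian) is segmented by assigning every
visited voxel to its nearest H-maxima peak (H = 0.2; for isolated point
seeds this nearest-seed assignment is exactly the watershed of the peak
distance transform), each field's peak moves to a random visited bin, and
the remaining bins follow field by field to the nearest free visited bin in
city-block distance. The value multiset, the peak rate and the unvisited
mask are preserved exactly -- the tests assert this bin for bin.

## Information, stability, direction, and temporal measures

`spatial_information()` reports both Skaggs conventions -- bits/s
`sum p_i lambda_i log2(lambda_i/lambda)` and bits/spike
`sum p_i (lambda_i/lambda) log2(lambda_i/lambda)` -- which satisfy
`bits_s = lambda x bits_spike` exactly; the published formula is typeset as
the per-spike form but labelled bits/s, so both are always available, along
with sparsity `(sum p_i lambda_i)^2 / sum p_i lambda_i^2`.
`spike_shift_shuffle()` standardises any statistic against circular
spike-train shifts (minimum 20 s, 0.02 s granularity; the two printed shift
granularities, 0.02 and 0.2 s, are reconciled to the finer one, which
subsumes the coarser). The z threshold 1.96 is quoted as "the shuffle 95th
percentile"; 1.96 is strictly the two-sided 97.5% point, and
where a 5% false-positive rate matters (the calibration tests) exceedance of
the empirical 95th percentile of the shuffle values is used instead.
`split_half_stability()` correlates first- and second-half maps over
mutually visited bins, with `stability_null()` providing the
mismatched-cell null. `movement_epoch_split()` partitions a session at
|pitch| = 30 degrees -- the boundary that divides the direction sphere into
equal areas. `directional_tuning()` builds 6-degree azimuthal tuning curves
(circularly smoothed, 3 bins) with Rayleigh vector length;
`directional_population_stability()` tests allocentric stability of the
pooled population curves against independently rotated copies.

`spike_autocorrelogram()` histograms spike-pair lags (plus/minus 500 ms,
10 ms bins; normalised to the 100-150 ms maximum with values above 1
removed); `theta_fit()` fits
`y(t) = (a (sin(2 pi w t + pi/2) + 1) + b) exp(-|t|/tau1) + c exp(-t^2/tau2^2)`
by bounded L-BFGS-B from five fixed starting points (bounds: `w` in [6, 12]
Hz, `c` in [0, 0.8], `tau2` in [0, 0.05] s, amplitudes non-negative; the
Gaussian term's argument is the lag). Only cells with at least 500 spikes
are fitted; `a/b` is the theta-modulation strength. `speed_rate_score()`
regresses mean instantaneous rate (20 ms bins, 13-bin Gaussian window) on
2 cm/s speed bins.

## What the synthetic data does and does not emulate

The trajectory generator reproduces the statistical features the analyses
are sensitive to: lattice-constrained, axis-aligned movement with a
horizontal bias and a floor-dwell bias, realistic speeds with persistent
fluctuations, and dense volumetric coverage over 20-minute-scale sessions.
It does not model biomechanics, posture, inter-animal variability, or
tracking artefacts beyond small Gaussian jitter, and spike generation is a
pure inhomogeneous Poisson process with no theta rhythmicity, adaptation or
bursting (theta modulation is simulated separately for the temporal module).
Passing tests on these data therefore demonstrate that the statistics
recover known ground truth under the study's geometry and sampling, not that
they are robust to every pathology of real recordings.

## Numerical choices and problem sizes

All stochastic procedures take explicit seeds; session-level master seeds
derive per-stage seeds deterministically. Gaussian smoothing renormalises
the kernel at volume borders; gaps longer than 1 s are left unfilled and
dropped. The test suite and the acceptance script run the planar pipeline at
a 21^3 map / 41^3 autocorrelation (the scale at which the FCC plane
geometry is crisp) with 65 x 65 plane sampling, and the configuration-
recovery battery at 2.5 cm voxels with 33 x 33 plane sampling and 20
simulations per kind -- sizes chosen to exercise the full method at
desk scale. Shuffle calibrations use 100-200 synthetic cells with 100
shuffles each on 2D arena sessions.

## Known limitations

* **HCP versus FCC by structure scores.** On simulated HCP arrangements the
  maximal-SGS planes sit 60 degrees from the hexagonal azimuths -- the FCC
  signature -- rather than at the hexagonal azimuths as descriptions of this
  analysis state, so `chi_hcp` carries little contrast and HCP recovery by any of
  the classifiers is near chance for large spacings (where only 2-3 field
  layers fit the maze). The package states this openly rather than adjusting
  the scores; use `vertical_self_similarity()` (layer-repeat at 2 vs 3 times
  `0.816 d`) to separate the two packings.
* Plane scores are undefined (NA) whenever a slice shows fewer than seven
  autocorrelation peaks; cells with very large spacing may be unscorable
  throughout, and are reported as such, never imputed.
* The adaptive estimator smooths aggressively where sampling is thin;
  quantitative comparisons between maps should use the histogram estimator,
  as the stability analyses do.
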