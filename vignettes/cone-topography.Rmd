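---
title: "Foveolar cone topography: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveolar cone topography: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conetopo)
```

`conetopo` turns annotated cone center coordinates into quantitative foveolar
topography: continuous density maps, the topographic landmarks PCD and CDC,
eccentricity profiles, a four-parameter sigmoid density model, angular
rugosity, and a normative-cohort machinery to recover centrally occluded
profiles. This vignette explains the underlying models and estimators, the
parameters that matter, and the design choices made where more than one
reasonable implementation exists.

## The density estimator

Cone density at a point is estimated from the 150 cones nearest to it: the
estimate is `k / (total Voronoi cell area of those k cones)` with `k = 150`,
reported in cones/mm². Equivalently, it is the reciprocal of the mean cell
area of the selected cones. Compared to a fixed-size counting window, the
analysis area adapts to local density — about 30 µm across at the foveolar
peak and growing with eccentricity — which is what makes a continuous map of
the rapidly changing foveolar density meaningful. The choice `k = 150`
balances robustness to annotation jitter against preservation of local
density structure, and is the convention this package follows throughout
(configurable via the `k` argument).

Cell areas are computed once from one global Voronoi tessellation
(`deldir`), then summed per query; this is mathematically identical to
re-tessellating per query point and vastly cheaper. Cones on the convex hull
have unbounded cells; rather than clipping them to some window (which would
bias areas downward near the mosaic border), any query whose 150 nearest
cones include an unbounded cell returns an explicit invalid marker. The
usable region of a density map therefore ends roughly one window-radius
inside the annotated area, and everything downstream treats invalid grid
points as missing.

On perfect lattices the estimator reproduces the closed forms
`2/(sqrt(3) s^2)` (hexagonal) and `1/s^2` (square) to well under 0.5%; these
oracles anchor the test suite.

`compute_density_map()` evaluates the estimator on a regular grid (default
spacing 1 µm; the examples and tests mostly use 2–4 µm, which changes
landmark estimates by far less than the estimator's own smoothing). Nearest
neighbours are found with a k-d tree (`RANN`); ties at exactly equal
distance are broken by the library's internal order. Ties occur only on
exact lattices, which no annotated mosaic ever is.

## Landmarks: PCD, CDC, D0

The peak cone density (PCD) is the single highest valid map value. Because a
single-pixel maximum is noisy, the topographic center is instead defined as
the cone density centroid (CDC): the density-weighted centroid of the
connected region (8-connected) of grid points with density at least 80% of
the PCD that contains the PCD. `D0`, the density at the CDC (bilinear
interpolation between grid nodes), is the central density statistic and the
normalizer of all profiles; by construction `D0 <= PCD`, and on realistic
mosaics it sits 0–2% below it. The area of the top-20% region is reported as
`isoa_top20`. If that region touches the border of the valid map a warning
flag is set, since the centroid may then be truncated.

## Profiles

All profiles are referenced to the CDC (eccentricity `E = 0`).

* **Meridional** (`meridional_profile`): mean of valid map values per
  eccentricity bin inside an isosceles triangle sector with a 5° vertex
  angle at the CDC. Bin width defaults to the grid spacing. The full
  horizontal/vertical meridians pool the two opposite sectors.
* **Radial** (`radial_profile`): per eccentricity, the mean of map values
  sampled around the full circle (bilinear interpolation at 1° steps). The
  profile is truncated at the largest radius whose circle lies entirely in
  the valid region; partial circles are rejected rather than renormalized,
  so a missing sector cannot silently bias the average.
* **Circular** (`circular_profile`): density around one circle, indexed by
  angle in retinal convention — 0° = nasal, 90° = superior retina. The map
  carries the eye's laterality; for right eyes the x-axis is mirrored so
  that fellow eyes are comparable in retinal coordinates.
* **Intercone distance** (`intercone_distance_profile`): per-cone ICD is
  defined here as the mean distance to the cone's Delaunay (equivalently,
  Voronoi-neighbor) cones, hull cones excluded; values are binned by
  eccentricity and smoothed with a centered 11 µm moving mean, truncated at
  the domain ends. ICD has no universally agreed definition; the
  Voronoi-neighbor mean is this package's choice, and on locally hexagonal
  mosaics it satisfies `ICD ≈ sqrt(2/(sqrt(3) D))`.

Angular and linear units interconvert through the retinal magnification
factor (RMF, µm per degree of visual angle), an individual, biometry-derived
per-eye quantity carried as metadata; `convert_units()` implements the
arithmetic and a default of 291 µm/° (emmetropic approximation) is used when
no individual value is supplied.

## The sigmoid density model

Density profiles are modeled as

$$D(E) = \frac{D_0}{\left(1 + (E/a)^b\right)^c}$$

with `a` (µm) a horizontal scale setting where the drop-off begins, `b` the
sharpness of the drop, and `c` the flatness of the tail. The fraction-of-D0
crossing has the closed form `E_f = a ((1/f)^{1/c} - 1)^{1/b}`, which is the
exact inverse of the model and is used for reporting (e.g. the eccentricity
where density halves).

`fit_profile()` minimizes raw density residuals (not log-density — residuals
are reported and interpreted on the density scale) under the box constraints
`a ∈ [0.1, 150]`, `b ∈ [1, 3]`, `c ∈ [0, 1]`, with bisquare robustness:
iteratively reweighted bounded Levenberg–Marquardt (`minpack.lm::nlsLM`)
with Tukey bisquare weights, tuning constant 4.685 (the conventional 95%
Gaussian-efficiency value), scale from the median absolute residual, outer
iterations until the relative parameter change is below 1e-8. In the default
mode `D0` is fixed at the measured density at the CDC and only `{a, b, c}`
are fitted; a free-`D0` mode exists for cases where no reliable central
measurement is available.

Two numerical points deserve mention. First, the model is weakly identified:
`a` and `c` trade off along a shallow valley, so a purely local optimizer
started at an extreme corner of the box can stall at a visually acceptable
but parametrically wrong solution. The fitter therefore always also tries
the normative radial seed, and falls back to a small deterministic grid of
starts if the best solution still has a mean relative error above 5%; the
best weighted solution wins. With this scheme, noiseless self-fits recover
the generating triplet to machine precision from arbitrary in-box seeds.
Second, fits are seeded by default at the group-average radial triplet, the
same convention used when refitting occluded eyes.

`fit_error()` reports `|D_data − D_fit| / D_fit` per eccentricity and its
mean — the error is measured relative to the fitted model, so a profile
uniformly 2% above the model has a mean error of exactly 0.02.

## Rugosity

Rugosity quantifies deviation from rotational symmetry. For each of a set of
eccentricities (default 15–240 µm in the ten steps used for the map-wide
analysis), the D0-normalized circular profile is smoothed with an 11°
circular moving mean, peaks and troughs are detected with wrap-around
(alternation enforced by discarding the lesser of adjacent same-type
extrema), and each extremum's angular width is delimited by the half-height
crossings on its two flanks — the angle where the profile crosses the mean
of the adjacent peak and trough values. Widths tile the circle by
construction. Rugosity is the sum of trough widths over the sum of peak
widths ("combined" ratio read as a sum ratio; a per-pair mean is the main
alternative reading and differs only in weighting). A value above one means
the high-density crests (on the horizontal meridian, in typical eyes) are
narrower than the low-density troughs — a horizontal ridge.

The 11° smoothing window is a package choice: wide enough to suppress
annotation-scale angular noise, narrow enough to leave the 2-cycle structure
of real maps untouched. Profiles with angular CV below 1% are declared flat
and excluded rather than forced to produce spurious extrema. Exact
`cos(2θ)` modulation gives four 90° widths and rugosity exactly 1;
`exp(k cos 2θ)` modulation gives rugosity > 1, increasing in `k` — both
serve as oracles in the tests.

## Occlusion recovery

When a central disk (radius 25–175 µm) of an image is unusable, `D0` cannot
be measured directly, but density just outside the disk still carries
information about it. Against a normative cohort of radial profiles on a
common grid, the package computes the mean z-score of the occluded eye in a
50 µm ring adjacent to the occlusion — per-eccentricity z-scores
`(individual − cohort mean)/cohort SD`, averaged over the ring — and plugs
it into a per-radius ordinary least-squares regression of `D0` on ring
z-score fitted on the cohort. Averaging (rather than integrating) the
z-scores over the ring, the 50 µm width, and the univariate regression are
the package's readings of the procedure; widening the ring or adding
further predictors has been reported not to help. The regression is fitted
separately per occlusion radius.

With `D0` estimated, the sigmoid is refitted to the visible profile with
`D0` fixed and the group-average triplet as seed; evaluating the result
inside the occlusion reconstructs the missing center, and when ground truth
is available the relative error is reported per eccentricity. Validation
uses a leave-one-out protocol — the reference never includes the test eye.

## The synthetic generator

`generate_mosaic()` produces the study material for all end-to-end tests: a
cone point pattern whose local density follows a prescribed 2-D field. The
field (`target_density`) extends the 1-D sigmoid by interpolating the shape
triplet between a horizontal and a vertical meridian triplet with
`cos²(θ)` weights (smooth, symmetric, and exact on both axes), optionally
multiplied by an angular modulation `exp(k cos 2θ)` normalized by the
Bessel factor `I0(k)` so its angular mean is one. The default field uses the
normative meridional triplets and `D0 = 175,500` cones/mm², a field radius
of 300 µm, and annotation jitter of 0.25 µm — the conditions the rest of the
package is validated under.

Placement warps a uniform hexagonal lattice of density `D0` (seeded random
rotation and offset) radially, so that the cumulative radial cone mass along
each ray matches the target field: if `M(R, θ)` is the target mass integral
along the ray, a lattice point at polar radius ρ maps to the radius `R`
solving `M(R, θ) = D0 ρ²/2`. Because the angular coordinate is kept, the
area Jacobian involves only the radial derivative, so local density is
matched exactly (measured fidelity is ~1%, against a 5% contract) while the
arrangement stays quasi-hexagonal — interior cones have 5–7 Voronoi
neighbors, with cell aspect ratios growing mildly toward the field edge
where the radial and tangential stretch factors diverge. The mass table is
tabulated at 0.5 µm × 1° resolution and inverted by monotone interpolation.

Jitter is isotropic Gaussian per cone, applied after placement, modeling
annotation click noise. A minimal dither of 2 nm is always applied even when
jitter is disabled: exactly cocircular lattice configurations are degenerate
inputs for Delaunay/Voronoi codes (and can corrupt the tessellation), and no
annotated mosaic is ever exact — the dither is three orders of magnitude
below cone spacing and has no measurable effect on any statistic. One seeded
generator drives each mosaic; the same seed and configuration reproduce the
coordinate list bit-identically, and the seed is recorded in the mosaic's
provenance string.

What the generator does *not* emulate: cone reflectance and image formation,
rods (which intrude into real mosaics beyond ~150 µm and perturb regularity),
the foveal avascular zone, montage seams, and annotation error modes other
than isotropic jitter (misses, false positives, merge/split errors).
Passing tests on synthetic mosaics therefore validate the estimators and
the pipeline plumbing — not the biological realism of any particular
density value.

## Synthetic cohorts

`simulate_profile_cohort()` draws profile-level cohorts for validating the
normative-reference machinery: `D0` from a truncated normal with mean
175,474, SD 20,543, range 136,001–216,209 cones/mm² (the normative cohort
statistics), shape triplets jittered around the group-average radial triplet
with relative SDs of 10% (`a`), 5% (`b`) and 8% (`c`), clamped to the
constraint box, plus 2% multiplicative bin noise. The triplet SDs are not
published; they were chosen once so that the simulated spread of the
half-density crossing matches the reported ±17 µm (≈11%) scale. On such
30-eye cohorts, leave-one-out `D0` estimation errors grow with occlusion
radius (medians ≈2–5% over 25–175 µm) and reconstruction error peaks at the
center — the qualitative signatures expected of the method.

## Problem sizes and runtime choices

The shipped tests and examples use field radii of 120–300 µm (≈5,000–23,000
cones), map spacings of 2–4 µm, and cohorts of 6–30 profiles; these sizes
were chosen so the full suite exercises every pipeline stage end-to-end in
a couple of minutes while keeping every tolerance meaningful. All estimator
contracts (5% generator fidelity, 0.5% lattice oracles, 2% fit error) are
stated independently of problem size and hold with margin at these sizes.

## Known limitations

* The usable map region excludes a border strip (unbounded-cell policy); on
  small mosaics the top-20% region may touch that border, which is flagged
  but not corrected.
* The CDC definition assumes the top-20% super-level region is connected;
  maps with multiple disjoint peaks keep only the component containing the
  PCD.
* Circular profiles crossing invalid regions are rejected outright; there is
  no partial-circle mode.
* The sigmoid model forces a monotone decay to a zero asymptote; mosaics
  with genuinely non-monotone profiles (pathology) will fit poorly, and the
  fit error — not a refusal — is the signal.
* Rugosity is reported per eccentricity without a cross-eccentricity
  summary, and its extrema detection assumes a dominant low-order angular
  structure.
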