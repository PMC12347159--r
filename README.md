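# conetopo

Quantitative analysis of cone photoreceptor topography in the human foveola,
from annotated cone center coordinates.

High-resolution retinal imaging (adaptive optics scanning light
ophthalmoscopy) resolves individual cone photoreceptors in the living eye.
Once cone centers have been annotated, the scientific questions are
topographical: how dense is the mosaic at its center, where exactly *is* the
center, how fast does density fall off with eccentricity, how anisotropic is
the fall-off, and what can be said when the centermost cones are not
resolved? `conetopo` implements this analysis chain for researchers in
vision science and ophthalmology:

- **Continuous density mapping.** Cone density at any point is estimated
  from the 150 nearest cones as `150 / (sum of their Voronoi cell areas)`,
  in cones/mm² — an analysis window that adapts its size to local density.
- **Topographic landmarks.** The peak cone density (PCD) is the highest map
  value; the cone density centroid (CDC) is the density-weighted centroid of
  the region enclosing the top 20% of density values, and serves as the
  eccentricity origin. `D0` denotes density at the CDC.
- **Profiles and model.** Meridional (5° sectors), radially averaged,
  circular, and intercone-distance profiles around the CDC; all density
  profiles are described by a four-parameter sigmoid decay

  `D(E) = D0 / (1 + (E/a)^b)^c`

  with eccentricity `E` in µm, fitted by constrained nonlinear least
  squares with bisquare robustness (`a ∈ [0.1, 150]`, `b ∈ [1, 3]`,
  `c ∈ [0, 1]`).
- **Rugosity.** Deviation from rotational symmetry, quantified per
  eccentricity as the ratio of trough to peak half-height angular widths of
  circular density profiles.
- **Occlusion recovery.** When a central disk of the mosaic is unusable,
  `D0` is estimated by regressing it on the mean density z-score in a 50 µm
  ring adjacent to the occlusion (against a normative cohort), and the
  central profile is reconstructed by refitting the sigmoid with the
  estimated `D0` anchored.
- **Synthetic mosaics.** A generator produces quasi-hexagonal cone point
  patterns following a prescribed anisotropic sigmoid density field (with
  controllable angular rugosity, annotation jitter, and occlusion), used
  throughout the test suite and available for simulation studies.

## Worked example

Generate a synthetic eye with the normative anisotropic density field,
map it, and analyze it:

```r
library(conetopo)

cfg    <- generator_config(seed = 1, jitter_sd = 0)   # D0 = 175,500 cones/mm^2
mosaic <- generate_mosaic(cfg)
mosaic
#> Cone mosaic: 22825 cones, rmf = 291 um/deg, laterality = synthetic

map <- compute_density_map(mosaic, grid_spacing = 2,
                           xlim = c(-260, 260), ylim = c(-260, 260))
tm  <- compute_cdc(map)
tm
#> PCD = 174019 cones/mm^2 at (0.0, 0.0) um
#> CDC at (-0.00, -0.05) um; D0 = 174017 cones/mm^2 (0.00% below PCD)
#> top-20% iso-density area: 12484 um^2

rp  <- radial_profile(map, tm$cdc_location)
fit <- fit_profile(rp, fix_d0 = tm$d0)
fit
#> Sigmoid density model: D0 = 174,016.9 cones/mm^2, a = 61.57 um, b = 2.231, c = 0.3122
#> mean |relative error| = 0.049%; converged: TRUE

fraction_crossing(fit$params, 0.5)   # eccentricity of the 50%-of-D0 crossing
#> [1] 158.21
profile_slope_metrics(fit)           # steepest descent of the fitted profile
#> $max_slope   -806.0  (cones/mm^2)/um
#> $inflection    53.3  um
```

The measured `D0` sits ~1% below the generator's 175,500 because the
150-nearest-cone window averages over the very peak. The radial 50% crossing
of this synthetic eye (158 µm) falls between the normative vertical (144 µm)
and horizontal (171 µm) crossings, as it must for a field that interpolates
the two meridians; the maximum slope (−806 (cones/mm²)/µm at 53 µm) is
within the normative spread (−870 ± 184 at 51 ± 8). `run_pipeline()` chains the same steps over a synthetic cohort of
fellow-eye pairs and reports cross-eye correlations; see the methods
vignette (`vignettes/cone-topography.Rmd`) for the model details and design
choices.

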