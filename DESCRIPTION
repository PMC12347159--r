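Package: conetopo
Title: Foveolar Cone Photoreceptor Topography Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of foveolar cone photoreceptor
    topography from annotated cone center coordinates. Computes continuous
    cone density maps with a 150-nearest-cone Voronoi estimator, locates the
    peak cone density (PCD) and the cone density centroid (CDC), extracts
    meridional, radial, circular and intercone-distance profiles, fits a
    constrained four-parameter sigmoid decay model with bisquare robustness,
    quantifies angular rugosity of the density map, and reconstructs
    centrally occluded density profiles by z-score regression against a
    normative cohort. Includes a synthetic mosaic generator that produces
    quasi-hexagonal cone point patterns following a prescribed anisotropic
    density field, for validation and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deldir,
    RANN,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
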