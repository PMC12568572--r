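Package: retinavasc
Title: Retinal Vascular and Optic Nerve Head Morphometry from Fundus Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative morphometry of the retinal vasculature and optic nerve
    head on disc-centered 45-degree color fundus photographs: multiscale
    vesselness segmentation, optic disc and cup detection, centerline graph
    extraction, and nine per-eye parameters (vascular fractal dimension,
    caliber, tortuosity, density, branching angle, arteriole-to-venule ratio,
    disc area, cup area, cup-to-disc ratio), measured globally and in
    peripapillary annuli and quadrants defined in disc-diameter units.
    Includes a synthetic fundus simulator with exact ground truth (vessel
    trees obeying a Murray-type caliber taper, disc and cup geometry, cohort
    covariates) for validating every stage, and a covariate-adjusted (ANCOVA)
    statistical layer for two-cohort comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    emmeans
Config/testthat/edition: 3
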