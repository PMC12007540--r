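Package: tractlife
Title: Lifespan Trajectories of White Matter Bundle Shape, Microstructure and Cortical Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of diffusion MRI tractography for lifespan studies:
    reads streamline bundles (TRK/TCK) and scalar volumes (NIfTI), derives the ten
    macrostructural shape metrics of a bundle (volume, endpoint volume, length, span,
    curl, diameter, elongation and surface areas), samples microstructure and cortical
    maps along tracts and at streamline endpoints, harmonizes multi-cohort feature
    tables under continuity assumptions, fits covariate-adjusted restricted cubic
    spline (C-RCS) age trajectories with case-resampling bootstrap bands, derives
    cross-sectional rates of change, peak ages with confidence intervals and
    cohort-averaged rates, and runs the cross-feature, cross-pathway and
    development-versus-aging correlation analyses with false discovery rate control.
    Includes synthetic generators for bundles with known analytic geometry and for
    lifespan feature tables with known ground truth, so the whole pipeline is testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
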