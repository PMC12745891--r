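Package: motion4d
Title: Simulation and Displacement Assessment of Respiratory-Binned 4D-MR
    and 4D-CT Acquisitions of a Motion Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing respiratory motion quantification protocols
    in four-dimensional magnetic resonance (4D-MR) and computed tomography
    (4D-CT) imaging. Generates sinusoidal and patient-like respiratory
    surrogate traces, sorts them into amplitude-based (MR-style) or
    phase-based (CT-style) respiratory bins, simulates binned acquisitions
    of a moving contrast-sphere phantom with a golden-angle radial
    stack-of-stars forward model, measures superior-inferior displacement
    from full-width-at-half-maximum edges of line intensity profiles, and
    compares protocols with Welch's ANOVA, Games-Howell post hoc tests and
    linear mixed-effects models.  Also reproduces box-ROI organ displacement
    arithmetic (per-direction translations, Euclidean norms, modality
    difference tables) for in-vivo protocol comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    RNifti,
    jsonlite,
    lme4,
    lmerTest,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
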