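Package: ossimotion
Title: Phase-Gated Tomographic Motion Analysis of the Ossicular Chain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying periodic rigid-body motion from
    time-resolved (phase-gated) tomographic volume series, motivated by
    dynamic synchrotron microtomography of the acoustically stimulated
    human middle ear. Provides retrospective phase gating of projection
    streams against a sinusoidal stimulation signal, intensity-based
    rigid registration of sub-volumes across motion phases, axis-angle
    transform algebra with origin re-expression and robust per-phase
    averaging, displacement tracking of anatomical regions of interest
    with constrained sine fitting, planar quality-control projections,
    and a synthetic 4D phantom generator with known ground-truth motion
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'demo-phantom.R'
    'displacement.R'
    'io.R'
    'kinematics.R'
    'phantom.R'
    'pipeline.R'
    'planar.R'
    'postgating.R'
    'registration.R'
    'transforms.R'
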