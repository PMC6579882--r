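Package: somatoseg
Title: Segregation of Motor Somatotopy Maps Across fMRI Acquisition Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantifying how fMRI
    acquisition protocols (voxel size, volume TR, number of volumes, 2D vs 3D
    encoding) affect the segregation of motor somatotopy representations in
    cortical and subcortical regions of interest. Generates block-design motor
    paradigms and synthetic BOLD time series with known pattern structure, fits
    subject-level general linear models with a canonical haemodynamic response
    function, estimates pattern-component covariances by expectation-
    maximization, converts them to an Index of Similarity (the absolute Fisher
    z-transformed pattern correlation) with Z-tests and false-discovery-rate
    control, computes temporal signal-to-noise metrics and their acquisition-
    weighted variants, extracts somatotopy geometry (centers of mass,
    activation maxima, ordering checks, principal-axis projections), and
    relates segregation to BOLD sensitivity with correlation, ANCOVA, MANOVA
    and ANOVA group statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
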