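Package: fusmap
Title: Functional Ultrasound Imaging Analysis: Clutter Filtering,
    Tonotopy, Decoding and Functional Resolution
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for event-related functional ultrasound (fUS)
    imaging experiments. Turns complex ultrafast Doppler frame blocks into
    power-Doppler images and percent cerebral blood volume (%CBV) series
    via singular-value-decomposition clutter filtering, optional axial
    blood-velocity band selection and baseline normalization; epochs the
    1 Hz %CBV series into trials and computes windowed responses, per-voxel
    frequency tuning statistics, mean hemodynamic responses and
    finite-impulse-response GLM estimates; post-processes best-frequency
    (tonotopic) maps with display masking, smoothing, surface projection,
    cortical depth layering and across-session slice matching; decodes
    stimulus identity from multivoxel response patterns with leave-one-out
    linear and Fisher (covariance-normalized) classifiers, pseudo-population
    assembly and label-permutation nulls; and estimates the functional
    spatial resolution of the imaging signal from pairwise two-way ANOVAs
    over voxel pairs against a randomization null. A fully seeded synthetic
    data generator emulates the trial structure, tonotopic gradients,
    hemodynamics and tissue/blood frame content needed to validate every
    step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
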