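Package: ecstrace
Title: Tracer Kinetics of the Brain Extracellular Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies diffusion and clearance in brain extracellular space
    (ECS) from dynamic contrast-enhanced image series of a locally injected
    tracer such as Gd-DTPA. Provides the analytic point-source
    diffusion-clearance forward model, a finite-difference PDE oracle for its
    validation, a seeded synthetic-cohort generator (four treatment groups,
    rendered 4-D image series with Gaussian noise), per-animal estimation of
    the effective diffusion coefficient (D*), clearance coefficient (k'),
    maximum distribution-volume ratio (Vd-max%) and half-life (t1/2) by
    bounded nonlinear least squares, and group statistics: one-way ANOVA from
    raw data or published summaries, Fisher's LSD post-hoc tests, Pearson
    correlation inference, and a sample-size consistency auditor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
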