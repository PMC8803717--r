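Package: dtialps
Title: Simulation and Analysis Along the Perivascular Space for Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the DTI-ALPS family of diffusion-MRI analyses of
    glymphatic/interstitial fluid dynamics: a synthetic corona-radiata
    diffusion phantom with a two-compartment (fiber + perivascular) tensor
    model, Rician-noise diffusion-weighted signal simulation under varying
    gradient schemes, head positions, echo/diffusion times and scanner noise
    profiles; a log-linear diffusion tensor fit and a 3-axis per-direction
    ADC path; ROI machinery and the ALPS index in unilateral and bilateral
    forms; test-retest reliability statistics (ICC(2,1) with confidence
    intervals and Landis-Koch labels, paired comparisons, repeated-measures
    ANOVA); and a study harness that runs a multi-condition acquisition
    experiment end to end on a simulated cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
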