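Package: slme
Title: Spatial Linear Mixed Effects Models for Sector-Lattice Retinal Thickness Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits spatial linear mixed effects (SLME) models for optical
    coherence tomography retinal thickness measured on the nine-subfield
    ETDRS grid. The model combines nested random intercepts (eye within
    patient) with a spatially correlated within-eye residual process
    (autoregressive-by-lag, Gaussian, exponential or spherical kernels over
    sector centroid distances) and optional heteroscedastic residual
    weights by diagnosis group. Provides maximum likelihood and restricted
    maximum likelihood estimation via profiled quasi-Newton optimisation,
    generalised least squares fixed effects with model-based standard
    errors, BLUP prediction of random effects, Wald and likelihood-ratio
    tests, AIC/BIC model selection with a top-down strategy, a Monte-Carlo
    simulation harness for coverage and power studies, and a synthetic
    clinical-data generator for nested two-eye designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse
Config/testthat/edition: 3
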