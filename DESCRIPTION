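Package: afmcp
Title: Contact-Point Detection and Thin-Sample Elasticity for AFM Force
    Curves
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Automated detection of the tip-sample contact point in atomic
    force microscopy (AFM) force-displacement curves obtained on soft, thin
    samples, together with Young's modulus extraction by Sneddon cone and
    bottom-effect-corrected (BECC) thin-film contact mechanics. Implements
    four sequential-search test parameters (goodness of fit over the whole
    or low-indentation contact region, ratio of deflection variances,
    log-modulus derivative, and power-law exponent), their multiplicative
    combination, distribution-based metrics for benchmarking detection
    strategies over curve collections, and a ground-truthed synthetic
    force-curve generator that solves the implicit cantilever force balance,
    so that every analysis stage can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'afmcp-package.R'
    'curves.R'
    'contact_models.R'
    'cp_detect.R'
    'assessment.R'
    'synthetic.R'
    'pipeline.R'
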