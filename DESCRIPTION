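Package: twinDTI
Title: Twin-Based Heritability Analysis of Regional White-Matter Diffusion Metrics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates genetic and environmental contributions to white-matter
    microstructure from classical twin designs. Provides regional extraction of
    diffusion tensor scalar metrics (FA, MD, AD, RD) from skeletonised 4D maps
    using an integer label atlas, empirical-Bayes ComBat harmonization of
    scanner batch effects with preservation of age and sex covariates, age- and
    sex-adjusted double-entry twin correlations for monozygotic and dizygotic
    pairs, and constrained maximum-likelihood ACE/ADE variance-component
    decomposition with Falconer closed-form estimates as an internal check.
    A synthetic twin-cohort generator with known biometric structure supports
    end-to-end validation without access to imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva,
    optparse
biocViews: StatisticalMethod, BatchEffect, Genetics, Preprocessing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
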