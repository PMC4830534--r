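Package: gblupad
Title: Multivariate GBLUP with Dominance Effects for Single-Cross Hybrid Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genomic best linear unbiased prediction (GBLUP) of single-cross
    hybrid performance with additive and dominance effects, in univariate and
    multivariate (multi-trait) form. Builds Cockerham additive and dominance
    marker incidence matrices, VanRaden-style additive and dominance genomic
    relationship matrices with positive-definite repair, and estimates
    unstructured trait covariance components by EM-REML through Henderson's
    mixed-model equations. Includes a partial-diallel hybrid simulator with
    pleiotropic QTN architectures and heritability scaling, model-comparison
    statistics (predictive correlation, PRESS, estimated heritability) and
    k-fold cross-validation, so the full additive-versus-additive-dominance
    and univariate-versus-multivariate model comparison can be run end-to-end
    on synthetic genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
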