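Package: globeseed
Title: Standardization, Forest Modeling and Global Mapping of Soil Seed Bank Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for harmonizing heterogeneous soil seed bank survey records
    (sampling season, quadrat area, soil depth slice, density units), capping
    extreme values with a generalized extreme studentized deviate test, and
    modeling seed bank diversity and density against environmental predictors
    with regression forests. Includes noise-thresholded forward variable
    selection, repeated random-holdout cross-validation, partial dependence
    curves, spatial diagnostics (great-circle semivariograms, Kruskal-Wallis
    biome contrasts, hemisphere bias checks), and projection of fitted models
    onto gridded predictor stacks. A synthetic-data module generates record
    sets, predictor tables and predictor grids with a known ground-truth
    ledger so the whole pipeline can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
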