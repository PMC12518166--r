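Package: maxentSDM
Title: Maximum-Entropy Species Distribution Modelling with AICc Tuning and
    Range-Shift Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Presence-background species distribution modelling for montane
    plants on gridded environmental layers. Implements a from-scratch
    maximum-entropy (Maxent-type) model with linear, quadratic, product,
    hinge and threshold features and L1 regularization fitted by cyclic
    coordinate descent; feature-class and regularization-multiplier tuning
    by small-sample AICc; replicate train/test evaluation by ROC AUC;
    jackknife variable importance, percent contribution and response
    curves; occurrence cleaning and one-point-per-cell spatial thinning;
    four-class habitat-suitability classification with spherical per-class
    areas, scenario gain/loss bookkeeping and range-centroid shifts; and
    per-species elevation-versus-year trend regressions split at the year
    2000. A seeded synthetic-landscape generator with known ground truth
    makes the whole pipeline testable without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'ascii.R'
    'classify.R'
    'features.R'
    'fit.R'
    'grid.R'
    'importance.R'
    'maxentSDM-package.R'
    'occurrences.R'
    'pipeline.R'
    'samples.R'
    'synthetic.R'
    'trend.R'
    'tuning.R'
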