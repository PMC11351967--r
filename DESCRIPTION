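Package: octplaque
Title: Intravascular OCT Plaque Quantification and Outcome Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies coronary plaque from labeled intravascular optical
    coherence tomography (IVOCT) pullback segmentations and relates the
    resulting lesion features to a binary cardiovascular-death outcome.
    Ray casting from the lumen centroid yields per-frame lumen, calcium and
    fibrous-cap measurements; these are aggregated into 31 lesion-level
    features including thickness-stratified fibrous-cap surface area and
    burden in the unrolled en-face view. A statistical cascade (group
    comparison, Spearman redundancy pruning, univariate and multivariate
    logistic regression, ROC with bootstrap confidence intervals and a
    Youden-style cutoff) identifies outcome-associated features. Synthetic
    vessel phantoms with analytically known geometry and simulated cohorts
    with a known generative logistic model make every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
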