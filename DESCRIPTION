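Package: wolfselect
Title: Grey Wolf Optimizer Wrapper Feature Selection with Adaptive Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for high-dimensional, small-sample
    classification (e.g. microarray gene expression) using the grey wolf
    optimizer (GWO) and an adaptive variant (AMGWO) that adds nonlinear
    convergence-factor control, fitness-distance-balance reference selection,
    and adaptive neighborhood mutation. Continuous wolf positions are mapped
    to binary feature masks through a sigmoid transfer function and scored by
    the stratified k-fold cross-validated error of a K-nearest-neighbour
    classifier. Includes a synthetic high-dimensional dataset generator with
    planted informative features, ablation variants toggling each mechanism,
    and the nonparametric evaluation battery (best/worst/mean/std summaries,
    Wilcoxon rank-sum comparisons, Friedman mean ranks, convergence-trace
    aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
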