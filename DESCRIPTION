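Package: snpmeta
Title: Meta-Analysis of Genetic Association Studies
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for case-control genetic-association meta-analysis:
    odds-ratio extraction from genotype tables or reported confidence
    intervals, dominant/recessive genetic-model selection, Hardy-Weinberg
    equilibrium filtering of control series, fixed-effect and
    DerSimonian-Laird random-effects pooling with Cochran's Q, I-squared
    and tau-squared heterogeneity statistics, Egger regression and Begg
    rank-correlation publication-bias tests, Galbraith (radial) outlier
    detection, leave-one-out sensitivity analysis, and stratified subgroup
    analysis. Ships a transcribed study-level table of CYP1A2 polymorphism
    case-control studies and a genotype-level simulator for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
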