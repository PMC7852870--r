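Package: cocultr
Title: Quantitative Analysis of Two-Species Coculture Experiments on
    Phenotype Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing two-species bacterial coculture experiments
    carried out across many carbon sources on Biolog GEN III phenotype
    microarray plates. Normalises raw absorbance readings into carbon usage
    efficiency (CUE) values, quantifies species abundance from qPCR standard
    curves, calls per-carbon-source preferences from monoculture CUEs,
    compares final species ratios across initial inoculum ratios, classifies
    species interactions as positive, negative or unresolved against an
    abundance-weighted expected-CUE null model using sequential one-sided
    Welch tests, clusters carbon sources into usage groups, and relates CUE
    to experimental factors by multiple linear regression. A synthetic
    experiment generator with a ground-truth ledger makes every pipeline
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan
Config/testthat/edition: 3
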