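Package: batchscope
Title: Nested Variance Decomposition and Empirical-Bayes Batch Correction
    for Expression Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and removing systematic (batch) noise in
    log2 expression matrices from microarray experiments. Implements
    per-probe nested variance-component estimation (expected mean squares
    and restricted maximum likelihood) across hierarchical
    sample-processing levels (experiment, run, chip, array), a parametric
    empirical-Bayes location/scale batch correction, evaluation of generic
    (reference RNA) versus pooled inter-batch calibrators via duplicate
    sample shifts, probe GC-content vulnerability analysis, detection
    filtering, quantile normalisation, and a simplified differential
    expression stage. Includes a synthetic-data generator that emulates the
    nested batch structure, control replicates and GC-dependent probe
    vulnerability, with full ground truth for recovery testing, and an
    end-to-end seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva,
    nlme,
    optparse,
    withr
Config/testthat/edition: 3
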