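Package: barseqfit
Title: Fitness Inference and Downstream Analysis for Pooled Barcoded Knockout Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-gene invasion fitness effects from random-barcode
    transposon sequencing (RB-TnSeq/BarSeq) read-count trajectories. Implements
    barcode error merging and gene assignment, estimation of technical noise and
    effective population size from intergenic (neutral) barcodes on the
    square-root frequency scale, robust mean-fitness estimation from
    super-barcodes, negative-binomial integrated-likelihood fitness estimation
    with calibrated standard errors and neutrality calls, resampling-based
    outlier-barcode rejection (resistant diagnostic), measurement-error-weighted
    cofitness networks with community detection, environment-similarity
    clustering with bootstrap support, and regression models linking fitness
    effects to evolutionary outcomes. A synthetic-data generator with the full
    generative noise model (selection, genetic drift, sqrt-scale measurement
    noise, overdispersed read sampling) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
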