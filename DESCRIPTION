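Package: segstudy
Title: Sensitivity Analysis and Parameter Auto-Tuning for Image
    Segmentation Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale framework for parameter studies of multi-stage
    image segmentation workflows. Implements Morris one-at-a-time (MOAT)
    elementary-effects screening, correlation-based importance measures
    (CC, PCC, RCC, PRCC), variance-based decomposition with Saltelli
    designs (first-order and total Sobol indices), and black-box
    parameter auto-tuning (Nelder-Mead, Parallel Rank Order, Genetic
    Algorithm) driven by Dice/Jaccard mask-comparison objectives. Ships
    a simplified watershed-style nuclei segmentation pipeline, a
    deterministic generator of tissue-like synthetic tiles with ground
    truth, and a dataflow executor that merges workflow instances
    sharing common computation prefixes so simultaneous parameter
    evaluations run shared stages once, backed by a bounded two-level
    result store with FIFO/LRU eviction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    lhs,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
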