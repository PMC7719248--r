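Package: ecmiR
Title: Endogenous-Control miRNA Selection and Stability Analysis for RT-qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and validation of endogenous-control (reference)
    miRNAs from RT-qPCR cycle-threshold (Ct) data. Implements
    determination-level quality filtering, technical-replicate collapsing,
    global mean-centering with concordance-correlation-restricted (CCR)
    candidate selection, the geNorm pairwise-variation M value, the BestKeeper
    index and correlation statistics, the NormFinder model-based
    intra/intergroup stability value, per-gene Kruskal-Wallis group
    comparisons, and a consensus ranking that combines the three algorithms.
    Includes a synthetic plasma-qPCR data generator with ground truth so the
    whole pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
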