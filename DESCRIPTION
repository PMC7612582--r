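Package: qnflux
Title: Executable Qualitative-Network Model of Lymph Node Fibroblast Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete qualitative-network (QN) modelling engine in the
    BioModelAnalyzer style, together with a reference model of fibroblastic
    reticular cell (FRC) central carbon metabolism and an in-silico
    mitochondrial stress test. Nodes hold bounded integer activity levels and
    move one level per synchronous step toward the value of an arithmetic
    target function. The package parses and evaluates target-function
    expressions, simulates trajectories to fixed points or cycles, enumerates
    attractors exhaustively on small state spaces, reads and writes models in
    a BMA-dialect JSON format and a native plain-text format, and drives
    counter-scheduled oligomycin/FCCP/rotenone+antimycin-A perturbation
    protocols over the model's oxygen consumption rate (OCR) readout, with
    basal, ATP-linked, maximal, spare and non-mitochondrial summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
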