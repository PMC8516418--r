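Package: synaptoquant
Title: Quantitative Analysis of Single-Vesicle and Synaptic Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for the quantitative analyses used in
    single-vesicle endocytosis studies: cell-attached lock-in capacitance
    step detection with fission/fusion-pore conductance estimation,
    whole-cell equivalent-circuit (Lindau-Neher) inversion and delta-Cm
    quantification, endocytosis-associated patch-current drift and its
    current-voltage relationship, carbon-fiber amperometric spike and foot
    analysis with per-cell median summaries, pHluorin/GCaMP/iGluSnFR
    fluorescence kinetics (endocytic time constants, reacidification rates,
    calcium transients), and short-term-depression train metrics. A
    synthetic-recording generator produces every input class with known
    ground truth so each stage is verifiable by parameter recovery and
    analytic identity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
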