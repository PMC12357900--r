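Package: nfcrosstalk
Title: Canonical/Non-Canonical NF-kB Crosstalk Modeling and BH3-Mimetic
    Response Analysis in B-Cell Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic ordinary-differential-equation model of crosstalk
    between the canonical and non-canonical NF-kB pathways in B cells, in
    which basal B-cell-receptor driven IKK activity reroutes CD40/NIK
    stimulation from RelB:p52/BCLXL induction towards IkB-delta-mediated
    cRel:p50 release and MCL1 induction. Includes parameter-sampled
    virtual-cell ensembles, a minimal BCL2-family sequestration surrogate
    mapping nuclear dimer activity to BH3-mimetic viability curves with
    four-parameter-logistic LC50 extraction, flow-cytometry z-score
    fingerprinting, nuclear:cytoplasmic ratio summaries, TSS-window ChIP
    score aggregation with ROUT outlier removal, and synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    MASS,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
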