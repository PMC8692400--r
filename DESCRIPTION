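Package: reefnfix
Title: Coral-Associated Nitrogen Fixation Rates, Budgets and Diazotroph
    Activity from 15N2 Tracer Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of coral-associated dinitrogen fixation
    measured with dissolved 15N2 tracer incubations in the field. Converts
    isotope-ratio measurements between delta notation and atom percent,
    estimates diazotroph-derived nitrogen (DDN) assimilation rates per
    holobiont compartment with a 3-standard-deviation detection limit,
    standardizes rates by surface area, dry weight or volume, scales them
    into holobiont and reef-level nitrogen budgets, and summarizes relative
    diazotroph activity from paired DNA/RNA amplicon tables (RNA:DNA ratios,
    order-level aggregation, nifH cluster shares). A synthetic-data generator
    with known ground truth makes every stage testable without sequence
    downloads or instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    withr
Config/testthat/edition: 3
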