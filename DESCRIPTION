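Package: strataDiv
Title: Stage-Binned Fossil Diversity, Turnover and Coverage-Standardized Richness
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for global fossil-occurrence diversity analysis across
    ordered chronostratigraphic stages: validated ingestion and taxonomic
    normalization of long-format occurrence tables, selection filters for
    open nomenclature and reworked material, stratigraphic range construction
    (range-through method), per-stage diversity and boundary-crosser turnover
    indices with per-Myr rates, shareholder quorum subsampling by reference
    using Good's coverage estimator, Spearman rank diagnostics of sampling
    bias, and a synthetic fossil-record generator with known truth for
    validating every analysis stage. Defaults target the Wuchiapingian to
    Ladinian (Permian-Triassic) interval.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
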