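Package: cbbscan
Title: Genome-Based Screening of Calvin-Benson-Bassham CO2-Fixation Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens prokaryotic proteomes for the genetic potential to fix CO2
    through the Calvin-Benson-Bassham (CBB) cycle. Detects CBB marker genes by
    similarity search against curated seed sequences, classifies RubisCO
    large-subunit (RbcL) copies into phylogenetic forms against a labelled
    reference panel, applies marker-based rules to predict electron donors,
    electron acceptors and anoxygenic phototrophy, and aggregates per-genome
    trait profiles into taxon-level and isolation-environment summary tables.
    Includes a synthetic proteome simulator with known ground truth so the
    whole pipeline can be exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    yaml,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
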