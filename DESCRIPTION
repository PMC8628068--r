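Package: plasmidfit
Title: Plasmid Fitness Costs and Plasmid-Mutation Epistasis from
    Competition Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the fitness effects of antibiotic resistance
    plasmids from head-to-head competition assays against a fluorescent
    reference strain, and measures plasmid-by-mutation epistasis against
    the multiplicative null model with ANOVA/Tukey classification and a
    sign-epistasis test. Also computes plasmid sequence features used to
    screen for correlates of cost (per-ORF codon adaptation index against
    a reference codon-usage table, GC content, replicon size and a
    sequencing-depth-ratio copy-number proxy), and ships a synthetic
    competition-experiment generator with known ground truth so the whole
    analysis chain is testable without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
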