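Package: immunobalance
Title: Balance of Positive and Negative Immune Regulators in Skin Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compares the balance of negative (immunosuppressive) versus
    positive (inflammatory) immune-regulator gene expression between
    transient delayed-type hypersensitivity skin reactions (diphencyprone,
    DPCP) and chronic psoriasis lesions. Implements paired differential
    expression with empirical-Bayes variance moderation, expression
    filtering and empirical-Bayes batch adjustment, regulator gene-list
    construction from Gene Ontology term closures, transcriptome overlap
    and odds-ratio enrichment statistics, a negative-to-positive regulator
    balance score, and housekeeping-normalized qPCR group comparison.
    Ships a curated table of negative-regulator fold changes and a
    synthetic-data generator mirroring the paired placebo/treated design
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
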