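Package: seedtox
Title: Predicted 6mer Seed Toxicity Analysis of Small RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Seedtox", "Maintainers", email = "maintainers@seedtox.dev",
           role = c("aut", "cre"))
Description: Analyzes small RNA sequencing data by the predicted toxicity of
    the 6mer seed (positions 2-7) of each read. Starting from trimmed or raw
    reads, or from a unique-read count table, the pipeline builds annotated
    count tables (seed, seed viability, miRNA and small-RNA identity),
    collapses them by seed, bins them into 1%-viability Seed Tox profiles,
    expands them for rank tests and sequence logos, and fits a multinomial
    mixed-effects logit comparing positional seed composition between groups
    with Tukey-adjusted odds ratios. Includes a native negative-binomial
    exact test for differential read abundance and a seeded synthetic-data
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
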