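Package: AREmd
Title: AU-Rich Element Scoring and ARE-Mediated Decay Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of AU-rich element (ARE) mediated mRNA
    decay under oxygen shifts. Scores 3'UTR sequences for destabilizing
    AUUUA pentamers with clustering and AU-context bonuses, tests regulated
    transcript sets for ARE enrichment against randomized expressed-gene
    backgrounds (cumulative-frequency Kolmogorov-Smirnov comparison and
    dichotomized chi-squared tests with Bonferroni correction), contrasts
    reoxygenation repression between genotypes and ranks the most
    decay-factor-sensitive genes, and estimates mRNA half-lives from
    reference-normalized transcription-shutoff time courses by one-phase
    exponential decay. A synthetic-data module generates sequences, count
    experiments and decay series with the statistical structure the
    analysis assumes, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Sequencing, StatisticalMethod
RoxygenNote: 7.3.3
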