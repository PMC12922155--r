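Package: crossphos
Title: Cross-Species Comparison of Hormone-Responsive Phosphoproteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing hormone-responsive protein
    phosphorylation across plant species from label-free phosphoproteomics
    quantification tables. Provides readers for phosphopeptide tables and
    proteome FASTA files, responsiveness calling by fold-change and t-test
    gates, iterative motif-x style phosphorylation-motif enrichment against a
    whole-proteome background, ortholog-group assignment by lowest-E-value
    best hit with an internal Smith-Waterman backend, cross-species
    conservation accounting (ortholog matrices and three-set Venn regions),
    alignment-based phosphosite conservation classification, and a fully
    seeded synthetic-data generator with planted ground truth for testing
    every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
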