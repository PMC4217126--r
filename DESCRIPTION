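Package: mircross
Title: Integrative miRNA-mRNA Differential Expression and Seed-Target Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-group differential-expression calling on miRNA and
    mRNA expression matrices (empirical-Bayes moderated t, exact Wilcoxon
    rank-sum, and SAM-style permutation d-statistic with estimated FDR),
    canonical seed-match target prediction in 3'UTRs (6mer, 7mer-A1, 7mer-m8
    and 8mer site types), counting and ranking of miRNAs and genomic miRNA
    clusters by anticorrelated predicted targets, seed-hexamer enrichment
    ranking of regulated versus non-regulated gene lists by Wilcoxon rank-sum,
    and delta-delta-Ct relative quantification for qPCR. Includes a
    truth-known synthetic data generator for two-group microarray experiments
    with planted miRNA clusters and seed-bearing target genes, and an
    end-to-end discovery pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
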