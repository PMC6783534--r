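Package: fluorosig
Title: Mutational Signature Analysis of Fluoropyrimidine-Induced Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and quantify the chemotherapy-associated
    mutational signature dominated by T>G substitutions in a CTT context
    (COSMIC signature 17-like) from somatic single base substitution calls.
    Builds 96-trinucleotide-context mutation catalogs from VCF and FASTA
    input, extracts de novo signatures by non-negative matrix factorization
    with consensus-based cophenetic rank selection, refits catalogs against
    signature sets by non-negative least squares, attributes individual
    mutations to signatures by likelihood, times mutations as clonal or
    subclonal via variant-ploidy kernel density estimation, tests
    replication and transcription strand asymmetry, scans paired-biopsy
    count tables for treatment enrichment with linear mixed models, and
    models the expected number of oncogenic driver mutations introduced by
    a mutagenic exposure. Includes seeded synthetic-data generators with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR,
    nlme
Suggests:
    testthat (>= 3.0.0),
    pracma,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
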