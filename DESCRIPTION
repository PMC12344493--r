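Package: methylgate
Title: Methylome Annotation, Hypermethylated-Region Calling and
    Epigenetic Silencing of Laterally Transferred Genes
Version: 0.1.0
Authors@R:
    person("Marc", "Verdaguer", email = "mverdaguer@example.org",
           role = c("aut", "cre"))
Description: Tools to annotate 5-methylcytosine (5mC) methylomes of
    non-model eukaryotes from per-cytosine calls in CGmap format:
    context-aware weighted methylation levels, spike-in conversion QC
    (lambda / pUC19 controls), CpG dyad symmetry, gene-body metaprofiles,
    bimodality-based methylated/unmethylated gene classification with
    k-means validation, sliding-window hypermethylated-region calling,
    CpG-modified Kimura 2-parameter transposable-element ages, taxonomic
    origin assignment of genes from best-hit tables with Fisher exact
    enrichment of categories in the methylated fraction, detection of
    clustered viral-gene neighborhoods (endogenized giant-virus
    candidates), and Dollo parsimony reconstruction of ancestral DNA
    methyltransferase repertoires. Ships a ground-truthed synthetic
    methylome generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
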