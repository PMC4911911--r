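Package: pufclip
Title: Peak Calling, Motif and Crosslink-Site Analysis for PUF-Protein iCLIP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to map the binding landscape of PUF-family RNA-binding
    proteins (such as C. elegans FBF-1/FBF-2) from iCLIP data. Implements
    candidate peak discovery with 20%-of-height borders, six peak-calling
    strategies that test the tallest 50-nt read bin against Gaussian, Poisson
    or negative-binomial background models built from RNA-seq, negative-control
    iCLIP or the iCLIP signal itself (locally or over the whole mature
    transcript), Bonferroni and Benjamini-Hochberg control, fold-enrichment and
    replicate-consensus filters, PUF binding-element (FBE) motif scanning with
    upstream-context classification and shuffle-based enrichment tests,
    crosslink-site inference from read-through deletions (CIMS) and cDNA
    truncations (CITS), and binding-landscape statistics (feature assignment,
    peak un-merging, 3'-end bias, target-list overlap tests). A seeded
    synthetic-data generator produces genomes, annotation, ground-truth binding
    sites and read sets with iCLIP-like statistical structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
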