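Package: rddiff
Title: Replicate-Aware Detection of RNA-DNA and RNA-RNA Differences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects single-nucleotide differences between two sets of
    replicate sequencing samples (genomic DNA versus cDNA, or cDNA versus
    cDNA), the classic signature of RNA editing. Base-call count vectors at
    each site are modelled with a Dirichlet-Multinomial distribution to
    account for overdispersion across replicates, base-call qualities enter
    through a pseudocount adjustment, and sites are scored with a
    likelihood-ratio statistic against a pooled null. A panel of positional
    artifact filters (read edge, INDEL, splice site, homopolymer), a genomic
    homozygosity filter and a maximum-allele filter prune common false
    positives. Includes a synthetic benchmark generator for RNA-DNA and
    RNA-RNA study designs with Beta-distributed variant frequencies, the
    associated precision/recall/accuracy/F-score evaluation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    parallel,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
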