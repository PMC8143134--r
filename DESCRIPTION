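Package: lincscout
Title: Novel Intergenic lncRNA Discovery and Tissue-Specific Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers and classifies novel intergenic long non-coding RNA
    (lincRNA) loci from per-sample assembled transcript models, merges them
    into per-tissue and genome-wide consensus locus sets, builds a unified
    count matrix over known genes and novel multi-exon lincRNAs, identifies
    tissue-specific genes with a two-tier one-vs-rest negative-binomial
    testing scheme, and tests enrichment of GWAS SNPs in tissue-specific
    gene sets. Includes a synthetic-data generator (toy genomes, noisy
    per-sample assemblies, negative-binomial counts with planted
    tissue-specific genes, SNP sets with planted enrichment) so the whole
    pipeline is testable without access to protected RNA-seq data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
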