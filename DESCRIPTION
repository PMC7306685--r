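Package: asepartition
Title: Allele-Specific Expression Partitioning in Introgression Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for allele-specific RNA-seq in
    parent/introgression-hybrid crossing designs. Provides count-level
    normalization (CPM, FPKM, trimmed mean of M-values), negative-binomial
    differential expression with fold-change threshold testing, binary
    allele-presence genotyping with heterozygous introgression-block
    detection, eight-category expression-inheritance classification,
    cis/trans regulatory-divergence partitioning from hybrid allele-specific
    expression, misexpression association tests, a diploid pseudoreference
    builder (reference FASTA plus biallelic-SNP VCF), and a synthetic-data
    generator with known per-gene cis, trans, dominance and misexpression
    effects that emulates a four-line, two-tissue, three-replicate design,
    including a forward simulator of the recurrent-selection backcross
    crossing scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    MASS,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
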