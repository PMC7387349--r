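Package: gbspopgen
Title: Population Genomics of Genotyping-by-Sequencing SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic analysis of sparse diploid SNP
    panels such as those produced by genotyping-by-sequencing (GBS) of
    inbreeding crop collections. Reads and filters biallelic SNP genotypes
    from VCF, annotates sites against gene models (coding, intronic,
    intergenic; synonymous versus non-synonymous), and computes windowed
    nucleotide diversity (pi, Watterson's theta, Tajima's D), Weir-Cockerham
    F_ST, AMOVA, and kinship. Infers population structure by LD pruning,
    PCA, maximum-likelihood EM admixture with Evanno delta-K model
    selection, and distance trees. Estimates linkage disequilibrium decay,
    D-prime confidence intervals and Gabriel-style haplotype blocks, and
    integrates PC loadings, windowed F_ST and haplotype blocks into
    candidate selective-sweep regions verified by regional PCA. Includes a
    calibrated Balding-Nichols genotype-panel simulator with planted sweep
    regions for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    ape,
    cluster,
    yaml,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
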