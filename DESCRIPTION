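Package: imprintscan
Title: Detection of Imprinted Genes from Parent-of-Origin Allele-Specific
    Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects genomic imprinting from pedigree-phased RNA-seq data.
    Reads overlapping informative heterozygous SNPs are assigned to the
    maternal or paternal haplotype, aggregated to per-gene per-individual
    parental transcript counts, and screened for parent-of-origin expression
    asymmetry with a two-level exact binomial sign test (a per-individual
    binomial Z-score followed by an exact Binomial(n, 1/2) test on the number
    of individuals favouring each parent) with Benjamini-Hochberg false
    discovery rate control. Significant genes are classified into imprinting
    categories, validated by direction concordance against a second dataset,
    and corroborated by partial-methylation signatures at imprinting control
    regions. A synthetic-data module generates phased genotypes, allele-
    specific read records, parental count tables and CpG methylation values
    with known ground truth so the whole pipeline can be exercised and
    calibrated without access to controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
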