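Package: pedmeth
Title: Genome-Methylome Interactions in Nuclear Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Family-based dissection of genetic effects on CpG methylation
    from targeted bisulfite sequencing of nuclear pedigrees. Implements
    mid-parent-offspring regression to estimate per-CpG heritability and
    call heritable sites, cis methylation-QTL mapping with family-aware
    permutation p-values, allele-specific methylation calling from
    allele-tagged read fragments by Fisher's exact test, and variance-QTL
    (vSNP) detection with variably-methylated-region (VMR) assembly and
    clustering. A synthetic pedigree-methylome generator with known ground
    truth makes every stage testable by parameter recovery without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
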