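Package: lethalScan
Title: Detection and Population Genetics of Recessive Embryonic Lethal
    Haplotypes in Livestock
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to discover recessive embryonic lethal alleles in intensively
    bred livestock populations from phased SNP-array genotypes. Implements a
    sliding-window scan for haplotypes exhibiting missing or deficit
    homozygosity (exact binomial test against Hardy-Weinberg and trio-based
    expectations), recombinant-based fine mapping, linkage-disequilibrium
    filtering of annotated candidate causal variants, Wright-Fisher
    forward simulation of lethal-allele frequency under viability selection
    and de novo mutation, and fertility-impact statistics for
    carrier-by-carrier matings (litter-size reduction, population-level
    piglet loss, heterosis attribution). A pedigree-aware synthetic genotype
    and litter simulator generates data with the statistical structure the
    scan assumes, so the whole pipeline is testable without proprietary
    breeding data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
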