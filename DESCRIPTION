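Package: cch
Title: Combinatorial Conflicting Homozygosity Analysis for Mapping
    Shared Haplotypes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects identical-by-descent (IBD) sharing of a haplotype
    among subsets of individuals directly from dense biallelic SNP
    genotypes, without haplotype reconstruction.  A pair of opposite
    homozygotes (IBS0, "conflicting homozygosity") at a marker excludes
    shared inheritance of a haplotype spanning it; long runs of
    consecutive markers free of conflicting homozygosity indicate IBD.
    The package scans all subsets of a group of individuals to localise
    dominant-trait loci in the presence of phenocopies, attaches
    exponential-null tail probabilities with Bonferroni correction to
    detected runs, reads PLINK ped/map and VCF genotypes, and provides
    gene-dropping pedigree simulation with founder-labelled haplotypes
    for calibration and for sensitivity/specificity evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
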