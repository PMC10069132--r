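Package: popscanr
Title: Population Diversity and Selection-Signature Scans for SNP-Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genetic analysis of diploid SNP-array
    genotypes in two-population designs: quality control and LD pruning,
    observed and expected heterozygosity, Weir-Cockerham FST with permutation
    significance and Reynolds distances, identity-by-state multidimensional
    scaling, linkage-disequilibrium based effective population size,
    runs-of-homozygosity calling with FROH and ROH islands, and
    cross-population haplotype scans (Rsb and XP-EHH) with window-consensus
    candidate-region calling. Includes a two-population haplotype simulator
    with planted selective sweeps and planted autozygosity so the whole
    pipeline is testable against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
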