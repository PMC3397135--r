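Package: amplipop
Title: Amplicon Haplotype Calling and Population Genetic Analysis for
    Diploid Outcrossers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis chain for candidate-gene amplicon resequencing in
    diploid outcrossing plants: tag demultiplexing, reference-anchored
    pileup, frequency-filtered SNP and indel calling, PCR-chimera-aware
    diploid haplotype reconstruction across overlapping amplicons,
    sequence diversity statistics (nucleotide diversity, Watterson's
    theta, Tajima's D, haplotype diversity), genotypic linkage
    disequilibrium permutation tests for multi-allelic SSR markers and
    r-squared decay for unphased SNPs, Ritland moment-estimator kinship,
    unified Q+K mixed linear model association scans, and Storey
    positive-FDR q-values. Includes a coalescent-based synthetic data
    generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
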