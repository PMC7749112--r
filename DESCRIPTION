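Package: clonescan
Title: Signatures of Recombination and Genetic Exchange in Clonal Diploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of facultatively clonal diploid
    populations and a toolkit for detecting signatures of recombination and
    inter-individual genetic exchange in small samples of diploid genomes.
    Provides per-site inbreeding coefficients (F_IS) with a
    subsampling-based clonality test, triallelic-site heterozygote
    enrichment analysis, linkage-disequilibrium decay from phased and
    unphased data, per-segment recombination tests (r2-distance
    correlation, sum of distances, pairwise homoplasy index), a
    gene-conversion-proof modified four-gamete test, quality control for
    read-based phasing output, and haplotype-incongruence detection with
    neighbor-joining trees, bootstrap supports, midpoint rooting and
    monophyly scanning.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    phangorn,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
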