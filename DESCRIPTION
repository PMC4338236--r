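Package: haplosweep
Title: Haplotype-Homozygosity Scans for Hard and Soft Selective Sweeps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and classification of recent selective sweeps from
    phased haplotype data using the haplotype homozygosity statistics H1,
    H12, H123 and H2/H1 computed in sliding windows of a fixed number of
    SNPs. Includes simulation-based calibration of a 1-per-genome false
    discovery rate threshold, peak calling with recombination-rate masking,
    a coalescent/forward-in-time sweep simulator for hard and soft sweeps
    from de novo mutation and standing variation, rejection-ABC inference of
    the adaptive mutation rate theta_A with Bayes factors for hard versus
    soft sweep classification, pairwise linkage-disequilibrium decay
    profiles, and an unpolarized iHS scan with enrichment windows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
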