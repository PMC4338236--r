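# Fixtures built in code: a small phased VCF, toy matrices and
# desk-scale simulation models shared across test files.

write_test_vcf <- function(path, records, samples = c("S1", "S2", "S3")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Cheap neutral model: small locus and population so a sample takes
# milliseconds.
tiny_neutral_model <- function(n = 20, locus = 2e4, ne = 5e4) {
  sweep_model(mode = "neutral", locus_length = locus,
              demography = demography_constant(ne), n = n, min_snps = 0)
}

# Desk-scale sweep model used for directional/stochastic tests: the
# reference study conditions (Ne = 1e6, mu = 1e-9, rho = 5e-7 cM/bp,
# L = 1e5 bp, n = 145) with the forward phase run at N' = 500.
study_sweep_model <- function(mode = "de_novo", ...) {
  sweep_model(mode = mode, ...)
}

# Brute-force haplotype spectrum: group rows (no missing data) by string
# identity.
oracle_spectrum <- function(mat) {
  key <- apply(mat, 1, paste, collapse = "")
  sort(as.integer(table(key)), decreasing = TRUE)
}

# Independent H12 etc. from first principles for a frequency vector.
oracle_stats <- function(p) {
  p <- sort(p, decreasing = TRUE)
  pad <- function(i) if (length(p) >= i) p[i] else 0
  list(h1 = sum(p^2),
       h12 = (pad(1) + pad(2))^2 + sum(p[-(1:2)][p[-(1:2)] > 0]^2),
       h123 = (pad(1) + pad(2) + pad(3))^2 +
         if (length(p) > 3) sum(p[-(1:3)]^2) else 0)
}
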