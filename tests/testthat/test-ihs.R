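test_that("EHH is 1 at the core, non-increasing, and matches pair counting", {
  # all carriers identical: EHH stays 1
  mat <- rbind(matrix(c(1L, 0L, 1L, 0L), 4, 4, byrow = TRUE),
               matrix(c(0L, 1L, 1L, 0L), 2, 4, byrow = TRUE))
  hap <- hap_matrix(mat, c(10L, 20L, 30L, 40L))
  e <- ehh(hap, 1, 1, "right")
  expect_equal(e$ehh, rep(1, 4))

  # two carriers differing at the adjacent SNP: EHH drops to 0 there
  mat2 <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 0L, 0L), c(0L, 0L, 0L))
  hap2 <- hap_matrix(mat2, c(10L, 20L, 30L))
  e2 <- ehh(hap2, 1, 1, "right")
  expect_equal(e2$ehh, c(1, 0, 0))

  # six-haplotype toy matrix versus brute-force pair enumeration
  set.seed(71)
  mat3 <- matrix(sample(0:1, 6 * 8, replace = TRUE, prob = c(0.6, 0.4)),
                 nrow = 6)
  mat3[, 4] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  hap3 <- hap_matrix(mat3, seq_len(8) * 100L)
  e3 <- ehh(hap3, 4, 1, "right")
  carriers <- which(mat3[, 4] == 1)
  for (k in seq_len(nrow(e3))) {
    jj <- 4:(3 + k)
    same <- 0
    for (a in 1:2) for (b in (a + 1):3) {
      if (all(mat3[carriers[a], jj] == mat3[carriers[b], jj]))
        same <- same + 1
    }
    expect_equal(e3$ehh[k], same / 3)
  }
  # monotone in both directions
  el <- ehh(hap3, 4, 0, "left")
  expect_true(all(diff(el$ehh) <= 1e-12))
  expect_error(ehh(hap2, 2, 1), "fewer than 2 carriers")
})

test_that("haplotypes with missing data are discarded as the region grows", {
  mat <- rbind(c(1L, 0L, 0L), c(1L, NA, 0L), c(1L, 0L, 0L), c(0L, 0L, 0L))
  hap <- hap_matrix(mat, c(10L, 20L, 30L))
  e <- ehh(hap, 1, 1, "right")
  # at SNP 2 the NA carrier is dropped: 1 identical pair of C(3,2)=3
  expect_equal(e$ehh, c(1, 1 / 3, 1 / 3))
  expect_true(all(diff(e$ehh) <= 1e-12))
})

test_that("mirror-image allele classes give an unstandardized score of 0", {
  # build perfect symmetry: the two classes have identical internal structure
  block <- rbind(c(0L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L), c(0L, 1L, 1L))
  mat <- cbind(rbind(block, block),
               rep(c(0L, 1L), each = 4),
               rbind(block, block))
  hap <- hap_matrix(mat, c(10L, 20L, 30L, 40L, 50L, 60L, 70L))
  res <- ihs_scan(hap, maf_min = 0.05)
  expect_equal(res$ihs_raw[res$snp == 4], 0)
})

test_that("standardization gives mean 0 and sd 1 per MAF bin, idempotently", {
  set.seed(72)
  s <- simulate_sweep(tiny_neutral_model(n = 40, locus = 5e4, ne = 2e5))
  res <- ihs_scan(s$hap)
  ok <- !is.na(res$ihs_std)
  expect_gt(sum(ok), 20)
  bins <- pmin(floor(res$maf[ok] / 0.05), 9)
  for (b in unique(bins)) {
    v <- res$ihs_std[ok][bins == b]
    if (length(v) >= 2) {
      expect_lt(abs(mean(v)), 1e-9)
      expect_lt(abs(sd(v) - 1), 1e-9)
    }
  }
  # idempotence
  again <- haplosweep:::standardize_ihs(res$ihs_std, res$maf)
  expect_equal(again[ok], res$ihs_std[ok], tolerance = 1e-9)
  # every SNP is scored or carries a drop reason
  expect_true(all(res$dropped == is.na(res$ihs_raw)))
  expect_true(all(!res$dropped | res$reason %in%
                    c("maf", "carriers", "edge", "zero_ihh")))
})

test_that("enrichment windows count extreme scores and flag the top decile", {
  res <- data.frame(snp = 1:10, pos = seq(5e4, by = 1e5, length.out = 10),
                    maf = 0.3, ihs_raw = 0,
                    ihs_std = c(3, -3, 0, 2.5, 0, 0, -2.2, 0, 0, 3.1),
                    dropped = FALSE, reason = NA)
  ew <- enrichment_windows(res, window_bp = 1e5, top_fraction = 0.1,
                           chrom_length = 1e6)
  expect_equal(nrow(ew), 10L)
  expect_equal(sum(ew$count), 5L)
  expect_equal(sum(ew$top), 1L)
  # counts 0..9 over ten windows: only the count-9 window is flagged
  res2 <- data.frame(pos = unlist(lapply(0:9, function(k)
    if (k == 0) numeric(0) else (k * 1e5) + seq_len(k) * 100)),
    ihs_std = 5)
  ew2 <- enrichment_windows(res2, window_bp = 1e5, top_fraction = 0.1,
                            chrom_length = 1e6)
  expect_equal(ew2$count, 0:9)
  expect_equal(which(ew2$top), 10L)
  # ties: the leftmost windows win
  res3 <- data.frame(pos = (0:9) * 1e5 + 50, ihs_std = 5)
  ew3 <- enrichment_windows(res3, window_bp = 1e5, top_fraction = 0.25,
                            chrom_length = 1e6)
  expect_equal(which(ew3$top), c(1L, 2L, 3L))
  # independent counting oracle
  set.seed(73)
  pos <- sort(sample(1:1e6, 300))
  std <- rnorm(300, 0, 1.5)
  res4 <- data.frame(pos = pos, ihs_std = std)
  ew4 <- enrichment_windows(res4, window_bp = 1e5, chrom_length = 1e6)
  oracle <- as.vector(table(cut(pos[abs(std) > 2],
                                breaks = seq(1, 1e6 + 1e5, by = 1e5),
                                right = FALSE)))
  expect_equal(ew4$count, oracle)
})

test_that("sweep regions are enriched for extreme |iHS| relative to neutrality", {
  # raw scores are standardized against neutral MAF-bin parameters, as in
  # a genome scan where the bulk of windows is neutral
  # recombination high enough that the sweep footprint (~s/(log(Ne s) r)
  # = 22 kb) sits inside the 50-kb locus, so EHH decays before the edges
  set.seed(74)
  sweep_m <- sweep_model(mode = "de_novo", theta_a = 0.01, s = 0.01,
                         pf = 0.5, te = 0, locus_length = 5e4,
                         rho_cmbp = 5e-6,
                         demography = demography_constant(1e6),
                         n = 30, np = 200, min_snps = 0)
  neut_m <- sweep_m
  neut_m$mode <- "neutral"
  raw_maf <- function(s) {
    res <- ihs_scan(s$hap)
    ok <- !is.na(res$ihs_raw)
    data.frame(raw = res$ihs_raw[ok], maf = res$maf[ok])
  }
  neut <- lapply(1:8, function(i) raw_maf(simulate_sweep(neut_m)))
  hard <- lapply(1:8, function(i) raw_maf(simulate_sweep(sweep_m)))
  pool <- do.call(rbind, neut)
  pool$bin <- pmin(floor(pool$maf / 0.05), 9)
  mbin <- tapply(pool$raw, pool$bin, mean)
  sbin <- tapply(pool$raw, pool$bin, sd)
  frac_extreme <- function(df) {
    b <- as.character(pmin(floor(df$maf / 0.05), 9))
    z <- (df$raw - mbin[b]) / sbin[b]
    mean(abs(z) > 2, na.rm = TRUE)
  }
  expect_gt(mean(vapply(hard, frac_extreme, numeric(1)), na.rm = TRUE),
            mean(vapply(neut, frac_extreme, numeric(1)), na.rm = TRUE))
})
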