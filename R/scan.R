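# Sliding-window genome scan: fixed-SNP windows, recombination-rate
# masking, a simulation-calibrated 1-per-genome FDR critical value, and
# peak calling.

#' Enumerate sliding fixed-SNP windows
#'
#' Windows contain exactly `size` SNPs and advance by `step` SNPs; trailing
#' partial windows are not emitted. Indices are 1-based and inclusive.
#'
#' @param n_snps number of SNPs available.
#' @param size window size in SNPs (default 400).
#' @param step step between window starts in SNPs (default 50).
#' @return Data frame with columns `start`, `end` (1-based inclusive SNP
#'   indices); zero rows when `n_snps < size`.
#' @export
sliding_windows <- function(n_snps, size = 400, step = 50) {
  stopifnot(size >= 1, step >= 1)
  if (n_snps < size) return(data.frame(start = integer(0), end = integer(0)))
  starts <- as.integer(seq.int(1L, n_snps - size + 1L, by = step))
  data.frame(start = starts, end = starts + as.integer(size) - 1L)
}

#' Scan a chromosome with sliding haplotype-homozygosity windows
#'
#' Every window is clustered ([cluster_window()]) and scored
#' ([homozygosity()]). When a recombination map is supplied, a window is
#' masked if the local rate at its centre SNP is below `rho_min` or unknown
#' (outside the map); masked windows carry statistics but are excluded from
#' peak calling. With `map = NULL` the rate filter is disabled.
#'
#' @param hap a [hap_matrix()] with at least `size` SNPs.
#' @param map optional [recomb_map()].
#' @param rho_min minimum local recombination rate in cM/bp (default 5e-7).
#' @param size,step window size and step in SNPs.
#' @return Data frame of window results: `window_index`, `snp_start`,
#'   `snp_end` (1-based inclusive), `center_pos`, `edge_start`, `edge_end`
#'   (bp), `h1`, `h12`, `h123`, `h2`, `h2_h1`, `k`, `rho`, `masked`.
#' @export
scan_chromosome <- function(hap, map = NULL, rho_min = 5e-7,
                            size = 400, step = 50) {
  stopifnot(inherits(hap, "hap_matrix"))
  if (n_snps(hap) < size)
    stop("chromosome has ", n_snps(hap), " SNPs; at least ", size,
         " are required for a ", size, "-SNP window scan")
  win <- sliding_windows(n_snps(hap), size = size, step = step)
  centre_off <- size %/% 2L          # the (size/2 + 1)-th SNP of the window
  res <- lapply(seq_len(nrow(win)), function(i) {
    idx <- win$start[i]:win$end[i]
    st <- window_stats(hap$alleles[, idx, drop = FALSE])
    centre <- hap$positions[win$start[i] + centre_off]
    data.frame(window_index = i, snp_start = win$start[i],
               snp_end = win$end[i], center_pos = centre,
               edge_start = hap$positions[win$start[i]],
               edge_end = hap$positions[win$end[i]],
               h1 = st$h1, h12 = st$h12, h123 = st$h123, h2 = st$h2,
               h2_h1 = st$h2_h1, k = st$k)
  })
  out <- do.call(rbind, res)
  if (is.null(map)) {
    out$rho <- NA_real_
    out$masked <- FALSE
  } else {
    out$rho <- rate_at(map, hap$chrom, out$center_pos)
    out$masked <- is.na(out$rho) | out$rho < rho_min
  }
  out$chrom <- hap$chrom
  out
}

#' Calibrate the 1-per-genome FDR critical value
#'
#' The critical value H12_o is the 10th-highest H12 value among neutral
#' simulations, run ten times as numerous as the genome's analysis windows
#' so that about one neutral window per genome is expected to exceed it.
#'
#' @param neutral_h12 numeric vector of H12 values from neutral
#'   simulations (length >= 10; intended length `10 * n_genome_windows`).
#' @param n_genome_windows number of analysis windows in the scanned
#'   genome.
#' @return List of class `fdr_calibration`: `h12_o`, `n_sims`,
#'   `n_genome_windows`.
#' @export
calibrate_fdr <- function(neutral_h12, n_genome_windows = NULL) {
  neutral_h12 <- as.numeric(neutral_h12)
  if (length(neutral_h12) < 10)
    stop("at least 10 neutral H12 values are required")
  h12_o <- sort(neutral_h12, decreasing = TRUE)[10]
  structure(list(h12_o = h12_o, n_sims = length(neutral_h12),
                 n_genome_windows = n_genome_windows),
            class = "fdr_calibration")
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat(sprintf("<fdr_calibration> H12_o = %.4f from %d neutral simulations\n",
              x$h12_o, x$n_sims))
  invisible(x)
}

#' Call sweep peaks from a window scan
#'
#' A peak is a maximal run of consecutive unmasked windows with
#' `h12 > h12_o`; a masked window terminates a run even if its own H12
#' exceeds the threshold. Each peak is represented by its highest-H12
#' member window, and peaks are returned in decreasing order of that
#' representative value. Edge coordinates run from the first SNP of the
#' first member window to the last SNP of the last member window.
#'
#' @param results window data frame from [scan_chromosome()], ordered by
#'   window index.
#' @param h12_o critical value (e.g. from [calibrate_fdr()]).
#' @return Data frame of peaks: `chrom`, `first_window`, `last_window`,
#'   `n_windows`, `edge_start`, `edge_end`, `rep_window`, `rep_center`,
#'   `rep_h12`, `rep_h2_h1`. Zero rows when nothing exceeds the threshold.
#' @export
call_peaks <- function(results, h12_o) {
  if (inherits(h12_o, "fdr_calibration")) h12_o <- h12_o$h12_o
  ok <- !results$masked & results$h12 > h12_o
  empty <- data.frame(chrom = character(0), first_window = integer(0),
                      last_window = integer(0), n_windows = integer(0),
                      edge_start = integer(0), edge_end = integer(0),
                      rep_window = integer(0), rep_center = integer(0),
                      rep_h12 = numeric(0), rep_h2_h1 = numeric(0))
  if (!any(ok)) return(empty)
  idx <- which(ok)
  run <- cumsum(c(1L, diff(idx) != 1L))
  peaks <- lapply(split(idx, run), function(members) {
    rep_i <- members[which.max(results$h12[members])]
    data.frame(chrom = results$chrom[rep_i],
               first_window = results$window_index[members[1]],
               last_window = results$window_index[members[length(members)]],
               n_windows = length(members),
               edge_start = results$edge_start[members[1]],
               edge_end = results$edge_end[members[length(members)]],
               rep_window = results$window_index[rep_i],
               rep_center = results$center_pos[rep_i],
               rep_h12 = results$h12[rep_i],
               rep_h2_h1 = results$h2_h1[rep_i])
  })
  out <- do.call(rbind, peaks)
  out <- out[order(-out$rep_h12), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected chance overlap of two candidate-region sets
#'
#' For two sets of candidate regions covering `peak_bp` and `enrich_bp` of
#' a `genome_bp` genome, the fraction of the genome expected to fall in
#' both by chance is the product of the two coverage fractions; scaling by
#' the number of regions in each set gives the expected numbers of
#' overlapping regions.
#'
#' @param peak_bp,enrich_bp,genome_bp total bp covered by each candidate
#'   set and by the genome (> 0).
#' @param n_peaks,n_enrich number of regions in each set.
#' @return List: `overlap_fraction`, `expected_peaks`, `expected_windows`.
#' @export
expected_overlap <- function(peak_bp, enrich_bp, genome_bp,
                             n_peaks, n_enrich) {
  if (any(c(peak_bp, enrich_bp, genome_bp) <= 0))
    stop("all bp totals must be > 0")
  frac <- (peak_bp / genome_bp) * (enrich_bp / genome_bp)
  list(overlap_fraction = frac,
       expected_peaks = n_peaks * frac * genome_bp / peak_bp,
       expected_windows = n_enrich * frac * genome_bp / enrich_bp)
}

#' Neutral H12 null distribution
#'
#' Simulates neutral samples under the given model and returns the H12
#' value of the central `size`-SNP window of each replicate; replicates
#' with fewer than `size` segregating sites are discarded and redrawn.
#' Feed the result to [calibrate_fdr()].
#'
#' @param n_sims number of neutral replicates.
#' @param model a neutral [sweep_model()] (defaults to the constant
#'   Ne = 1e6 study conditions).
#' @param size window size in SNPs.
#' @return Numeric vector of `n_sims` H12 values.
#' @export
neutral_h12_distribution <- function(n_sims,
                                     model = sweep_model(mode = "neutral"),
                                     size = 400) {
  vapply(seq_len(n_sims), function(i) {
    s <- simulate_sweep(model, min_snps = size)
    sweep_window_stats(s, size = size)$h12
  }, numeric(1))
}
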