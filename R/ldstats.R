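# Pairwise linkage disequilibrium (R^2) and its decay profile with
# distance, using anchored 10-kb sliding windows and the two-regime
# binning scheme (20-bp bins to 300 bp, 150-bp bins beyond).

#' Pairwise R-squared between two SNP columns
#'
#' Computed over the haplotypes non-missing at both sites:
#' `R^2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))`.
#' Returns `NA` (pair excluded) when fewer than 4 complete haplotypes
#' remain or either site is monomorphic in the complete subset.
#'
#' @param col_a,col_b integer vectors of 0/1/NA, equal length.
#' @return R-squared in `[0, 1]`, or `NA` when the pair is excluded.
#' @export
r_squared <- function(col_a, col_b) {
  if (length(col_a) != length(col_b))
    stop("columns must have equal length")
  ok <- !is.na(col_a) & !is.na(col_b)
  if (sum(ok) < 4) return(NA_real_)
  a <- col_a[ok]
  b <- col_b[ok]
  pa <- mean(a)
  pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  pab <- mean(a == 1 & b == 1)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Linkage-disequilibrium decay profile
#'
#' In sliding windows of `window_bp` advanced by `step_bp`, R-squared is
#' computed between the first SNP in the window whose allele frequency
#' (among non-missing haplotypes) lies in `[maf[1], maf[2]]` and every
#' other frequency-passing SNP in the window. Pairs are pooled over
#' windows, deduplicated, and averaged in distance bins: 20-bp bins up to
#' 300 bp, 150-bp bins beyond, up to `window_bp`.
#'
#' @param hap a [hap_matrix()].
#' @param window_bp window length in bp (default 10000).
#' @param step_bp step between window starts in bp (default 50).
#' @param maf inclusive allele-frequency bounds (default `c(0.05, 0.95)`).
#' @return Data frame of class `ld_profile`: `bin_start`, `bin_end`
#'   (half-open bp distance bins), `mean_r2`, `n_pairs`; zero rows when no
#'   pair qualifies.
#' @export
ld_decay <- function(hap, window_bp = 1e4, step_bp = 50,
                     maf = c(0.05, 0.95)) {
  stopifnot(inherits(hap, "hap_matrix"))
  pos <- hap$positions
  al <- hap$alleles
  freq <- colMeans(al, na.rm = TRUE)
  pass <- !is.na(freq) & freq >= maf[1] & freq <= maf[2]
  empty <- data.frame(bin_start = integer(0), bin_end = integer(0),
                      mean_r2 = numeric(0), n_pairs = integer(0))
  class(empty) <- c("ld_profile", "data.frame")
  if (sum(pass) < 2) return(empty)

  starts <- seq.int(min(pos), max(pos), by = step_bp)
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  for (w0 in starts) {
    inwin <- which(pass & pos >= w0 & pos < w0 + window_bp)
    if (length(inwin) < 2) next
    anchor <- inwin[1]
    others <- inwin[-1]
    pairs_i <- c(pairs_i, rep(anchor, length(others)))
    pairs_j <- c(pairs_j, others)
  }
  if (!length(pairs_i)) return(empty)
  keep <- !duplicated(cbind(pairs_i, pairs_j))
  pairs_i <- pairs_i[keep]
  pairs_j <- pairs_j[keep]
  r2 <- vapply(seq_along(pairs_i), function(k)
    r_squared(al[, pairs_i[k]], al[, pairs_j[k]]), numeric(1))
  dist <- pos[pairs_j] - pos[pairs_i]
  ok <- !is.na(r2)
  r2 <- r2[ok]
  dist <- dist[ok]
  if (!length(r2)) return(empty)

  breaks <- c(seq(0, 300, by = 20),
              seq(450, max(300 + 150, ceiling(window_bp / 150) * 150),
                  by = 150))
  bin <- findInterval(dist, breaks, left.open = FALSE)
  agg <- tapply(r2, bin, mean)
  cnt <- tapply(r2, bin, length)
  b <- as.integer(names(agg))
  out <- data.frame(bin_start = breaks[b],
                    bin_end = ifelse(b < length(breaks), breaks[b + 1],
                                     breaks[b] + 150),
                    mean_r2 = as.numeric(agg),
                    n_pairs = as.integer(cnt))
  out <- out[order(out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ld_profile", "data.frame")
  out
}
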