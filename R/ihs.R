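# Unpolarized iHS: extended haplotype homozygosity (EHH) decay around a
# core SNP, the integrated haplotype score, MAF-binned standardisation,
# and 100-kb enrichment windows of |iHS| > 2.

#' Extended haplotype homozygosity from a core SNP
#'
#' EHH at a SNP x is the fraction of carrier pairs of the core allele whose
#' haplotypes are identical over the interval from the core to x (carrier
#' pairs at the core form the denominator). Haplotypes with missing data in
#' the traversed region are discarded as the region extends, so the curve
#' is non-increasing with EHH(core) = 1.
#'
#' @param hap a [hap_matrix()].
#' @param core 1-based SNP index of the core.
#' @param allele 0 or 1: the core allele whose carriers are followed.
#' @param direction `"right"` (increasing position) or `"left"`.
#' @return Data frame `pos`, `ehh`, starting at the core SNP.
#' @export
ehh <- function(hap, core, allele, direction = c("right", "left")) {
  direction <- match.arg(direction)
  al <- hap$alleles
  pos <- hap$positions
  carriers <- which(!is.na(al[, core]) & al[, core] == allele)
  if (length(carriers) < 2)
    stop("fewer than 2 carriers of allele ", allele, " at core SNP ", core)
  n0 <- length(carriers)
  denom <- n0 * (n0 - 1) / 2
  idx <- if (direction == "right") seq(core, ncol(al)) else seq(core, 1)
  active <- carriers
  grp <- rep(1L, length(active))
  out_pos <- numeric(length(idx))
  out_ehh <- numeric(length(idx))
  for (k in seq_along(idx)) {
    j <- idx[k]
    if (k > 1) { # core column already conditions the carrier set
      a <- al[active, j]
      keep <- !is.na(a)
      active <- active[keep]
      grp <- grp[keep]
      a <- a[keep]
      if (length(active)) {
        grp <- match(paste(grp, a), unique(paste(grp, a)))
      }
    }
    sizes <- tabulate(grp)
    out_pos[k] <- pos[j]
    out_ehh[k] <- sum(sizes * (sizes - 1) / 2) / denom
  }
  data.frame(pos = out_pos, ehh = out_ehh)
}

# Integrated EHH: trapezoidal integral over bp until EHH decays below
# `cutoff` (linearly interpolated crossing). Returns NA when the curve
# never reaches the cutoff before the chromosome end ("edge").
ihh_one <- function(curve, cutoff) {
  p <- curve$pos
  e <- curve$ehh
  if (length(p) < 2) return(NA_real_)
  total <- 0
  for (k in 2:length(p)) {
    if (e[k] < cutoff) {
      if (e[k - 1] <= cutoff) return(total)
      frac <- (e[k - 1] - cutoff) / (e[k - 1] - e[k])
      dx <- abs(p[k] - p[k - 1]) * frac
      total <- total + dx * (e[k - 1] + cutoff) / 2
      return(total)
    }
    total <- total + abs(p[k] - p[k - 1]) * (e[k] + e[k - 1]) / 2
  }
  NA_real_ # still above cutoff at the chromosome end
}

#' Unpolarized iHS scan
#'
#' For every SNP with minor allele frequency at least `maf_min` (computed
#' on non-missing haplotypes), the EHH curves of the major and minor
#' alleles are integrated over bp in both directions, truncating where EHH
#' falls below `ehh_cutoff`; the unstandardized score is
#' `ln(iHH_major / iHH_minor)`. Scores are then standardized to mean 0 and
#' unit variance within MAF bins of width 0.05. SNPs are dropped, with a
#' reason, when the MAF filter fails, an allele has fewer than two
#' carriers, or an EHH curve reaches a chromosome end before decaying below
#' the cutoff ("edge").
#'
#' @param hap a [hap_matrix()].
#' @param maf_min minor-allele-frequency threshold (default 0.05).
#' @param ehh_cutoff EHH truncation level (default 0.05).
#' @return Data frame of class `ihs_result`: `snp`, `pos`, `maf`,
#'   `ihs_raw`, `ihs_std`, `dropped`, `reason`.
#' @export
ihs_scan <- function(hap, maf_min = 0.05, ehh_cutoff = 0.05) {
  al <- hap$alleles
  S <- ncol(al)
  freq <- colMeans(al, na.rm = TRUE)
  maf <- pmin(freq, 1 - freq)
  raw <- rep(NA_real_, S)
  reason <- rep(NA_character_, S)
  for (j in seq_len(S)) {
    if (is.na(maf[j]) || maf[j] < maf_min) {
      reason[j] <- "maf"
      next
    }
    major <- if (freq[j] >= 0.5) 1L else 0L
    minor <- 1L - major
    n_min <- sum(al[, j] == minor, na.rm = TRUE)
    n_maj <- sum(al[, j] == major, na.rm = TRUE)
    if (n_min < 2 || n_maj < 2) {
      reason[j] <- "carriers"
      next
    }
    ihh <- numeric(2)
    bad <- FALSE
    for (a in c(major, minor)) {
      left <- ihh_one(ehh(hap, j, a, "left"), ehh_cutoff)
      right <- ihh_one(ehh(hap, j, a, "right"), ehh_cutoff)
      if (is.na(left) || is.na(right)) { bad <- TRUE; break }
      v <- left + right
      if (a == major) ihh[1] <- v else ihh[2] <- v
    }
    if (bad) {
      reason[j] <- "edge"
      next
    }
    if (ihh[1] <= 0 || ihh[2] <= 0) {
      reason[j] <- "zero_ihh"
      next
    }
    raw[j] <- log(ihh[1] / ihh[2])
  }
  std <- standardize_ihs(raw, maf)
  out <- data.frame(snp = seq_len(S), pos = hap$positions, maf = maf,
                    ihs_raw = raw, ihs_std = std,
                    dropped = is.na(raw), reason = reason)
  class(out) <- c("ihs_result", "data.frame")
  out
}

# Standardize within MAF bins of width 0.05; single-SNP bins keep their
# centred value (0).
standardize_ihs <- function(raw, maf) {
  std <- rep(NA_real_, length(raw))
  ok <- !is.na(raw)
  if (!any(ok)) return(std)
  bin <- pmin(floor(maf / 0.05), 9)
  for (b in unique(bin[ok])) {
    i <- ok & bin == b
    m <- mean(raw[i])
    s <- stats::sd(raw[i])
    std[i] <- if (isTRUE(s > 0)) (raw[i] - m) / s else 0
  }
  std
}

#' Enrichment windows of extreme iHS scores
#'
#' Tiles the chromosome with non-overlapping windows starting at bp 1,
#' counts SNPs with |standardized iHS| above `threshold` in each, and
#' flags the top `top_fraction` of windows by count (ties broken in favour
#' of the leftmost window).
#'
#' @param result an `ihs_result` from [ihs_scan()].
#' @param window_bp window length (default 1e5).
#' @param top_fraction fraction of windows to flag (default 0.10).
#' @param threshold |iHS| threshold (default 2).
#' @param chrom_length optional chromosome length; defaults to the last
#'   SNP position.
#' @return Data frame: `start`, `end` (half-open bp), `count`, `top`.
#' @export
enrichment_windows <- function(result, window_bp = 1e5, top_fraction = 0.10,
                               threshold = 2, chrom_length = NULL) {
  if (is.null(chrom_length)) chrom_length <- max(result$pos)
  starts <- seq.int(1L, chrom_length, by = window_bp)
  hits <- result$pos[!is.na(result$ihs_std) &
                       abs(result$ihs_std) > threshold]
  count <- vapply(starts, function(s)
    sum(hits >= s & hits < s + window_bp), integer(1))
  n_top <- ceiling(top_fraction * length(starts))
  ord <- order(-count, starts)
  top <- logical(length(starts))
  top[ord[seq_len(n_top)]] <- TRUE
  data.frame(start = starts, end = starts + window_bp, count = count,
             top = top)
}
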