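# Haplotype clustering within a fixed-SNP window and the homozygosity
# statistics H1, H12, H123, H2 and H2/H1.
#
# If p_i is the frequency of the i-th most common haplotype among n
# sampled haplotypes:
#   H1   = sum_i p_i^2
#   H12  = (p_1 + p_2)^2 + sum_{i>2} p_i^2 = H1 + 2 p_1 p_2
#   H123 = (p_1 + p_2 + p_3)^2 + sum_{i>3} p_i^2
#   H2   = sum_{i>1} p_i^2 = H1 - p_1^2
# H12 pools the two most frequent haplotypes and so keeps power for soft
# sweeps, in which several haplotypes sweep together; H2/H1 grows with the
# softness of a sweep and is interpretable where H12 is already high.

#' Cluster haplotypes in a window by exact identity
#'
#' Haplotypes are grouped by exact sequence identity over the window.
#' Complete (missing-free) haplotypes are clustered first. Haplotypes
#' containing missing entries are then processed in input-row order: a
#' haplotype joins an existing cluster if it is consistent with the cluster
#' representative (no site where both are genotyped and differ); when it is
#' consistent with several clusters one is chosen uniformly at random; with
#' none it founds a new cluster and becomes its representative. A
#' representative is the first haplotype assigned to the cluster, so later
#' comparisons against a representative founded by a missing-bearing
#' haplotype treat its missing sites as matching anything.
#'
#' Randomness is drawn from R's global RNG; seed with [set.seed()] for
#' reproducible spectra.
#'
#' @param window integer matrix of 0/1/NA (rows = haplotypes), or a
#'   [hap_matrix()] whose full width is used.
#' @return A `hap_spectrum`: list with `counts` (descending cluster sizes),
#'   `n` (haplotypes) and `freq` (`counts / n`).
#' @export
cluster_window <- function(window) {
  if (inherits(window, "hap_matrix")) window <- window$alleles
  window <- as.matrix(window)
  storage.mode(window) <- "integer"
  if (nrow(window) < 1) stop("window must contain at least one haplotype")

  has_na <- anyNA(window)
  if (!has_na) {
    grp <- .identity_groups(window)
    counts <- sort(tabulate(grp), decreasing = TRUE)
    return(hap_spectrum(counts))
  }

  complete <- !apply(window, 1, anyNA)
  reps <- list()   # cluster representatives
  counts <- integer(0)
  if (any(complete)) {
    sub <- window[complete, , drop = FALSE]
    grp <- .identity_groups(sub)
    for (g in seq_len(max(grp))) {
      rows <- which(grp == g)
      reps[[g]] <- sub[rows[1], ]
      counts[g] <- length(rows)
    }
  }
  for (i in which(!complete)) {
    h <- window[i, ]
    match_g <- which(vapply(reps, function(r) {
      both <- !is.na(h) & !is.na(r)
      !any(h[both] != r[both])
    }, TRUE))
    if (length(match_g) == 0L) {
      reps[[length(reps) + 1L]] <- h
      counts[length(counts) + 1L] <- 1L
    } else {
      g <- if (length(match_g) == 1L) match_g else
        match_g[sample.int(length(match_g), 1L)]
      counts[g] <- counts[g] + 1L
    }
  }
  hap_spectrum(sort(counts, decreasing = TRUE))
}

#' Haplotype frequency spectrum of one window
#'
#' @param counts cluster sizes (positive integers); order is irrelevant.
#' @return A `hap_spectrum` with descending `counts`, `n` and `freq`.
#' @export
hap_spectrum <- function(counts) {
  counts <- as.integer(counts)
  if (!length(counts) || any(counts < 1L)) stop("counts must be >= 1")
  counts <- sort(counts, decreasing = TRUE)
  n <- sum(counts)
  structure(list(counts = counts, n = n, freq = counts / n),
            class = "hap_spectrum")
}

#' @export
print.hap_spectrum <- function(x, ...) {
  cat(sprintf("<hap_spectrum> n = %d, k = %d clusters; top frequencies: %s\n",
              x$n, length(x$counts),
              paste(sprintf("%.3f", utils::head(x$freq, 5)), collapse = " ")))
  invisible(x)
}

#' Haplotype homozygosity statistics of a spectrum
#'
#' Computes H1, H12, H123, H2 and H2/H1 from a haplotype frequency
#' spectrum. Spectra with fewer than two (or three) clusters treat the
#' missing frequencies as zero, so a complete hard sweep (one cluster)
#' yields H1 = H12 = H123 = 1 and H2/H1 = 0.
#'
#' @param spectrum a [hap_spectrum()] or a bare vector of cluster counts.
#' @return List with `h1`, `h12`, `h123`, `h2`, `h2_h1` and `k` (number of
#'   clusters), of class `homozygosity_stats`.
#' @export
homozygosity <- function(spectrum) {
  if (!inherits(spectrum, "hap_spectrum")) spectrum <- hap_spectrum(spectrum)
  p <- spectrum$freq
  p1 <- p[1]
  p2 <- if (length(p) >= 2) p[2] else 0
  p3 <- if (length(p) >= 3) p[3] else 0
  h1 <- sum(p^2)
  h12 <- h1 + 2 * p1 * p2
  h123 <- h12 + 2 * p3 * (p1 + p2)
  h2 <- h1 - p1^2
  structure(list(h1 = h1, h12 = h12, h123 = h123, h2 = h2,
                 h2_h1 = h2 / h1, k = length(p)),
            class = "homozygosity_stats")
}

#' @export
print.homozygosity_stats <- function(x, ...) {
  cat(sprintf(
    "<homozygosity_stats> H1 = %.4f, H12 = %.4f, H123 = %.4f, H2/H1 = %.4f (k = %d)\n",
    x$h1, x$h12, x$h123, x$h2_h1, x$k))
  invisible(x)
}

#' Cluster a window and compute its homozygosity statistics
#'
#' Convenience wrapper: [cluster_window()] followed by [homozygosity()].
#'
#' @inheritParams cluster_window
#' @return A `homozygosity_stats` list.
#' @export
window_stats <- function(window) homozygosity(cluster_window(window))
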