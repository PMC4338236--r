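# Input/output of phased haplotype matrices and recombination maps, and the
# coordinate conventions shared by all downstream modules:
#   * positions are 1-based bp coordinates, strictly increasing;
#   * interval semantics are half-open [start, end);
#   * alleles are 0/1 with NA for missing ("N"); heterozygous calls in
#     effectively-haploid (inbred-line) data are converted to NA on ingest.

#' Construct a haplotype matrix
#'
#' The universal container for phased haplotype data: one row per haploid
#' sample, one column per biallelic SNP. Entries are `0L`, `1L` or `NA`
#' (missing, written as `N` in text formats).
#'
#' @param alleles integer matrix of 0/1/NA, one row per haplotype.
#' @param positions integer vector of 1-based bp positions, strictly
#'   increasing, one per column.
#' @param chrom chromosome label (single string).
#' @param sample_ids optional character vector of row labels.
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(alleles, positions, chrom = "chr", sample_ids = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.integer(positions)
  if (ncol(alleles) != length(positions))
    stop("number of columns must equal number of positions")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (length(positions) && any(positions < 1L))
    stop("positions must be >= 1")
  ok <- alleles %in% c(0L, 1L, NA_integer_)
  if (!all(ok)) stop("alleles must be 0, 1 or NA")
  if (is.null(sample_ids))
    sample_ids <- sprintf("hap%d", seq_len(nrow(alleles)))
  if (length(sample_ids) != nrow(alleles))
    stop("sample_ids length must equal number of rows")
  structure(list(chrom = as.character(chrom)[1], positions = positions,
                 alleles = alleles, sample_ids = as.character(sample_ids)),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("<hap_matrix> %s: %d haplotypes x %d SNPs", x$chrom,
              nrow(x$alleles), ncol(x$alleles)))
  if (length(x$positions))
    cat(sprintf(", span %d-%d bp", min(x$positions), max(x$positions)))
  cat(sprintf(", %.2f%% missing\n", 100 * mean(is.na(x$alleles))))
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$alleles)

#' Number of SNPs in a haplotype matrix
#' @param hap a [hap_matrix()].
#' @return Integer SNP count.
#' @export
n_snps <- function(hap) ncol(hap$alleles)

#' Read phased haplotypes from a VCF file
#'
#' Keeps biallelic SNPs only (single-base REF and ALT); multiallelic sites
#' and indels are skipped. Diploid genotypes are split into two haplotype
#' rows per sample when phased (`|` separator); unphased heterozygotes and
#' missing genotypes become `NA` on both rows. Haploid genotype fields
#' (as in inbred-line callsets) yield one row per sample, with heterozygous
#' diploid-coded calls (`0/1`) treated as missing.
#'
#' @param path VCF file (plain or gzipped).
#' @param region optional chromosome label to restrict to.
#' @param haploid if `TRUE`, force one row per sample: any genotype other
#'   than an unambiguous homozygous/haploid call becomes `NA`.
#' @return A [hap_matrix()].
#' @export
read_vcf <- function(path, region = NULL, haploid = FALSE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) keep <- keep & fix[, "CHROM"] == region
  snp <- nchar(fix[, "REF"]) == 1L & !is.na(fix[, "ALT"]) &
    nchar(fix[, "ALT"]) == 1L & fix[, "ALT"] %in% c("A", "C", "G", "T")
  keep <- keep & snp
  if (!any(keep)) stop("no biallelic SNPs found",
                       if (!is.null(region)) paste0(" in region ", region))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  pos <- as.integer(fix[keep, "POS"])
  chrom <- unique(fix[keep, "CHROM"])
  if (length(chrom) > 1)
    stop("VCF spans multiple chromosomes; supply `region`")
  o <- order(pos)
  pos <- pos[o]
  gt <- gt[o, , drop = FALSE]
  if (anyDuplicated(pos)) {
    first <- !duplicated(pos)
    pos <- pos[first]
    gt <- gt[first, , drop = FALSE]
  }

  samples <- colnames(gt)
  nv <- nrow(gt)
  ns <- length(samples)
  code1 <- function(g) { # single-allele call -> 0/1/NA
    out <- rep(NA_integer_, length(g))
    out[g == "0"] <- 0L
    out[g == "1"] <- 1L
    out
  }
  g <- as.vector(gt)                       # column-major: variants fastest
  g[is.na(g)] <- "."
  phased <- grepl("\\|", g)
  slash <- gsub("\\|", "/", g)
  first <- sub("/.*$", "", slash)
  second <- sub("^[^/]*/?", "", slash)
  second[second == ""] <- first[second == ""]  # haploid call
  het <- first != second
  ploidy2 <- any(grepl("[/|]", g))
  if (haploid || !ploidy2) {
    # one row per sample; het and missing calls -> NA
    val <- ifelse(het, ".", first)
    mat <- t(matrix(code1(val), nrow = nv, ncol = ns))
    ids <- samples
  } else {
    # unphased heterozygotes: missing on both haplotypes
    first[het & !phased] <- "."
    second[het & !phased] <- "."
    h1 <- t(matrix(code1(first), nrow = nv, ncol = ns))
    h2 <- t(matrix(code1(second), nrow = nv, ncol = ns))
    mat <- matrix(NA_integer_, nrow = 2 * ns, ncol = nv)
    mat[seq(1, 2 * ns, by = 2), ] <- h1
    mat[seq(2, 2 * ns, by = 2), ] <- h2
    ids <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
  }
  hap_matrix(mat, pos, chrom = chrom, sample_ids = ids)
}

#' Read ms/msms-style simulator output
#'
#' Parses the standard text layout of Hudson's `ms` (one `//` block per
#' replicate with `segsites:` and `positions:` lines followed by 0/1 rows).
#' Fractional positions are mapped to integer bp in `[1, locus_length]`;
#' ties after rounding are resolved by shifting duplicates right so that
#' positions remain strictly increasing.
#'
#' @param path ms-format text file.
#' @param locus_length locus length in bp used to scale positions.
#' @param n_expected optional expected number of haplotypes per replicate;
#'   a mismatch is an error.
#' @return A list of [hap_matrix()] objects, one per replicate, in file
#'   order.
#' @export
read_ms <- function(path, locus_length, n_expected = NULL) {
  if (!file.exists(path)) stop("cannot read ms file: ", path)
  lines <- readLines(path)
  starts <- grep("^//", lines)
  if (!length(starts)) stop("no replicate blocks ('//') found")
  bounds <- c(starts, length(lines) + 1L)
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[(bounds[r] + 1L):(bounds[r + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    segline <- grep("^segsites:", block, value = TRUE)
    if (length(segline) != 1L)
      stop("malformed block in replicate ", r, ": missing segsites line")
    S <- as.integer(sub("^segsites:\\s*", "", segline))
    if (is.na(S)) stop("malformed segsites count in replicate ", r)
    if (S == 0L) {
      nrows <- if (!is.null(n_expected)) n_expected else 0L
      out[[r]] <- hap_matrix(matrix(integer(0), nrow = nrows, ncol = 0),
                             integer(0))
      next
    }
    posline <- grep("^positions:", block, value = TRUE)
    if (length(posline) != 1L)
      stop("malformed block in replicate ", r, ": missing positions line")
    frac <- as.numeric(strsplit(trimws(sub("^positions:\\s*", "", posline)),
                                "\\s+")[[1]])
    if (length(frac) != S || anyNA(frac))
      stop("malformed positions in replicate ", r)
    rows <- block[grepl("^[01]+$", block)]
    if (!length(rows) || any(nchar(rows) != S))
      stop("malformed haplotype rows in replicate ", r)
    if (!is.null(n_expected) && length(rows) != n_expected)
      stop("replicate ", r, " has ", length(rows), " haplotypes; expected ",
           n_expected)
    mat <- matrix(as.integer(unlist(strsplit(rows, ""), use.names = FALSE)),
                  nrow = length(rows), byrow = TRUE)
    pos <- fractions_to_bp(frac, locus_length)
    out[[r]] <- hap_matrix(mat, pos)
  }
  out
}

# Map sorted fractional positions to strictly increasing integer bp
# (duplicates after rounding are shifted right).
fractions_to_bp <- function(frac, locus_length) {
  pos <- pmin(pmax(round(frac * locus_length), 1), locus_length)
  if (length(pos) > 1) {
    i <- seq_along(pos)
    pos <- cummax(pos - i) + i
  }
  as.integer(pos)
}

# Internal constructor for simulator output known to satisfy the
# invariants; skips element validation.
new_hap_matrix <- function(alleles, positions, chrom = "chr",
                           sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- sprintf("hap%d", seq_len(nrow(alleles)))
  structure(list(chrom = chrom, positions = as.integer(positions),
                 alleles = alleles, sample_ids = sample_ids),
            class = "hap_matrix")
}

#' Write samples in ms format
#'
#' Inverse of [read_ms()]: emits one `//` block per sample with positions
#' as fractions of `locus_length`. Matrices with missing data cannot be
#' represented in ms format and raise an error.
#'
#' @param samples a [hap_matrix()], a `sweep_sample`, or a list of either.
#' @param path output file.
#' @param locus_length locus length in bp.
#' @return `path`, invisibly.
#' @export
write_ms <- function(samples, path, locus_length) {
  if (inherits(samples, "hap_matrix") || inherits(samples, "sweep_sample"))
    samples <- list(samples)
  mats <- lapply(samples, function(s)
    if (inherits(s, "sweep_sample")) s$hap else s)
  n <- if (length(mats)) nrow(mats[[1]]$alleles) else 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ms %d %d", n, length(mats)), ""), con)
  for (m in mats) {
    if (anyNA(m$alleles))
      stop("ms format cannot encode missing data")
    writeLines("//", con)
    S <- ncol(m$alleles)
    writeLines(sprintf("segsites: %d", S), con)
    if (S > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.10f", m$positions / locus_length),
                             collapse = " ")), con)
      writeLines(apply(m$alleles, 1, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write/read the internal haplotype TSV format
#'
#' A plain-text matrix with a header row of bp positions and one row of
#' `0`/`1`/`N` characters per haplotype, preceded by the sample id.
#'
#' @param hap a [hap_matrix()].
#' @param path file path.
#' @return `write_hap_tsv`: `path` invisibly; `read_hap_tsv`: a
#'   [hap_matrix()].
#' @export
write_hap_tsv <- function(hap, path) {
  ch <- matrix(as.character(hap$alleles), nrow = nrow(hap$alleles))
  ch[is.na(ch)] <- "N"
  lines <- c(paste(c("#chrom", hap$chrom), collapse = "\t"),
             paste(c("id", hap$positions), collapse = "\t"),
             vapply(seq_len(nrow(ch)), function(i)
               paste(c(hap$sample_ids[i], ch[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hap_tsv
#' @export
read_hap_tsv <- function(path) {
  lines <- readLines(path)
  chrom <- strsplit(lines[1], "\t")[[1]][2]
  pos <- as.integer(strsplit(lines[2], "\t")[[1]][-1])
  body <- strsplit(lines[-(1:2)], "\t")
  ids <- vapply(body, `[`, "", 1)
  vals <- lapply(body, `[`, -1)
  mat <- do.call(rbind, lapply(vals, function(v) {
    out <- rep(NA_integer_, length(v))
    out[v == "0"] <- 0L
    out[v == "1"] <- 1L
    out
  }))
  hap_matrix(mat, pos, chrom = chrom, sample_ids = ids)
}

#' Construct or read a recombination-rate map
#'
#' Intervals are half-open `[start, end)` with 1-based starts; rates are in
#' cM/bp. `read_recomb_map` reads a BED-like TSV with columns
#' chrom, start, end, rate.
#'
#' @param chrom,start,end,rate interval columns.
#' @return A data frame of class `recomb_map`.
#' @export
recomb_map <- function(chrom, start, end, rate) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), rate = as.numeric(rate),
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop("intervals must satisfy start < end")
  if (any(df$rate < 0)) stop("rates must be >= 0")
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("overlapping intervals on ", ch)
  }
  class(df) <- c("recomb_map", "data.frame")
  df
}

#' @rdname recomb_map
#' @param path TSV file (comment lines starting `#` are skipped).
#' @export
read_recomb_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("recombination map needs 4 columns")
  recomb_map(df[[1]], df[[2]], df[[3]], df[[4]])
}

#' Look up the local recombination rate
#'
#' Returns the rate (cM/bp) of the interval covering `position`
#' (half-open `[start, end)`), or `NA_real_` when the position is outside
#' all intervals. Callers must treat `NA` as failing any rate filter.
#'
#' @param map a [recomb_map()].
#' @param chrom chromosome label.
#' @param position bp position (>= 1); vectorised.
#' @return Numeric vector of rates, `NA` where unknown.
#' @export
rate_at <- function(map, chrom, position) {
  stopifnot(inherits(map, "recomb_map"))
  position <- as.numeric(position)
  if (any(position < 1, na.rm = TRUE)) stop("position must be >= 1")
  sub <- map[map$chrom == chrom, , drop = FALSE]
  out <- rep(NA_real_, length(position))
  if (!nrow(sub)) return(out)
  for (i in seq_along(position)) {
    hit <- which(sub$start <= position[i] & position[i] < sub$end)
    if (length(hit)) out[i] <- sub$rate[hit[1]]
  }
  out
}

#' DGRP-style strain quality filter
#'
#' Removes strains flagged for residual heterozygosity (incomplete
#' inbreeding) from a set of line IDs. `dgrp_excluded_strains` is the
#' published 17-line exclusion list that reduces the 162 sequenced DGRP
#' freeze-1 lines to the 145 used for haplotype scans.
#'
#' @param sample_ids character vector of line IDs.
#' @param exclude IDs to drop (default [dgrp_excluded_strains]).
#' @return The retained IDs, in input order.
#' @export
filter_strains <- function(sample_ids, exclude = dgrp_excluded_strains) {
  sample_ids[!(sample_ids %in% as.character(exclude))]
}

#' @rdname filter_strains
#' @format `dgrp_excluded_strains`: character vector of 17 line IDs.
#' @export
dgrp_excluded_strains <- c("49", "85", "101", "109", "136", "153", "237",
                           "309", "317", "325", "338", "352", "377", "386",
                           "426", "563", "802")
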