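# Neutral and sweep sample simulation.
#
# Neutral samples come from a sequentially Markovian coalescent (SMC') with
# recombination and piecewise-constant population size. Sweep samples are
# generated by a forward Wright-Fisher phase in a rescaled population of
# N' = Ne/Q diploids, initialised at neutral stationarity by a coalescent
# draw of the whole scaled population. Rescaling preserves the
# population-scaled parameters theta = 4*Ne*mu*L, rho_pop = 4*Ne*r*L,
# theta_A = 4*Ne*mu_A and 2*Ne*s (so s' = s*Q, mu' = mu*Q, r' = r*Q), and
# times scale as t' = t/Q generations.
#
# Selection is co-dominant: diploid fitnesses 1 : 1+s' : 1+2s', so a
# homozygote for the adaptive allele has twice the heterozygote advantage.
# The adaptive site sits at the centre of the locus. Selection switches off
# when the combined adaptive-allele frequency first reaches PF; the
# population then ages neutrally for T_E * 4N' generations before n
# haplotypes are sampled without replacement.

#' Demography specifications
#'
#' `demography_constant` is a single population of diploid effective size
#' `ne`. `demography_bottleneck` is, looking backwards in time: the present
#' size `nf` (relative to the ancestral size) for `tf` time units, a
#' bottleneck of relative size `nb` for `tb` units, then the ancestral size;
#' times are in units of 2*Ne(ancestral) generations. `demography_admixture`
#' is a founding-admixture template: the present population was founded
#' `t_found_gen` generations ago by drawing a fraction `prop` of haplotypes
#' from source population 1 (relative size `size1`) and the rest from source
#' population 2 (`size2`), then evolving forward to the present. Source
#' parameters are user-supplied.
#'
#' @param ne ancestral/reference diploid effective population size.
#' @param nb,tb bottleneck relative size and duration.
#' @param nf,tf present-epoch relative size and duration.
#' @param prop admixture proportion from source 1.
#' @param size1,size2 source population sizes relative to `ne`.
#' @param t_found_gen founding time in generations before the present.
#' @return A `demography` list consumed by [sweep_model()].
#' @export
demography_constant <- function(ne = 1e6) {
  stopifnot(ne > 0)
  structure(list(model = "constant", ne = ne,
                 epoch_start = 0, epoch_size = 1), class = "demography")
}

#' @rdname demography_constant
#' @export
demography_bottleneck <- function(ne = 1e6, nb, tb, nf = 1, tf = 0.005) {
  stopifnot(ne > 0, nb > 0, tb >= 0, nf > 0, tf >= 0)
  structure(list(model = "bottleneck", ne = ne, nb = nb, tb = tb,
                 nf = nf, tf = tf,
                 epoch_start = c(0, tf, tf + tb),
                 epoch_size = c(nf, nb, 1)), class = "demography")
}

#' @rdname demography_constant
#' @export
demography_admixture <- function(ne = 5e6, prop = 0.85, size1 = 1,
                                 size2 = 1, t_found_gen = 1525) {
  stopifnot(ne > 0, prop >= 0, prop <= 1, size1 > 0, size2 > 0,
            t_found_gen >= 0)
  structure(list(model = "admixture", ne = ne, prop = prop, size1 = size1,
                 size2 = size2, t_found_gen = t_found_gen,
                 epoch_start = 0, epoch_size = 1), class = "demography")
}

#' Specify a simulation model
#'
#' Defaults are the scan's reference study conditions: a constant
#' Ne = 1e6 diploid population, neutral mutation rate 1e-9 per bp per
#' generation, recombination rate 5e-7 cM/bp, a 1e5 bp locus and samples of
#' 145 haplotypes; sweep samples with fewer than 400 segregating sites are
#' discarded and redrawn.
#'
#' @param mode `"neutral"`, `"de_novo"` (recurrent adaptive mutation at
#'   population rate `theta_a = 4*Ne*mu_A`) or `"sgv"` (a single standing
#'   allele conditioned, by rejection, on first drifting to frequency `f0`
#'   before selection starts).
#' @param demography a [demography_constant()], [demography_bottleneck()]
#'   or [demography_admixture()].
#' @param locus_length locus length in bp.
#' @param mu neutral mutation rate per bp per generation.
#' @param rho_cmbp recombination rate in cM/bp (1 cM = 0.01 crossovers).
#' @param n sample size (haplotypes).
#' @param theta_a population-scaled adaptive mutation rate (de novo mode).
#' @param f0 starting adaptive-allele frequency (sgv mode).
#' @param s selection coefficient of the heterozygote (co-dominance:
#'   homozygote advantage `2s`).
#' @param pf partial frequency at which selection ceases (1 = complete
#'   sweep).
#' @param te time since selection ended, in units of `4*Ne` generations.
#' @param np scaled population size N' (diploids) for the forward phase;
#'   the rescaling factor is `Q = ne/np`.
#' @param min_snps minimum segregating sites per sample; smaller samples
#'   are rejected and redrawn.
#' @return A `sweep_model` list.
#' @export
sweep_model <- function(mode = c("neutral", "de_novo", "sgv"),
                        demography = demography_constant(1e6),
                        locus_length = 1e5, mu = 1e-9, rho_cmbp = 5e-7,
                        n = 145, theta_a = 0.01, f0 = 1e-4, s = 0.01,
                        pf = 0.5, te = 0, np = 500, min_snps = 400) {
  mode <- match.arg(mode)
  stopifnot(inherits(demography, "demography"), locus_length >= 1,
            mu >= 0, rho_cmbp >= 0, n >= 2, theta_a >= 0,
            f0 >= 0, f0 < 1, s >= 0, pf > 0, pf <= 1, te >= 0, np >= 2)
  structure(list(mode = mode, demography = demography,
                 locus_length = locus_length, mu = mu, rho_cmbp = rho_cmbp,
                 n = as.integer(n), theta_a = theta_a, f0 = f0, s = s,
                 pf = pf, te = te, np = as.integer(np),
                 min_snps = as.integer(min_snps)), class = "sweep_model")
}

#' @export
print.sweep_model <- function(x, ...) {
  cat(sprintf("<sweep_model> mode = %s, Ne = %g (%s), L = %g bp, n = %d\n",
              x$mode, x$demography$ne, x$demography$model, x$locus_length,
              x$n))
  if (x$mode != "neutral")
    cat(sprintf("  s = %g, PF = %g, T_E = %g, %s, N' = %d (Q = %g)\n", x$s,
                x$pf, x$te,
                if (x$mode == "de_novo") sprintf("theta_A = %g", x$theta_a)
                else sprintf("f0 = %g", x$f0),
                x$np, x$demography$ne / x$np))
  invisible(x)
}

# Population-scaled locus parameters.
scaled_params <- function(model) {
  ne <- model$demography$ne
  r <- model$rho_cmbp * 0.01        # crossovers per bp per generation
  list(theta = 4 * ne * model$mu * model$locus_length,
       rho = 4 * ne * r * model$locus_length,
       q = ne / model$np)
}

#' Simulate one neutral or sweep sample
#'
#' Uses R's global RNG; seed with [set.seed()]. Samples with fewer than
#' `min_snps` segregating sites are rejected and redrawn (up to
#' `max_tries`).
#'
#' @param model a [sweep_model()].
#' @param min_snps override of the model's minimum segregating-site count.
#' @param max_tries redraw budget for the `min_snps` rejection.
#' @return A `sweep_sample`: list with `hap` (a [hap_matrix()]),
#'   `adaptive_col` (column of the adaptive site, `NA` if not segregating
#'   in the sample), `adaptive_pos` (bp), `origins` (per-haplotype
#'   mutational-origin label, 0 for non-carriers), `freq_at_stop` (adaptive
#'   frequency when selection ceased), `final_freq` (at sampling), `mode`,
#'   `generations`, `restarts`.
#' @export
simulate_sweep <- function(model, min_snps = model$min_snps,
                           max_tries = 100) {
  stopifnot(inherits(model, "sweep_model"))
  for (i in seq_len(max_tries)) {
    s <- simulate_once(model)
    if (n_snps(s$hap) >= min_snps) return(s)
  }
  stop("no sample with >= ", min_snps, " segregating sites in ",
       max_tries, " tries; reduce min_snps or enlarge the locus")
}

simulate_once <- function(model) {
  sp <- scaled_params(model)
  dem <- model$demography
  L <- model$locus_length

  if (model$mode == "neutral" && dem$model != "admixture") {
    cs <- .coal_sample(model$n, sp$theta, sp$rho, dem$epoch_start,
                       dem$epoch_size)
    hap <- new_hap_matrix(cs$alleles, fractions_to_bp(cs$positions, L))
    return(structure(list(hap = hap, adaptive_col = NA_integer_,
                          adaptive_pos = as.integer(round(L / 2)),
                          origins = integer(model$n), freq_at_stop = NA_real_,
                          final_freq = NA_real_, mode = "neutral",
                          generations = 0, restarts = 0L),
                     class = "sweep_sample"))
  }

  np <- model$np
  nhap <- 2L * np
  mu_g <- sp$theta / (4 * np)
  rr_g <- sp$rho / (4 * np)
  mua_g <- model$theta_a / (4 * np)
  sel <- model$s * sp$q
  te_gens <- as.integer(round(model$te * 4 * np))
  max_gen <- 500L * np

  if (dem$model == "admixture") {
    init <- admixture_init(model, sp)
    t_found_scaled <- round(dem$t_found_gen / sp$q)
    if (model$mode == "neutral") {
      fw <- .forward_sweep(init$positions, init$alleles, mu_g, rr_g, 0, 0,
                           0L, 1, 0, 0L, model$n, as.integer(t_found_scaled),
                           max_gen, 1000L, integer(0))
    } else {
      # selection onset uniform on [0, founding time], running to sampling
      onset <- runif(1, 0, t_found_scaled)
      pre <- as.integer(round(t_found_scaled - onset))
      sel_gens <- as.integer(round(onset))
      fw0 <- .forward_sweep(init$positions, init$alleles, mu_g, rr_g, 0, 0,
                            0L, 1, 0, 0L, nhap, pre, max_gen, 1000L,
                            integer(0))
      init_orig <- integer(nhap)
      adapt_rate <- mua_g
      if (model$mode == "sgv") {
        # seed standing copies directly in the founded population
        k <- max(1L, as.integer(round(model$f0 * nhap)))
        init_orig[sample.int(nhap, k)] <- seq_len(k)
        adapt_rate <- 0
      }
      fw <- .forward_sweep(fw0$positions, fw0$alleles, mu_g, rr_g, sel,
                           adapt_rate, 3L, 1, 0, 0L, model$n, sel_gens,
                           max_gen, 1000L, init_orig)
    }
  } else {
    cs <- .coal_sample(nhap, sp$theta, sp$rho, dem$epoch_start,
                       dem$epoch_size)
    mode_code <- switch(model$mode, de_novo = 1L, sgv = 2L,
                        neutral = 0L)
    fw <- .forward_sweep(cs$positions, cs$alleles, mu_g, rr_g, sel, mua_g,
                         mode_code, model$pf, model$f0, te_gens, model$n,
                         0L, max_gen, 1000L, integer(0))
  }

  hap <- new_hap_matrix(fw$alleles, fractions_to_bp(fw$positions, L))
  structure(list(hap = hap,
                 adaptive_col = fw$adaptive_col,
                 adaptive_pos = as.integer(round(L / 2)),
                 origins = as.integer(fw$origins),
                 freq_at_stop = fw$freq_at_stop,
                 final_freq = fw$final_freq, mode = model$mode,
                 generations = fw$generations,
                 restarts = fw$restarts),
            class = "sweep_sample")
}

# Founding admixed population: 2*np haplotypes drawn from two coalescent
# source samples.
admixture_init <- function(model, sp) {
  dem <- model$demography
  nhap <- 2L * model$np
  k1 <- rbinom(1, nhap, dem$prop)
  parts <- list()
  if (k1 >= 2) {
    parts$a <- .coal_sample(k1, sp$theta, sp$rho, 0, dem$size1)
  } else if (k1 == 1) {
    parts$a <- .coal_sample(2L, sp$theta, sp$rho, 0, dem$size1)
    parts$a$alleles <- parts$a$alleles[1, , drop = FALSE]
  }
  k2 <- nhap - k1
  if (k2 >= 2) {
    parts$b <- .coal_sample(k2, sp$theta, sp$rho, 0, dem$size2)
  } else if (k2 == 1) {
    parts$b <- .coal_sample(2L, sp$theta, sp$rho, 0, dem$size2)
    parts$b$alleles <- parts$b$alleles[1, , drop = FALSE]
  }
  pos <- sort(unique(unlist(lapply(parts, `[[`, "positions"))))
  mat <- matrix(0L, nrow = 0, ncol = length(pos))
  for (p in parts) {
    m <- matrix(0L, nrow = nrow(p$alleles), ncol = length(pos))
    m[, match(p$positions, pos)] <- p$alleles
    mat <- rbind(mat, m)
  }
  list(positions = pos, alleles = mat)
}

#' @export
print.sweep_sample <- function(x, ...) {
  cat(sprintf("<sweep_sample> mode = %s: %d haplotypes x %d SNPs", x$mode,
              nrow(x$hap$alleles), n_snps(x$hap)))
  if (x$mode != "neutral")
    cat(sprintf("; adaptive freq %.3f, %d origin(s) in sample",
                x$final_freq, count_origins(x)))
  cat("\n")
  invisible(x)
}

#' Number of adaptive-mutation origins in a sample
#'
#' Counts the distinct mutational origins (for standing variation: distinct
#' standing copies at the onset of selection) among sampled carriers of the
#' adaptive allele.
#'
#' @param sample a `sweep_sample` from a non-neutral [simulate_sweep()].
#' @return Integer origin count (0 if no carrier was sampled).
#' @export
count_origins <- function(sample) {
  stopifnot(inherits(sample, "sweep_sample"))
  if (sample$mode == "neutral")
    stop("origin counts are undefined for neutral samples")
  length(unique(sample$origins[sample$origins > 0]))
}

#' Physical footprint of a hard sweep
#'
#' The expected width of the region swept to low diversity by a hard sweep,
#' `s / (log(Ne * s) * r)` bp, with the natural log. Requires `Ne * s > 1`
#' (a selection strength drift can feel) and `r > 0`.
#'
#' @param s selection coefficient.
#' @param ne diploid effective population size.
#' @param r recombination rate in crossovers per bp per generation
#'   (cM/bp divided by 100).
#' @return Footprint length in bp.
#' @export
footprint_length <- function(s, ne, r) {
  if (r <= 0) stop("r must be > 0")
  if (ne * s <= 1) stop("footprint undefined for Ne * s <= 1")
  s / (log(ne * s) * r)
}

#' Homozygosity statistics of the sweep-centred window
#'
#' Clusters the `size`-SNP window centred on the adaptive site (or on the
#' SNP nearest the locus centre for neutral samples) and returns its
#' homozygosity statistics.
#'
#' @param sample a `sweep_sample`.
#' @param size window size in SNPs.
#' @return A `homozygosity_stats` list.
#' @export
sweep_window_stats <- function(sample, size = 400) {
  stopifnot(inherits(sample, "sweep_sample"))
  S <- n_snps(sample$hap)
  if (S < size)
    stop("sample has ", S, " SNPs; window needs ", size)
  centre <- if (!is.na(sample$adaptive_col)) sample$adaptive_col else
    which.min(abs(sample$hap$positions - sample$adaptive_pos))
  start <- centre - size %/% 2L
  start <- min(max(start, 1L), S - size + 1L)
  window_stats(sample$hap$alleles[, start:(start + size - 1L), drop = FALSE])
}
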