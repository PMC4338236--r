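test_that("neutral segregating sites match the Watterson expectation", {
  set.seed(31)
  n <- 20
  theta <- 40 # population-scaled locus mutation rate
  model <- sweep_model(mode = "neutral", locus_length = 2e4,
                       demography = demography_constant(5e5),
                       mu = theta / (4 * 5e5 * 2e4), n = n, min_snps = 0)
  reps <- 200
  S <- vapply(seq_len(reps), function(i)
    n_snps(simulate_sweep(model)$hap), numeric(1))
  expected <- theta * sum(1 / seq_len(n - 1))
  se <- sd(S) / sqrt(reps)
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("neutral pairwise diversity matches the Tajima expectation", {
  set.seed(32)
  n <- 12
  theta <- 30
  model <- sweep_model(mode = "neutral", locus_length = 2e4,
                       demography = demography_constant(5e5),
                       mu = theta / (4 * 5e5 * 2e4), n = n, min_snps = 0)
  reps <- 200
  pw <- vapply(seq_len(reps), function(i) {
    al <- simulate_sweep(model)$hap$alleles
    f <- colSums(al)
    sum(2 * f * (n - f) / (n * (n - 1)))
  }, numeric(1))
  expect_lt(abs(mean(pw) - theta), 3 * sd(pw) / sqrt(reps))
})

test_that("a bottleneck reduces diversity relative to the constant model", {
  set.seed(33)
  base <- sweep_model(mode = "neutral", locus_length = 2e4,
                      demography = demography_constant(2e5), n = 20,
                      min_snps = 0)
  bot <- base
  bot$demography <- demography_bottleneck(2e5, nb = 0.02, tb = 0.05,
                                          nf = 1, tf = 0.01)
  S0 <- mean(replicate(60, n_snps(simulate_sweep(base)$hap)))
  S1 <- mean(replicate(60, n_snps(simulate_sweep(bot)$hap)))
  expect_lt(S1, S0)
})

test_that("footprint formula, domain errors and monotonicity", {
  expect_equal(footprint_length(5e-4, 1e6, 5e-9),
               5e-4 / (log(500) * 5e-9))
  expect_gt(footprint_length(5e-4, 1e6, 5e-9), 1e4)
  expect_error(footprint_length(1e-6, 1e6, 5e-9), "Ne")
  expect_error(footprint_length(0.01, 1e6, 0), "r must")
  # monotone in s; the log denominator makes the growth slightly sublinear
  f1 <- footprint_length(0.01, 1e6, 5e-9)
  f2 <- footprint_length(0.02, 1e6, 5e-9)
  expect_gt(f2, f1)
  expect_equal(f2 / f1, 2 * log(1e4) / log(2e4), tolerance = 1e-12)
})

test_that("selection stops at the first generation crossing PF", {
  # with a weak scaled coefficient (s' = s*Q = 0.2) the per-generation
  # frequency increment is small, so the first crossing lands just above
  # PF; a Wright-Fisher generation can overshoot by about
  # s'*p*(1-p) plus binomial noise, never land below
  set.seed(34)
  model <- sweep_model(mode = "de_novo", theta_a = 5, s = 0.004, pf = 0.5,
                       locus_length = 1e4,
                       demography = demography_constant(2e4),
                       n = 30, np = 400, min_snps = 0)
  for (i in 1:5) {
    s <- simulate_sweep(model)
    expect_gte(s$freq_at_stop, 0.5)
    expect_lte(s$freq_at_stop, 0.5 + 0.2 * 0.25 + 4 * sqrt(0.25 / 800))
  }
})

test_that("hard-sweep simulations carry a single mutational origin", {
  set.seed(35)
  model <- sweep_model(mode = "de_novo", theta_a = 0.01, s = 0.01, pf = 1,
                       locus_length = 1e4,
                       demography = demography_constant(1e6),
                       n = 30, np = 200, min_snps = 0)
  orig <- replicate(40, count_origins(simulate_sweep(model)))
  expect_gte(mean(orig == 1), 0.95)
})

test_that("origin counts increase with the adaptive mutation rate", {
  set.seed(36)
  model <- sweep_model(mode = "de_novo", s = 0.01, pf = 0.5,
                       locus_length = 1e4,
                       demography = demography_constant(1e6),
                       n = 40, np = 200, min_snps = 0)
  model$theta_a <- 0.01
  o_hard <- replicate(30, count_origins(simulate_sweep(model)))
  model$theta_a <- 10
  o_soft <- replicate(30, count_origins(simulate_sweep(model)))
  expect_gt(mean(o_soft), mean(o_hard))
  expect_gte(min(o_hard), 1)
})

test_that("neutral samples refuse origin counts", {
  set.seed(37)
  s <- simulate_sweep(tiny_neutral_model(n = 4, locus = 5e3))
  expect_error(count_origins(s), "neutral")
})

test_that("standing-variation sweeps respect f0 conditioning and PF", {
  set.seed(38)
  model <- sweep_model(mode = "sgv", f0 = 0.02, s = 0.05, pf = 0.6,
                       locus_length = 1e4,
                       demography = demography_constant(1e5),
                       n = 30, np = 150, min_snps = 0)
  s <- simulate_sweep(model)
  expect_gte(s$freq_at_stop, 0.6)
  expect_gte(count_origins(s), 1)
  # standing origins cannot exceed the copies present when selection began
  expect_lte(count_origins(s), 2 * 150)
})

test_that("rescaling invariance: Q = 500 vs Q = 1000 statistics agree", {
  set.seed(39)
  mk <- function(np) sweep_model(mode = "de_novo", theta_a = 2, s = 0.02,
                                 pf = 0.5, locus_length = 2e4,
                                 demography = demography_constant(5e5),
                                 n = 40, np = np, min_snps = 0)
  reps <- 120
  h12_a <- replicate(reps, {
    s <- simulate_sweep(mk(500))
    sweep_window_stats(s, size = min(100, n_snps(s$hap)))$h12
  })
  h12_b <- replicate(reps, {
    s <- simulate_sweep(mk(1000))
    sweep_window_stats(s, size = min(100, n_snps(s$hap)))$h12
  })
  expect_gt(suppressWarnings(stats::ks.test(h12_a, h12_b)$p.value), 0.01)
})

test_that("sweep signatures decay with sweep age", {
  set.seed(40)
  model <- sweep_model(mode = "de_novo", theta_a = 0.01, s = 0.01, pf = 1,
                       locus_length = 2e4,
                       demography = demography_constant(5e5),
                       n = 40, np = 250, min_snps = 0)
  h12_young <- replicate(40, {
    s <- simulate_sweep(model)
    sweep_window_stats(s, size = min(100, n_snps(s$hap)))$h12
  })
  model$te <- 0.05
  h12_old <- replicate(40, {
    s <- simulate_sweep(model)
    sweep_window_stats(s, size = min(100, n_snps(s$hap)))$h12
  })
  expect_lt(mean(h12_old), mean(h12_young))
})

test_that("the admixture template produces valid neutral and sweep samples", {
  set.seed(41)
  dem <- demography_admixture(ne = 1e5, prop = 0.6, size1 = 1, size2 = 0.5,
                              t_found_gen = 2000)
  model <- sweep_model(mode = "neutral", demography = dem,
                       locus_length = 1e4, n = 20, np = 100, min_snps = 0)
  s <- simulate_sweep(model)
  expect_s3_class(s$hap, "hap_matrix")
  expect_gt(n_snps(s$hap), 0)
  model$mode <- "de_novo"
  model$theta_a <- 20
  model$s <- 0.1
  s2 <- simulate_sweep(model)
  expect_true(is.finite(s2$final_freq))
})
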