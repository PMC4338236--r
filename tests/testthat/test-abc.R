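test_that("accept_distance implements the normalised metric", {
  expect_equal(accept_distance(c(0.5, 0.5), c(0.5, 0.5), 0.01, 0.04), 0)
  expect_equal(accept_distance(c(0.5, 0.5), c(0.6, 0.5), 0.01, 0.04), 1)
  # symmetry
  o <- c(0.3, 0.7); s <- c(0.5, 0.2)
  expect_equal(accept_distance(o, s, 0.02, 0.03),
               accept_distance(s, o, 0.02, 0.03))
  # plug-in arithmetic
  expect_equal(accept_distance(c(0.2, 0.4), c(0.3, 0.6), 0.01, 0.04),
               sqrt(0.01 / 0.01 + 0.04 / 0.04))
  expect_error(accept_distance(o, s, 0, 0.03), "> 0")
})

test_that("map_estimate recovers point masses, uniform CIs and modes", {
  set.seed(51)
  # near point mass
  est <- map_estimate(10 + runif(200, -0.01, 0.01), support = c(0, 100))
  expect_lt(abs(est$map - 10), 0.5)
  expect_lt(diff(est$ci), 0.05)
  # uniform draws: CI close to (2.5, 97.5)
  est <- map_estimate(runif(1e4, 0, 100), support = c(0, 100))
  expect_lt(abs(est$ci[1] - 2.5), 2)
  expect_lt(abs(est$ci[2] - 97.5), 2)
  # bimodal: MAP at the taller smoothed mode, CI spans both
  draws <- c(rnorm(700, 5, 0.3), rnorm(300, 50, 0.3))
  est <- map_estimate(draws, support = c(0, 100))
  expect_lt(abs(est$map - 5), 1)
  expect_lt(est$ci[1], 10)
  expect_gt(est$ci[2], 45)
  # KDE oracle on a fine grid
  d <- stats::density(draws, bw = stats::bw.nrd0(draws), n = 512,
                      from = 0, to = 100)
  expect_equal(est$map, d$x[which.max(d$y)])
  expect_error(map_estimate(1:10), "at least 30")
})

test_that("a degenerate simulator accepts everything; a hopeless one errors", {
  set.seed(52)
  cfg <- abc_config(target = 50, max_sims = 200)
  # stub table echoing the observation exactly: every draw accepted
  tab <- data.frame(theta_a = runif(100, 0, 100), s = runif(100),
                    pf = runif(100), te = runif(100, 0, 1e-3),
                    rho = 1e-6, h12 = 0.30, h2_h1 = 0.40)
  post <- abc_posterior(c(0.30, 0.40), cfg, table = tab)
  expect_equal(nrow(post$draws), 50L)
  expect_equal(post$acceptance_rate, 1)
  # posterior = prior: draws within support
  expect_true(all(post$draws$theta_a >= 0 & post$draws$theta_a <= 100))

  # simulator pinned far away: nothing accepted within the budget
  tab_far <- tab
  tab_far$h12 <- 1e-9 + rnorm(100, 0, 1e-10)
  tab_far$h2_h1 <- 1e-9 + abs(rnorm(100, 0, 1e-10))
  expect_error(abc_posterior(c(1, 1), cfg, table = tab_far),
               "at least 30 draws|acceptance rate")
})

test_that("acceptance is monotone in the radius and within prior support", {
  set.seed(53)
  tab <- data.frame(theta_a = runif(500, 0, 100), s = runif(500),
                    pf = runif(500), te = runif(500, 0, 1e-3), rho = 1e-6,
                    h12 = runif(500), h2_h1 = runif(500))
  obs <- c(0.4, 0.6)
  acc1 <- haplosweep:::abc_accept(obs, tab, 0.1)
  acc2 <- haplosweep:::abc_accept(obs, tab, 0.5)
  expect_true(all(which(acc1) %in% which(acc2)))
  # relative rule behaves as a 10% box
  accr <- haplosweep:::abc_accept(obs, tab, 0.1, rule = "relative")
  expect_true(all(abs(tab$h12[accr] - 0.4) <= 0.04 + 1e-12))
  expect_true(all(abs(tab$h2_h1[accr] - 0.6) <= 0.06 + 1e-12))
})

test_that("bayes_factor counts, bounds and flags behave", {
  set.seed(54)
  mk <- function(n, h12, h2h1, sd = 0.05)
    data.frame(h12 = pmin(pmax(rnorm(n, h12, sd), 0), 1),
               h2_h1 = pmin(pmax(rnorm(n, h2h1, sd), 0), 1))
  hard <- mk(500, 0.30, 0.05)
  soft <- mk(500, 0.25, 0.60)
  # identical sets: BF = 1 at any observation with neighbours in radius
  b <- bayes_factor(c(0.3, 0.05), hard, hard, radius = 0.5)
  expect_equal(b$bf, 1)
  # soft-like observation favours soft
  b2 <- bayes_factor(c(0.25, 0.6), hard, soft, radius = 0.5)
  expect_gt(b2$bf, 1)
  # antisymmetry on sets with known counts: swapping inverts the BF
  ha <- data.frame(h12 = c(rep(0.5, 4), rep(0.9, 46)),
                   h2_h1 = c(rep(0.5, 4), rep(0.9, 46)))
  so <- data.frame(h12 = c(rep(0.5, 40), rep(0.9, 10)),
                   h2_h1 = c(rep(0.5, 40), rep(0.9, 10)))
  bfwd <- bayes_factor(c(0.5, 0.5), ha, so, radius = 0.1)
  brev <- bayes_factor(c(0.5, 0.5), so, ha, radius = 0.1)
  expect_equal(bfwd$bf, 1 / brev$bf)
  # zero hard count: flagged lower bound equal to the soft count
  b4 <- bayes_factor(c(0.25, 0.6), mk(50, 0.999, 0.001, 1e-6), soft,
                     radius = 0.5)
  expect_true(b4$bound)
  expect_equal(b4$bf, b4$n_soft)
  # both zero: undefined flag, not NaN/Inf
  b5 <- bayes_factor(c(0.5, 0.5), mk(50, 0.99, 0.01, 1e-6),
                     mk(50, 0.01, 0.99, 1e-6))
  expect_true(b5$undefined)
  expect_true(is.na(b5$bf))
  expect_error(bayes_factor(c(0.5, 0.5), hard[0, ], soft), "non-empty")
})

test_that("exact count ratios give exact Bayes factors", {
  # place simulations at controlled distances so counts are known
  hard <- data.frame(h12 = c(rep(0.5, 4), rep(0.9, 46)),
                     h2_h1 = c(rep(0.5, 4), rep(0.9, 46)))
  soft <- data.frame(h12 = c(rep(0.5, 40), rep(0.9, 10)),
                     h2_h1 = c(rep(0.5, 40), rep(0.9, 10)))
  b <- bayes_factor(c(0.5, 0.5), hard, soft, radius = 0.1)
  expect_equal(b$n_hard, 4L)
  expect_equal(b$n_soft, 40L)
  expect_equal(b$bf, 10)
})

test_that("bf_grid flags empty cells and reproduces the sweep geometry", {
  set.seed(55)
  hard <- data.frame(h12 = runif(400, 0.4, 0.9), h2_h1 = runif(400, 0, 0.15))
  soft <- data.frame(h12 = runif(400, 0.1, 0.5), h2_h1 = runif(400, 0.3, 0.9))
  g <- bf_grid(hard, soft, h12_breaks = seq(0, 1, 0.25),
               h2h1_breaks = seq(0, 1, 0.25), radius = 1)
  expect_false(any(is.nan(g$bf) & !is.na(g$bf)))
  expect_true(all(is.na(g$bf) == g$undefined))
  # hard-favoured corner: high H12, low H2/H1; soft corner the reverse
  corner_hard <- g[g$h12 == 0.625 & g$h2_h1 == 0.125, ]
  corner_soft <- g[g$h12 == 0.375 & g$h2_h1 == 0.625, ]
  expect_gt(corner_hard$n_hard, corner_hard$n_soft)
  if (!corner_hard$bound && !corner_hard$undefined)
    expect_lt(corner_hard$bf, 1)
  expect_gt(corner_soft$bf, 1)
  # identical sets: every defined cell has BF 1
  g2 <- bf_grid(hard, hard, h12_breaks = seq(0, 1, 0.5),
                h2h1_breaks = seq(0, 1, 0.5), radius = 1)
  expect_true(all(g2$bf[!g2$undefined & !g2$bound] == 1))
})
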