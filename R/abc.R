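# Rejection-ABC inference of the adaptive mutation rate theta_A from an
# observed (H12, H2/H1) pair, and Bayes factors comparing soft versus hard
# sweep generative models.
#
# A parameter draw (theta_A, s, PF, T_E) is accepted when the
# variance-normalised distance between its simulated (H12, H2/H1) and the
# observation,
#   d = sqrt( (H12_obs - H12_i)^2 / Var(H12)
#           + (H2/H1_obs - H2/H1_i)^2 / Var(H2/H1) ),
# is below the acceptance radius (default 0.1), with the variances
# estimated from all simulated data sets of the run.

#' ABC configuration
#'
#' Priors follow the reference analysis: theta_A ~ U[0, 100], s ~ U[0, 1],
#' PF ~ U[0, 1], T_E ~ U[0, 0.001] (in units of 4*Ne generations). The
#' recombination rate is drawn uniformly from a rate bin (cM/bp); the five
#' reference bins partition [5.42e-7, 5.88e-6).
#'
#' @param target number of acceptances to collect (reference analysis:
#'   1000).
#' @param radius acceptance radius on the normalised distance.
#' @param rho_bin length-2 numeric, the cM/bp bin to draw the
#'   recombination rate from; see [abc_rho_bins].
#' @param theta_a_max,s_max,pf_max,te_max upper prior bounds.
#' @param model template [sweep_model()] giving demography, locus length,
#'   sample size, scaled population size and `min_snps`; its `mode` is
#'   forced to `"de_novo"`.
#' @param max_sims simulation budget before giving up.
#' @param rule `"distance"` for the normalised-distance acceptance rule;
#'   `"relative"` for the alternative per-component rule accepting when
#'   both statistics are within 10% (`radius`) of the observed values;
#'   `"nearest"` to accept the `target` draws with the smallest
#'   normalised distance (the standard fixed-acceptance-fraction form of
#'   rejection ABC, useful when the simulation budget rather than the
#'   tolerance is fixed).
#' @return An `abc_config` list.
#' @export
abc_config <- function(target = 1000, radius = 0.1,
                       rho_bin = abc_rho_bins[[1]],
                       theta_a_max = 100, s_max = 1, pf_max = 1,
                       te_max = 0.001, model = sweep_model(mode = "de_novo"),
                       max_sims = 100 * target,
                       rule = c("distance", "relative", "nearest")) {
  rule <- match.arg(rule)
  stopifnot(target >= 1, radius > 0, length(rho_bin) == 2,
            rho_bin[1] <= rho_bin[2], inherits(model, "sweep_model"))
  model$mode <- "de_novo"
  structure(list(target = as.integer(target), radius = radius,
                 rho_bin = as.numeric(rho_bin), theta_a_max = theta_a_max,
                 s_max = s_max, pf_max = pf_max, te_max = te_max,
                 model = model, max_sims = as.integer(max_sims),
                 rule = rule), class = "abc_config")
}

#' @rdname abc_config
#' @format `abc_rho_bins`: list of five length-2 numeric recombination-rate
#'   bins in cM/bp.
#' @export
abc_rho_bins <- list(c(5.42e-7, 1.61e-6), c(1.61e-6, 2.68e-6),
                     c(2.68e-6, 3.74e-6), c(3.74e-6, 4.81e-6),
                     c(4.81e-6, 5.88e-6))

#' Normalised (H12, H2/H1) acceptance distance
#'
#' @param obs,sim length-2 numeric vectors `(h12, h2_h1)`.
#' @param var_h12,var_h2h1 variances of the two statistics over all
#'   simulations of the run (> 0).
#' @return The normalised Euclidean distance.
#' @export
accept_distance <- function(obs, sim, var_h12, var_h2h1) {
  if (any(c(var_h12, var_h2h1) <= 0)) stop("variances must be > 0")
  sqrt((obs[1] - sim[1])^2 / var_h12 + (obs[2] - sim[2])^2 / var_h2h1)
}

# Simulate (h12, h2_h1) for one prior draw; NA row when the draw failed to
# produce a sweep within the simulation's internal budget.
simulate_draw <- function(model, theta_a, s, pf, te, rho_cmbp,
                          window_size) {
  model$theta_a <- theta_a
  model$s <- s
  model$pf <- pf
  model$te <- te
  model$rho_cmbp <- rho_cmbp
  res <- tryCatch({
    smp <- simulate_sweep(model, max_tries = 20)
    st <- sweep_window_stats(smp, size = window_size)
    c(st$h12, st$h2_h1)
  }, error = function(e) c(NA_real_, NA_real_))
  res
}

#' Simulate a reference table of prior draws
#'
#' Draws parameters from the priors in `config`, simulates a sweep for
#' each, and records the window statistics. The table can be reused for
#' several observations ([abc_posterior()]) or as a hard/soft reference
#' set ([bayes_factor()]).
#'
#' @param n_draws number of prior draws.
#' @param config an [abc_config()].
#' @param theta_a optional fixed theta_A (point hypothesis) instead of the
#'   prior.
#' @param window_size SNP window for the statistics.
#' @return Data frame: `theta_a`, `s`, `pf`, `te`, `rho`, `h12`, `h2_h1`
#'   (`NA` statistics mark draws whose simulation failed to sweep).
#' @export
abc_reference_table <- function(n_draws, config, theta_a = NULL,
                                window_size = 400) {
  stopifnot(inherits(config, "abc_config"))
  ta <- if (is.null(theta_a)) runif(n_draws, 0, config$theta_a_max) else
    rep(theta_a, n_draws)
  s <- runif(n_draws, 0, config$s_max)
  pf <- runif(n_draws, 0, config$pf_max)
  pf[pf <= 0] <- .Machine$double.eps
  te <- runif(n_draws, 0, config$te_max)
  rho <- runif(n_draws, config$rho_bin[1], config$rho_bin[2])
  stats <- t(vapply(seq_len(n_draws), function(i)
    simulate_draw(config$model, ta[i], s[i], pf[i], te[i], rho[i],
                  window_size), numeric(2)))
  data.frame(theta_a = ta, s = s, pf = pf, te = te, rho = rho,
             h12 = stats[, 1], h2_h1 = stats[, 2])
}

abc_accept <- function(obs, tab, radius, rule = "distance",
                       var_h12 = NULL, var_h2h1 = NULL, target = NULL) {
  ok <- !is.na(tab$h12)
  if (rule == "relative") {
    acc <- ok & abs(tab$h12 - obs[1]) <= radius * obs[1] &
      abs(tab$h2_h1 - obs[2]) <= radius * obs[2]
    return(acc)
  }
  if (is.null(var_h12)) var_h12 <- var(tab$h12[ok])
  if (is.null(var_h2h1)) var_h2h1 <- var(tab$h2_h1[ok])
  # a component with zero spread contributes 0 where the simulation agrees
  # exactly with the observation and rejects otherwise (degenerate
  # simulators that echo the observation accept everything)
  comp <- function(diff, v) {
    if (isTRUE(v > 0)) return(diff^2 / v)
    ifelse(abs(diff) == 0, 0, Inf)
  }
  d <- sqrt(comp(obs[1] - tab$h12, var_h12) +
              comp(obs[2] - tab$h2_h1, var_h2h1))
  if (rule == "nearest") {
    acc <- rep(FALSE, nrow(tab))
    k <- min(target, sum(ok))
    acc[order(ifelse(ok, d, Inf))[seq_len(k)]] <- TRUE
    return(acc)
  }
  ok & d < radius
}

#' Sample the theta_A posterior by rejection ABC
#'
#' Simulates prior draws in batches until `config$target` draws are
#' accepted (normalised distance below `config$radius`, variances estimated
#' from all simulations of the run) or the simulation budget is exhausted.
#' A pre-computed [abc_reference_table()] can be supplied to skip
#' simulation.
#'
#' @param obs length-2 numeric `(h12, h2_h1)` observed at the candidate
#'   sweep.
#' @param config an [abc_config()].
#' @param table optional reference table to use instead of simulating.
#' @param window_size SNP window for simulated statistics.
#' @param batch simulation batch size.
#' @return An `abc_posterior`: `draws` (accepted parameter rows),
#'   `theta_a_map`, `ci` (2.5/97.5 percentiles), `acceptance_rate`,
#'   `n_sims`, `budget_exhausted`.
#' @export
abc_posterior <- function(obs, config, table = NULL, window_size = 400,
                          batch = 200) {
  stopifnot(inherits(config, "abc_config"), length(obs) == 2,
            all(obs >= 0), all(obs <= 1))
  fixed_table <- !is.null(table)
  if (!fixed_table) {
    # the nearest-draw rule uses the whole simulation budget up front
    n0 <- if (config$rule == "nearest") config$max_sims else
      min(batch, config$max_sims)
    table <- abc_reference_table(n0, config, window_size = window_size)
  }
  repeat {
    acc <- abc_accept(obs, table, config$radius, config$rule,
                      target = config$target)
    if (fixed_table || sum(acc) >= config$target ||
        nrow(table) >= config$max_sims) break
    more <- abc_reference_table(min(batch, config$max_sims - nrow(table)),
                                config, window_size = window_size)
    table <- rbind(table, more)
  }
  draws <- table[acc, , drop = FALSE]
  n_acc <- nrow(draws)
  rate <- n_acc / nrow(table)
  exhausted <- !fixed_table && n_acc < config$target
  if (exhausted && rate < 1e-5)
    stop("ABC acceptance rate below 1e-5 after ", nrow(table),
         " simulations; partial acceptances: ", n_acc)
  if (n_acc > config$target) draws <- draws[seq_len(config$target), ,
                                            drop = FALSE]
  est <- map_estimate(draws$theta_a, support = c(0, config$theta_a_max))
  structure(list(draws = draws, theta_a_map = est$map, ci = est$ci,
                 acceptance_rate = rate, n_sims = nrow(table),
                 budget_exhausted = exhausted), class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf(
    "<abc_posterior> theta_A MAP = %.2f, 95%% CI [%.2f, %.2f], %d draws (rate %.3g)\n",
    x$theta_a_map, x$ci[1], x$ci[2], nrow(x$draws), x$acceptance_rate))
  invisible(x)
}

#' MAP estimate and credible interval from posterior draws
#'
#' The MAP is the mode of a Gaussian kernel density estimate
#' (Silverman-rule bandwidth, 512-point grid on the prior support); the
#' credible interval is the empirical 2.5/97.5 percentile pair.
#'
#' @param draws accepted parameter values (>= 30).
#' @param support length-2 prior support for the density grid.
#' @return List with `map` and `ci`.
#' @export
map_estimate <- function(draws, support = c(0, 100)) {
  draws <- as.numeric(draws)
  if (length(draws) < 30) stop("need at least 30 draws for a MAP estimate")
  bw <- stats::bw.nrd0(draws)
  if (!isTRUE(bw > 0)) bw <- max(1e-8, stats::sd(draws), na.rm = TRUE)
  d <- stats::density(draws, bw = bw, n = 512, from = support[1],
                      to = support[2])
  list(map = d$x[which.max(d$y)],
       ci = unname(stats::quantile(draws, c(0.025, 0.975))))
}

#' Bayes factor for soft versus hard sweeps
#'
#' BF = (number of soft-sweep simulations within the acceptance radius of
#' the observation) / (number of hard-sweep simulations within it), with
#' distances normalised by variances pooled over both simulation sets.
#' A zero hard-sweep count with a non-zero soft count yields a flagged
#' lower bound (`bf = n_soft`, `bound = TRUE`); zero counts on both sides
#' yield `bf = NA` with `undefined = TRUE`.
#'
#' @param obs length-2 `(h12, h2_h1)`.
#' @param hard_sims,soft_sims data frames (or 2-column matrices) with
#'   columns `h12`, `h2_h1` simulated under the hard (theta_A = 0.01) and
#'   soft (e.g. theta_A = 10) point hypotheses.
#' @param radius acceptance radius (default 0.1).
#' @return List of class `bayes_factor`: `bf`, `n_soft`, `n_hard`,
#'   `bound`, `undefined`.
#' @export
bayes_factor <- function(obs, hard_sims, soft_sims, radius = 0.1) {
  hard_sims <- as.data.frame(hard_sims)
  soft_sims <- as.data.frame(soft_sims)
  if (!nrow(hard_sims) || !nrow(soft_sims))
    stop("both simulation sets must be non-empty")
  nm <- c("h12", "h2_h1")
  if (!all(nm %in% names(hard_sims))) names(hard_sims)[1:2] <- nm
  if (!all(nm %in% names(soft_sims))) names(soft_sims)[1:2] <- nm
  pool <- rbind(hard_sims[nm], soft_sims[nm])
  pool <- pool[!is.na(pool$h12), ]
  v1 <- var(pool$h12)
  v2 <- var(pool$h2_h1)
  if (!isTRUE(v1 > 0) || !isTRUE(v2 > 0))
    stop("zero pooled variance; cannot normalise distances")
  inside <- function(tab) {
    ok <- !is.na(tab$h12)
    d <- sqrt((obs[1] - tab$h12)^2 / v1 + (obs[2] - tab$h2_h1)^2 / v2)
    sum(ok & d < radius)
  }
  n_hard <- inside(hard_sims)
  n_soft <- inside(soft_sims)
  if (n_hard == 0 && n_soft == 0)
    return(structure(list(bf = NA_real_, n_soft = 0L, n_hard = 0L,
                          bound = FALSE, undefined = TRUE),
                     class = "bayes_factor"))
  if (n_hard == 0)
    return(structure(list(bf = as.numeric(n_soft), n_soft = n_soft,
                          n_hard = 0L, bound = TRUE, undefined = FALSE),
                     class = "bayes_factor"))
  structure(list(bf = n_soft / n_hard, n_soft = n_soft, n_hard = n_hard,
                 bound = FALSE, undefined = FALSE), class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  if (x$undefined) cat("<bayes_factor> undefined (no simulations in radius)\n")
  else cat(sprintf("<bayes_factor> BF %s %.3g (soft %d / hard %d)\n",
                   if (x$bound) ">=" else "=", x$bf, x$n_soft, x$n_hard))
  invisible(x)
}

#' Bayes-factor grid over (H12, H2/H1) space
#'
#' Evaluates [bayes_factor()] at the centres of a grid of (H12, H2/H1)
#' cells, reproducing the classification landscape in which high H12 with
#' low H2/H1 favours hard sweeps and high H2/H1 favours soft sweeps.
#'
#' @param hard_sims,soft_sims as in [bayes_factor()].
#' @param h12_breaks,h2h1_breaks cell boundaries on each axis.
#' @param radius acceptance radius.
#' @return Data frame: `h12`, `h2_h1` (cell centres), `bf`, `n_soft`,
#'   `n_hard`, `bound`, `undefined`.
#' @export
bf_grid <- function(hard_sims, soft_sims,
                    h12_breaks = seq(0, 1, by = 0.05),
                    h2h1_breaks = seq(0, 1, by = 0.05), radius = 0.1) {
  cx <- (utils::head(h12_breaks, -1) + utils::tail(h12_breaks, -1)) / 2
  cy <- (utils::head(h2h1_breaks, -1) + utils::tail(h2h1_breaks, -1)) / 2
  grid <- expand.grid(h12 = cx, h2_h1 = cy)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    b <- bayes_factor(c(grid$h12[i], grid$h2_h1[i]), hard_sims, soft_sims,
                      radius = radius)
    data.frame(h12 = grid$h12[i], h2_h1 = grid$h2_h1[i], bf = b$bf,
               n_soft = b$n_soft, n_hard = b$n_hard, bound = b$bound,
               undefined = b$undefined)
  })
  do.call(rbind, res)
}
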