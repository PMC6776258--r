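# Bayesian rate estimation: univariate slice sampling over the free
# rates with independent exponential priors.

#' MCMC configuration
#'
#' Two-phase scheme: an initial chain with a fixed slice width
#' (`initial_tuning`), after which each parameter's width is reset to the
#' width of the middle 90% (5th-95th percentile) of its initial posterior
#' samples, followed by the main chain.
#'
#' @param n_initial Generations of the tuning phase.
#' @param initial_tuning Slice width used in the tuning phase.
#' @param n_main Generations of the main chain.
#' @param prior_rate Rate of the exponential prior on every rate
#'   parameter; if `NULL`, computed as `1 / (2 r)` with `r` the net
#'   diversification rate of a character-independent constant-rate
#'   birth-death fit to the tree.
#' @param seed Integer seed.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_initial = 1000L, initial_tuning = 0.1,
                        n_main = 10000L, prior_rate = NULL, seed = 1L) {
  if (n_initial < 1L || n_main < 1L)
    stopf("generation counts must be >= 1")
  if (!is.null(prior_rate) && prior_rate <= 0)
    stopf("prior_rate must be positive")
  structure(list(n_initial = as.integer(n_initial),
                 initial_tuning = initial_tuning,
                 n_main = as.integer(n_main), prior_rate = prior_rate,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Character-independent net diversification rate
#'
#' Maximum-likelihood constant-rate birth-death fit (a single-state model
#' through the same likelihood machinery) returning `r = lambda - mu`.
#'
#' @param tree Binary `ape::phylo`.
#' @param f Global sampling fraction.
#' @return List: `lambda`, `mu`, `r`, `lnL`.
#' @export
bd_net_div_mle <- function(tree, f = 1) {
  spec <- make_model("bd", fractions = list(f0 = f, f1 = f),
                     root_state_policy = "given", root_weights = 1)
  st <- setNames(rep(0L, length(tree$tip.label)), tree$tip.label)
  fit <- fit_mle(spec, tree, st, n_starts = 5L, seed = 1L)
  list(lambda = unname(fit$rates$lambda), mu = unname(fit$rates$mu),
       r = unname(fit$ndiv), lnL = fit$lnL)
}

# one univariate slice-sampling update (Neal 2003, stepping out with a
# randomly split step budget + shrinkage) on coordinate j, support x > 0
slice_update <- function(par, j, w, logpost, ll0, max_steps = 30L) {
  y <- ll0 - rexp(1)
  u <- runif(1)
  L <- max(par[j] - w * u, 0)
  R <- L + w
  J <- floor(max_steps * runif(1))
  K <- max_steps - 1L - J
  pl <- par; pl[j] <- L
  while (J > 0 && L > 0 && logpost(pl) > y) {
    L <- max(L - w, 0)
    pl[j] <- L
    J <- J - 1L
  }
  pr <- par; pr[j] <- R
  while (K > 0 && logpost(pr) > y) {
    R <- R + w
    pr[j] <- R
    K <- K - 1L
  }
  repeat {
    x1 <- runif(1, L, R)
    p1 <- par; p1[j] <- x1
    l1 <- logpost(p1)
    if (l1 > y) return(list(par = p1, ll = l1))
    if (x1 < par[j]) L <- x1 else R <- x1
    if (R - L < 1e-300) return(list(par = par, ll = ll0))
  }
}

run_chain <- function(par, w, n_gen, logpost, ll) {
  k <- length(par)
  trace <- matrix(NA_real_, n_gen, k,
                  dimnames = list(NULL, names(par)))
  lls <- numeric(n_gen)
  for (g in seq_len(n_gen)) {
    for (j in seq_len(k)) {
      up <- slice_update(par, j, w[j], logpost, ll)
      par <- up$par
      ll <- up$ll
    }
    trace[g, ] <- par
    lls[g] <- ll
  }
  list(trace = trace, par = par, ll = ll, lls = lls)
}

#' Slice-sampling MCMC for SSE rate parameters
#'
#' Samples the free rates under independent exponential priors with rate
#' `1/(2r)` (r the character-independent net diversification rate of the
#' tree) using univariate slice sampling, with the two-phase tuning of
#' [mcmc_config()]. Summaries report posterior mean, sd, and the 2.5/97.5
#' percentile credible interval per parameter, plus per-state net
#' diversification.
#'
#' @inheritParams tree_loglik
#' @param config An [mcmc_config()].
#' @param init Starting parameter vector; defaults to the
#'   character-independent start of the MLE machinery.
#' @param prior_only Replace the likelihood by a constant (samples the
#'   prior; used to check sampler correctness).
#' @return List of class `sse_mcmc`: `trace` (n_main x k matrix),
#'   `summary` (data frame: parameter, mean, sd, lower, upper),
#'   `tuning` (per-parameter main-phase slice widths), `prior_rate`,
#'   `config`.
#' @export
mcmc_bisse <- function(spec, tree, tip_states, config = mcmc_config(),
                       init = NULL, prior_only = FALSE,
                       condition_surv = FALSE, rtol = default_rtol,
                       atol = default_atol) {
  stopifnot(inherits(spec, "sse_model_spec"),
            inherits(config, "mcmc_config"))
  prep <- tree_postorder(tree, tip_states, spec)
  prior_rate <- config$prior_rate
  if (is.null(prior_rate)) {
    r <- bd_net_div_mle(tree, f = mean(spec$f))$r
    if (r <= 0) r <- log(length(tree$tip.label)) /
        max(ape::node.depth.edgelength(tree))
    prior_rate <- 1 / (2 * r)
  }
  depth <- max(ape::node.depth.edgelength(tree))
  logpost <- function(par) {
    if (any(par < 0)) return(-Inf)
    lp <- sum(dexp(par, rate = prior_rate, log = TRUE))
    if (prior_only) return(lp)
    if (max(par) * depth > 1e4) return(-Inf)
    ll <- sse_loglik_call(prep, spec, par, condition_surv, rtol,
                          atol)$loglik
    lp + ll
  }
  par <- init %||% default_start(spec, tree)
  par <- pmax(par, 1e-6)
  names(par) <- spec$par_names
  ll <- logpost(par)
  if (!is.finite(ll))
    stopf("non-finite posterior at the starting point; supply init")
  with_seed(config$seed, {
    w0 <- rep(config$initial_tuning, spec$k)
    phase1 <- run_chain(par, w0, config$n_initial, logpost, ll)
    w <- apply(phase1$trace, 2, function(v)
      diff(quantile(v, c(0.05, 0.95), names = FALSE)))
    w[w < 1e-8] <- config$initial_tuning
    main <- run_chain(phase1$par, w, config$n_main, logpost, phase1$ll)
    tr <- main$trace
    summ <- data.frame(
      parameter = colnames(tr),
      mean = colMeans(tr),
      sd = apply(tr, 2, sd),
      lower = apply(tr, 2, quantile, 0.025, names = FALSE),
      upper = apply(tr, 2, quantile, 0.975, names = FALSE),
      row.names = NULL, stringsAsFactors = FALSE)
    # derived per-state net diversification
    div <- sapply(seq_along(spec$states), function(s)
      tr[, spec$lambda_class[s]] - tr[, spec$mu_class[s]])
    div <- matrix(div, nrow = nrow(tr))
    colnames(div) <- paste0("div", spec$states)
    dsum <- data.frame(
      parameter = colnames(div),
      mean = colMeans(div),
      sd = apply(div, 2, sd),
      lower = apply(div, 2, quantile, 0.025, names = FALSE),
      upper = apply(div, 2, quantile, 0.975, names = FALSE),
      row.names = NULL, stringsAsFactors = FALSE)
    structure(list(trace = tr, loglik = main$lls,
                   summary = rbind(summ, dsum), tuning = w,
                   prior_rate = prior_rate, config = config,
                   spec = spec),
              class = "sse_mcmc")
  })
}
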