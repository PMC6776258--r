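# Maximum-likelihood fitting and AIC comparison for the model family.

# crude data fingerprint so compare_models can refuse cross-data tables
data_fingerprint <- function(tree, tip_states) {
  st <- tip_states[tree$tip.label]
  sprintf("n%d|L%.10e|s%d|h%.10e",
          length(tree$tip.label), sum(tree$edge.length), sum(st),
          sum(tree$edge.length * seq_along(tree$edge.length)))
}

# character-independent starting guess: pure-birth rate log(n)/depth
default_start <- function(spec, tree) {
  depth <- max(ape::node.depth.edgelength(tree))
  lam <- log(length(tree$tip.label)) / max(depth, 1e-8)
  par <- numeric(spec$k)
  par[unique(spec$lambda_class)] <- lam
  par[unique(spec$mu_class)] <- lam / 2
  qcls <- unique(spec$q_class[spec$q_class > 0L])
  if (length(qcls)) par[qcls] <- lam / 10
  setNames(par, spec$par_names)
}

#' Fit an SSE model by maximum likelihood
#'
#' Multi-start box-constrained optimization of the free parameters on the
#' log scale (Nelder-Mead exploration polished by L-BFGS-B). Returns the
#' best run with AIC = 2k - 2 lnL, k the number of shared-parameter
#' classes.
#'
#' @inheritParams tree_loglik
#' @param n_starts Number of optimizer starts: the character-independent
#'   default start plus log-normal jitters of it.
#' @param seed Integer seed for the start jitters.
#' @param lower,upper Box bounds on the rates.
#' @return List of class `sse_fit`: family, `par` (free parameters),
#'   `rates` (per-state lambda/mu/Q), `ndiv` (per-state net
#'   diversification), `lnL`, `k`, `AIC`, `convergence`, `spec`,
#'   `data_id`.
#' @export
fit_mle <- function(spec, tree, tip_states, n_starts = 10L, seed = 1L,
                    condition_surv = FALSE, lower = 1e-8, upper = 1e3,
                    rtol = default_rtol, atol = default_atol) {
  stopifnot(inherits(spec, "sse_model_spec"))
  prep <- tree_postorder(tree, tip_states, spec)
  depth <- max(ape::node.depth.edgelength(tree))
  negll <- function(logpar) {
    par <- exp(logpar)
    # rates implying >> 1e4 expected events over the tree depth cannot
    # describe the data; skip the (stiff) integration outright
    if (any(!is.finite(par)) || max(par) * depth > 1e4) return(1e10)
    ll <- sse_loglik_call(prep, spec, par, condition_surv,
                          rtol, atol)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  base <- pmin(pmax(default_start(spec, tree), lower * 10), upper / 10)
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1L) log(base)
      else log(base) + stats::rnorm(spec$k, 0, 1)
    })
  })
  best <- NULL
  n_ok <- 0L
  for (s in starts) {
    fit <- tryCatch({
      if (!is.finite(negll(s)) || negll(s) >= 1e10) NULL
      else {
        nm <- optim(s, negll, method = "Nelder-Mead",
                    control = list(maxit = 400, reltol = 1e-8))
        lb <- tryCatch(
          optim(nm$par, negll, method = "L-BFGS-B",
                lower = log(lower), upper = log(upper),
                control = list(maxit = 100, factr = 1e7)),
          error = function(e) nm)
        if (lb$value <= nm$value) lb else nm
      }
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10)
      next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stopf("all %d optimizer starts failed for family '%s'",
          n_starts, spec$family)
  par <- setNames(exp(best$par), spec$par_names)
  rates <- spec_rates(spec, par)
  lnL <- -best$value
  out <- list(family = spec$family, par = par, rates = rates,
              ndiv = net_diversification(rates$lambda, rates$mu),
              lnL = lnL, k = spec$k, AIC = 2 * spec$k - 2 * lnL,
              convergence = best$convergence, n_starts_ok = n_ok,
              spec = spec,
              data_id = data_fingerprint(tree, tip_states))
  class(out) <- "sse_fit"
  out
}

#' @export
print.sse_fit <- function(x, ...) {
  cat(sprintf("SSE fit: %s  lnL = %.4f  k = %d  AIC = %.4f\n",
              x$family, x$lnL, x$k, x$AIC))
  print(round(rbind(lambda = x$rates$lambda, mu = x$rates$mu,
                    div = x$ndiv), 5))
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' @param fits List of `sse_fit` objects (or plain lists with `family`,
#'   `lnL`, `k`, `AIC`), all fitted to the same data.
#' @return Data frame sorted by AIC ascending with `dAIC` relative to the
#'   best model.
#' @export
compare_models <- function(fits) {
  if (!length(fits)) stopf("no fits to compare")
  ids <- unlist(lapply(fits, function(f) f$data_id %||% NA_character_))
  if (length(unique(ids[!is.na(ids)])) > 1L)
    stopf("fits were made on different data")
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$family, lnL = f$lnL, k = f$k, AIC = f$AIC,
               stringsAsFactors = FALSE)))
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  tab
}
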