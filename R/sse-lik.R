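# Pruning likelihood for state-dependent diversification models, plus
# marginal ancestral states and tip-averaged rates.

default_rtol <- 1e-8
default_atol <- 1e-10

#' Integrate the extinction/likelihood ODEs along one branch
#'
#' Propagates the per-state extinction probability E and likelihood
#' density D from the bottom to the top of a branch of length `dt` under
#' the model's rates, with an adaptive embedded Runge-Kutta scheme.
#'
#' @param spec An `sse_model_spec`.
#' @param par Free-parameter vector (see [spec_rates()]).
#' @param E0,D0 Per-state initial values at the branch bottom.
#' @param dt Branch length (time units of the tree).
#' @param rtol,atol Relative/absolute integration tolerances.
#' @return List with `E` and `D` at the branch top.
#' @export
branch_integrate <- function(spec, par, E0, D0, dt,
                             rtol = default_rtol, atol = default_atol) {
  if (dt < 0) stopf("dt must be non-negative")
  r <- spec_rates(spec, par)
  out <- sse_integrate_cpp(r$lambda, r$mu, r$Q, E0, D0, dt, rtol, atol)
  if (!out$ok) stopf("branch integration failed (dt = %g)", dt)
  list(E = setNames(out$E, spec$states),
       D = setNames(out$D, spec$states))
}

# postorder edge representation shared by the likelihood entry points
tree_postorder <- function(tree, tip_states, spec) {
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch lengths")
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    stopf("tree must be rooted and binary (no polytomies)")
  ntip <- length(tree$tip.label)
  st <- tip_states[tree$tip.label]
  if (anyNA(st)) stopf("every tip needs a state")
  if (!all(st %in% 0:1)) stopf("tip states must be 0/1")
  po <- ape::reorder.phylo(tree, "postorder")
  nstate <- length(spec$states)
  tipD <- matrix(0, ntip, nstate)
  for (i in seq_len(ntip))
    tipD[i, ] <- spec$f * as.numeric(spec$obs == st[i])
  list(edge = po$edge, edge_length = po$edge.length, ntip = ntip,
       tipD = tipD, tipE = 1 - spec$f, states = st)
}

sse_loglik_call <- function(prep, spec, par, condition_surv, rtol, atol,
                            constrain_node = 0L,
                            allowed = numeric(0)) {
  r <- spec_rates(spec, par)
  if (length(allowed) == 0L) allowed <- rep(1, length(spec$states))
  sse_loglik_cpp(prep$edge, prep$edge_length, prep$ntip, prep$tipD,
                 prep$tipE, r$lambda, r$mu, r$Q, spec$root_weights,
                 condition_surv, rtol, atol, as.integer(constrain_node),
                 allowed)
}

#' Log-likelihood of tip states on a tree under an SSE model
#'
#' Computes the pruning log-likelihood: tips are initialized with
#' `D = f * indicator(state compatible)` and `E = 1 - f`, branches are
#' integrated independently, daughters are combined with the speciation
#' rate at each node, and the root applies the spec's root-weight policy
#' (by default all mass on the hidden classes of observed state 0). No
#' survival conditioning unless requested.
#'
#' @inheritParams branch_integrate
#' @param tree Binary rooted `ape::phylo` with branch lengths.
#' @param tip_states Named 0/1 vector over the tip labels.
#' @param condition_surv Condition the likelihood on survival of the two
#'   root lineages.
#' @return The log-likelihood (scalar; `-Inf` when the likelihood
#'   underflows or integration fails).
#' @export
tree_loglik <- function(spec, tree, tip_states, par,
                        condition_surv = FALSE, rtol = default_rtol,
                        atol = default_atol) {
  prep <- tree_postorder(tree, tip_states, spec)
  out <- sse_loglik_call(prep, spec, par, condition_surv, rtol, atol)
  out$loglik
}

#' Marginal ancestral state probabilities
#'
#' For each internal node, the marginal probability of each observed
#' state (hidden classes summed out), computed by constraining the node
#' to each observed state in turn and renormalizing the resulting
#' likelihoods.
#'
#' @inheritParams tree_loglik
#' @return Matrix (internal nodes x observed states); rownames are ape
#'   node ids, columns `"0"` and `"1"` (or the single observed state for
#'   degenerate specs). Rows sum to 1.
#' @export
asr_marginal <- function(spec, tree, tip_states, par,
                         condition_surv = FALSE, rtol = default_rtol,
                         atol = default_atol) {
  prep <- tree_postorder(tree, tip_states, spec)
  ntip <- prep$ntip
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  obs_vals <- sort(unique(spec$obs))
  out <- matrix(NA_real_, length(nodes), length(obs_vals),
                dimnames = list(nodes, obs_vals))
  for (i in seq_along(nodes)) {
    ll <- vapply(obs_vals, function(v) {
      allowed <- as.numeric(spec$obs == v)
      sse_loglik_call(prep, spec, par, condition_surv, rtol, atol,
                      constrain_node = nodes[i], allowed = allowed)$loglik
    }, numeric(1))
    m <- max(ll)
    if (!is.finite(m)) stopf("non-finite likelihood at node %d",
                             nodes[i])
    p <- exp(ll - m)
    out[i, ] <- p / sum(p)
  }
  out
}

#' Tip-level hidden-class marginals and tip-averaged rates
#'
#' For each tip, the marginal probability of each hidden class given the
#' data (computed by constraining the tip to each compatible state), the
#' probability-weighted speciation, extinction, and net diversification
#' rate at that tip, and per-observed-state means across tips.
#'
#' @inheritParams tree_loglik
#' @return List: `tips` (data frame: tip, state, lambda, mu, div, one
#'   marginal column per model state), `by_state` (data frame of mean
#'   rates per observed state).
#' @export
tip_rate_average <- function(spec, tree, tip_states, par,
                             condition_surv = FALSE,
                             rtol = default_rtol, atol = default_atol) {
  prep <- tree_postorder(tree, tip_states, spec)
  ntip <- prep$ntip
  r <- spec_rates(spec, par)
  nstate <- length(spec$states)
  marg <- matrix(0, ntip, nstate,
                 dimnames = list(tree$tip.label, spec$states))
  for (i in seq_len(ntip)) {
    compat <- which(spec$obs == prep$states[i])
    if (length(compat) == 1L) {
      marg[i, compat] <- 1
      next
    }
    ll <- vapply(compat, function(s) {
      allowed <- as.numeric(seq_len(nstate) == s)
      sse_loglik_call(prep, spec, par, condition_surv, rtol, atol,
                      constrain_node = i, allowed = allowed)$loglik
    }, numeric(1))
    p <- exp(ll - max(ll))
    marg[i, compat] <- p / sum(p)
  }
  lam <- as.numeric(marg %*% r$lambda)
  mu <- as.numeric(marg %*% r$mu)
  tips <- data.frame(tip = tree$tip.label,
                     state = as.integer(prep$states),
                     lambda = lam, mu = mu,
                     div = net_diversification(lam, mu),
                     stringsAsFactors = FALSE)
  tips <- cbind(tips, as.data.frame(marg))
  by_state <- do.call(rbind, lapply(sort(unique(tips$state)),
                                    function(v) {
    sel <- tips$state == v
    data.frame(state = v, n_tips = sum(sel),
               lambda = mean(tips$lambda[sel]),
               mu = mean(tips$mu[sel]),
               div = mean(tips$div[sel]))
  }))
  list(tips = tips, by_state = by_state)
}
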