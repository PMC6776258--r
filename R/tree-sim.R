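# Forward (Gillespie) simulation of trees under state-dependent
# birth-death, for parameter-recovery and calibration experiments.
# Daughters inherit the parent's state at speciation; state changes are
# anagenetic (along branches) only.

#' Simulate a tree under a state-dependent birth-death model
#'
#' Event-driven simulation: with total rate summed over extant lineages,
#' waiting times are exponential; events are speciation, extinction, or a
#' state transition of a uniformly chosen lineage weighted by its rates.
#' Simulation starts from a single lineage in `root_state` and stops when
#' the extant lineage count reaches `target_tips` (simple stop-at-n) or
#' at `max_time`. Extinct lineages are pruned; incomplete sampling drops
#' each surviving tip independently with probability `1 - f(state)`.
#' Attempts leaving fewer than 2 tips are retried up to `max_tries`.
#'
#' @param spec An `sse_model_spec` carrying the true model structure and
#'   sampling fractions.
#' @param par True free-parameter vector (see [spec_rates()]).
#' @param target_tips Extant lineage count at which simulation stops.
#' @param root_state State the root lineage starts in (index into
#'   `spec$states`; default the first state with observed value 0).
#' @param max_time Optional time cap.
#' @param apply_sampling Apply the spec's sampling fractions post hoc.
#' @param seed Integer seed.
#' @param max_tries Retry cap for failed attempts.
#' @return List: `tree` (ape::phylo of the surviving sampled tips),
#'   `tip_states` (named 0/1 vector of observed states),
#'   `tip_model_states` (full state labels), `par`, `attempts`, and
#'   `events` (data frame: t, wait, total_rate, type).
#' @export
simulate_tree <- function(spec, par, target_tips = 100L,
                          root_state = NULL, max_time = Inf,
                          apply_sampling = TRUE, seed = 1L,
                          max_tries = 100L) {
  stopifnot(inherits(spec, "sse_model_spec"))
  if (target_tips < 2L) stopf("target_tips must be >= 2")
  r <- spec_rates(spec, par)
  nstate <- length(spec$states)
  qoff <- r$Q
  diag(qoff) <- 0
  if (is.null(root_state)) root_state <- which(spec$obs == 0L)[1]
  if (is.na(root_state)) root_state <- 1L
  with_seed(seed, {
    for (attempt in seq_len(max_tries)) {
      sim <- sim_attempt(spec, r, qoff, nstate, root_state,
                         target_tips, max_time)
      if (is.null(sim)) next
      res <- assemble_sim_tree(sim, spec, apply_sampling)
      if (!is.null(res)) {
        res$par <- par
        res$attempts <- attempt
        return(res)
      }
    }
    stopf("no attempt yielded >= 2 sampled tips in %d tries (rates %s)",
          max_tries, paste(signif(par, 3), collapse = ", "))
  })
}

sim_attempt <- function(spec, r, qoff, nstate, root_state, target_tips,
                        max_time) {
  # lineage arrays; children recorded for tree assembly
  state <- root_state
  parent <- 0L
  t_start <- 0
  t_end <- NA_real_
  status <- "alive"          # alive | split | dead
  alive <- 1L
  t <- 0
  ev_t <- ev_wait <- ev_rate <- numeric(0)
  ev_type <- character(0)
  lam <- r$lambda; mu <- r$mu
  qrow <- rowSums(qoff)
  repeat {
    n_alive <- length(alive)
    if (n_alive == 0L) return(NULL)
    if (n_alive >= target_tips) break
    tot_i <- lam[state[alive]] + mu[state[alive]] + qrow[state[alive]]
    Tot <- sum(tot_i)
    if (Tot <= 0) break                       # frozen: nothing can happen
    wait <- rexp(1, Tot)
    if (t + wait > max_time) { t <- max_time; break }
    t <- t + wait
    ev_t <- c(ev_t, t); ev_wait <- c(ev_wait, wait)
    ev_rate <- c(ev_rate, Tot)
    i <- alive[sample.int(n_alive, 1L, prob = tot_i)]
    s <- state[i]
    u <- runif(1) * (lam[s] + mu[s] + qrow[s])
    if (u < lam[s]) {
      ev_type <- c(ev_type, "speciation")
      status[i] <- "split"
      t_end[i] <- t
      for (d in 1:2) {
        state <- c(state, s); parent <- c(parent, i)
        t_start <- c(t_start, t); t_end <- c(t_end, NA_real_)
        status <- c(status, "alive")
      }
      alive <- c(setdiff(alive, i),
                 length(state) - 1L, length(state))
    } else if (u < lam[s] + mu[s]) {
      ev_type <- c(ev_type, "extinction")
      status[i] <- "dead"
      t_end[i] <- t
      alive <- setdiff(alive, i)
    } else {
      ev_type <- c(ev_type, "transition")
      w <- u - lam[s] - mu[s]
      state[i] <- which(w <= cumsum(qoff[s, ]))[1]
    }
  }
  t_end[is.na(t_end)] <- t
  list(state = state, parent = parent, t_start = t_start, t_end = t_end,
       status = status,
       events = data.frame(t = ev_t, wait = ev_wait,
                           total_rate = ev_rate, type = ev_type,
                           stringsAsFactors = FALSE))
}

assemble_sim_tree <- function(sim, spec, apply_sampling) {
  n <- length(sim$state)
  children <- split(seq_len(n), sim$parent)[-1]
  kids <- vector("list", n)
  kids[as.integer(names(children))] <- children
  len <- sim$t_end - sim$t_start
  lab <- paste0("t", seq_len(n))
  nw <- function(i) {
    if (is.null(kids[[i]]))
      sprintf("%s:%.10g", lab[i], len[i])
    else
      sprintf("(%s,%s)%s:%.10g", nw(kids[[i]][1]), nw(kids[[i]][2]),
              "", len[i])
  }
  extant <- which(sim$status == "alive")
  if (length(extant) < 2L) return(NULL)
  txt <- paste0(nw(1L), ";")
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) return(NULL)
  drop <- lab[sim$status == "dead"]
  if (length(drop)) {
    if (length(setdiff(tree$tip.label, drop)) < 2L) return(NULL)
    tree <- ape::drop.tip(tree, drop)
  }
  keep_states <- sim$state[match(tree$tip.label, lab)]
  if (apply_sampling) {
    f <- spec$f[keep_states]
    keep <- runif(length(f)) < f
    if (sum(keep) < 2L) return(NULL)
    tree <- ape::keep.tip(tree, tree$tip.label[keep])
    keep_states <- sim$state[match(tree$tip.label, lab)]
  }
  tree$root.edge <- NULL
  obs <- setNames(spec$obs[keep_states], tree$tip.label)
  list(tree = tree,
       tip_states = obs,
       tip_model_states = setNames(spec$states[keep_states],
                                   tree$tip.label),
       events = sim$events)
}

#' Parameter-recovery experiment
#'
#' Simulates `n_reps` trees under known rates, refits the model to each,
#' and tabulates per-parameter bias and root-mean-square error; with
#' `do_mcmc = TRUE`, also runs an MCMC per replicate and records whether
#' the true value falls inside the 95% credible interval.
#'
#' @param spec True (and fitted) model specification.
#' @param par True free-parameter vector.
#' @param n_reps Number of replicates.
#' @param n_tips Target extant tips per simulated tree.
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param n_starts Optimizer starts per fit.
#' @param do_mcmc Also run MCMC per replicate.
#' @param config `mcmc_config` used when `do_mcmc` is on.
#' @return List: `estimates` (replicate x parameter matrix of MLEs, NA
#'   for failed replicates), `summary` (parameter, truth, median, bias,
#'   rmse), `coverage` (per-parameter CI coverage when MCMC ran),
#'   `failures` (error messages per failed replicate).
#' @export
recovery_experiment <- function(spec, par, n_reps = 20L, n_tips = 300L,
                                seed = 1L, n_starts = 3L,
                                do_mcmc = FALSE,
                                config = mcmc_config(n_initial = 200L,
                                                     n_main = 1000L)) {
  if (n_reps < 1L) stopf("n_reps must be >= 1")
  est <- matrix(NA_real_, n_reps, spec$k,
                dimnames = list(NULL, spec$par_names))
  cov <- if (do_mcmc) est else NULL
  failures <- character(0)
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      sim <- simulate_tree(spec, par, target_tips = n_tips,
                           seed = derive_seed(seed, i))
      fit <- fit_mle(spec, sim$tree, sim$tip_states,
                     n_starts = n_starts, seed = derive_seed(seed, i))
      if (do_mcmc) {
        cfg <- config
        cfg$seed <- derive_seed(seed, 1000L + i)
        mc <- mcmc_bisse(spec, sim$tree, sim$tip_states, cfg,
                         init = fit$par)
        s <- mc$summary[seq_len(spec$k), ]
        cov[i, ] <- as.numeric(par >= s$lower & par <= s$upper)
      }
      est[i, ] <- fit$par
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) failures <- c(failures, sprintf("rep %d: %s",
                                                       i, res))
  }
  med <- apply(est, 2, stats::median, na.rm = TRUE)
  summary <- data.frame(parameter = spec$par_names, truth = par,
                        median = med, bias = med - par,
                        rmse = sqrt(colMeans((t(t(est) - par))^2,
                                             na.rm = TRUE)),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(estimates = est, summary = summary,
       coverage = if (do_mcmc) colMeans(cov, na.rm = TRUE) else NULL,
       failures = failures)
}
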