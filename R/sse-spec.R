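# Model specifications for the BiSSE/HiSSE family.
#
# A spec lists the model's states (observed 0/1, optionally split into
# hidden rate classes), assigns every speciation, extinction, and
# transition rate to a shared-parameter class (0 = fixed at zero), and
# records the root policy and per-state sampling fractions. Dual
# transitions -- simultaneous change of observed state and hidden class --
# are fixed to zero throughout the family.

sse_families <- function() {
  c("bisse_null", "bisse", "cid2", "cid4", "hisse_1hidden", "hisse_full")
}

# states differing in exactly one of (observed, hidden) may exchange
allowed_transition <- function(obs_i, hid_i, obs_j, hid_j) {
  (obs_i != obs_j) + (hid_i != hid_j) == 1L
}

#' Construct a state-dependent diversification model specification
#'
#' Families and their constraint patterns:
#' * `bisse_null`: two observed states, speciation and extinction shared
#'   across states, both transition rates free (k = 4).
#' * `bisse`: two observed states, all six rates free (k = 6).
#' * `cid2`: four states (0A, 1A, 0B, 1B); speciation and extinction tied
#'   across observed states within each hidden class (character-
#'   independent diversification); all allowed transitions share one rate
#'   (k = 5).
#' * `cid4`: eight states over hidden classes A-D, diversification tied
#'   across observed states within each class, all 32 allowed transitions
#'   equal (k = 9).
#' * `hisse_1hidden`: hidden class B attached to observed state 1 only
#'   (states 0A, 1A, 1B); all rates free (k = 10).
#' * `hisse_full`: four states, four speciation and four extinction rates,
#'   eight free transitions (twelve off-diagonals minus the four dual
#'   transitions) (k = 16).
#'
#' @param family One of `bisse_null`, `bisse`, `cid2`, `cid4`,
#'   `hisse_1hidden`, `hisse_full` (or `bd`, a single-state constant-rate
#'   birth-death model used for character-independent baselines).
#' @param fractions A `sampling_fractions` object, or a list/vector with
#'   `f0` and `f1` (probability that a species of each observed state is
#'   in the tree). Default complete sampling.
#' @param root_state_policy `"fixed0"` (probability mass spread equally
#'   over the hidden classes of observed state 0), `"equal"` (uniform
#'   over all states), or `"given"` (supply `root_weights`).
#' @param root_weights Numeric weights over states, for `"given"`.
#' @return List of class `sse_model_spec`.
#' @export
make_model <- function(family, fractions = list(f0 = 1, f1 = 1),
                       root_state_policy = c("fixed0", "equal", "given"),
                       root_weights = NULL) {
  root_state_policy <- match.arg(root_state_policy)
  if (family == "bd") {
    spec <- list(states = "0", obs = 0L, hidden = "A",
                 lambda_class = 1L, mu_class = 2L,
                 q_class = matrix(0L, 1, 1),
                 par_names = c("lambda", "mu"))
  } else if (family %in% c("bisse", "bisse_null")) {
    obs <- c(0L, 1L)
    hid <- c("A", "A")
    states <- c("0", "1")
    if (family == "bisse") {
      lc <- c(1L, 2L); mc <- c(3L, 4L)
      q <- matrix(0L, 2, 2); q[1, 2] <- 5L; q[2, 1] <- 6L
      pn <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")
    } else {
      lc <- c(1L, 1L); mc <- c(2L, 2L)
      q <- matrix(0L, 2, 2); q[1, 2] <- 3L; q[2, 1] <- 4L
      pn <- c("lambda", "mu", "q01", "q10")
    }
    spec <- list(states = states, obs = obs, hidden = hid,
                 lambda_class = lc, mu_class = mc, q_class = q,
                 par_names = pn)
  } else if (family %in% c("cid2", "hisse_full")) {
    states <- c("0A", "1A", "0B", "1B")
    obs <- c(0L, 1L, 0L, 1L)
    hid <- c("A", "A", "B", "B")
    n <- 4L
    q <- matrix(0L, n, n)
    if (family == "cid2") {
      lc <- c(1L, 1L, 2L, 2L); mc <- c(3L, 3L, 4L, 4L)
      for (i in seq_len(n)) for (j in seq_len(n))
        if (i != j && allowed_transition(obs[i], hid[i], obs[j], hid[j]))
          q[i, j] <- 5L
      pn <- c("lambdaA", "lambdaB", "muA", "muB", "q")
    } else {
      lc <- 1:4; mc <- 5:8
      qn <- character(0)
      nxt <- 9L
      for (i in seq_len(n)) for (j in seq_len(n))
        if (i != j && allowed_transition(obs[i], hid[i], obs[j],
                                         hid[j])) {
          q[i, j] <- nxt
          qn <- c(qn, paste0("q", states[i], states[j]))
          nxt <- nxt + 1L
        }
      pn <- c(paste0("lambda", states), paste0("mu", states), qn)
    }
    spec <- list(states = states, obs = obs, hidden = hid,
                 lambda_class = lc, mu_class = mc, q_class = q,
                 par_names = pn)
  } else if (family == "cid4") {
    hidc <- c("A", "B", "C", "D")
    states <- as.vector(t(outer(hidc, c("0", "1"),
                                function(h, o) paste0(o, h))))
    # order: 0A, 1A, 0B, 1B, 0C, 1C, 0D, 1D
    obs <- rep(c(0L, 1L), times = 4L)
    hid <- rep(hidc, each = 2L)
    n <- 8L
    lc <- rep(1:4, each = 2L)
    mc <- rep(5:8, each = 2L)
    q <- matrix(0L, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i != j && allowed_transition(obs[i], hid[i], obs[j], hid[j]))
        q[i, j] <- 9L
    pn <- c(paste0("lambda", hidc), paste0("mu", hidc), "q")
    spec <- list(states = states, obs = obs, hidden = hid,
                 lambda_class = lc, mu_class = mc, q_class = q,
                 par_names = pn)
  } else if (family == "hisse_1hidden") {
    states <- c("0A", "1A", "1B")
    obs <- c(0L, 1L, 1L)
    hid <- c("A", "A", "B")
    lc <- 1:3; mc <- 4:6
    q <- matrix(0L, 3, 3)
    q[1, 2] <- 7L   # 0A -> 1A
    q[2, 1] <- 8L   # 1A -> 0A
    q[2, 3] <- 9L   # 1A -> 1B
    q[3, 2] <- 10L  # 1B -> 1A
    pn <- c(paste0("lambda", states), paste0("mu", states),
            "q0A1A", "q1A0A", "q1A1B", "q1B1A")
    spec <- list(states = states, obs = obs, hidden = hid,
                 lambda_class = lc, mu_class = mc, q_class = q,
                 par_names = pn)
  } else {
    stopf("unknown model family '%s' (expected one of: %s, bd)",
          family, paste(sse_families(), collapse = ", "))
  }
  if (inherits(fractions, "sampling_fractions"))
    fractions <- list(f0 = fractions$f0, f1 = fractions$f1)
  f <- ifelse(spec$obs == 1L, fractions$f1 %||% 1, fractions$f0 %||% 1)
  if (any(f <= 0 | f > 1)) stopf("sampling fractions must be in (0, 1]")
  spec$f <- as.numeric(f)
  spec$family <- family
  spec$k <- max(c(spec$lambda_class, spec$mu_class, spec$q_class))
  spec$root_policy <- root_state_policy
  nst <- length(spec$states)
  w <- switch(root_state_policy,
              fixed0 = as.numeric(spec$obs == 0L),
              equal = rep(1, nst),
              given = {
                if (length(root_weights) != nst)
                  stopf("root_weights must have %d entries", nst)
                as.numeric(root_weights)
              })
  if (sum(w) <= 0) stopf("root weights sum to zero")
  spec$root_weights <- w / sum(w)
  class(spec) <- "sse_model_spec"
  spec
}

#' Expand a free-parameter vector into per-state rates
#'
#' @param spec An `sse_model_spec`.
#' @param par Numeric vector of length `spec$k` (one value per shared
#'   parameter class; all rates non-negative).
#' @return List: `lambda`, `mu` (per state), `Q` (transition matrix with
#'   diagonal set so rows sum to zero).
#' @export
spec_rates <- function(spec, par) {
  stopifnot(inherits(spec, "sse_model_spec"))
  if (length(par) != spec$k)
    stopf("expected %d free parameters, got %d", spec$k, length(par))
  if (any(par < 0)) stopf("rates must be non-negative")
  n <- length(spec$states)
  lambda <- par[spec$lambda_class]
  mu <- par[spec$mu_class]
  Q <- matrix(0, n, n, dimnames = list(spec$states, spec$states))
  nz <- which(spec$q_class > 0L, arr.ind = TRUE)
  if (nrow(nz)) Q[nz] <- par[spec$q_class[nz]]
  diag(Q) <- -rowSums(Q)
  list(lambda = setNames(lambda, spec$states),
       mu = setNames(mu, spec$states), Q = Q)
}

#' Net diversification rate
#'
#' Speciation minus extinction, elementwise over states.
#'
#' @param lambda,mu Numeric vectors of equal length.
#' @return `lambda - mu`.
#' @export
net_diversification <- function(lambda, mu) lambda - mu
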