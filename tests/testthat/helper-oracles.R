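# Independent oracles and fixture builders used across the suite.

# --- text-mining oracles -------------------------------------------------

# quadratic whole-token phrase scan, independent of the package matcher:
# tokenizes and slides a window of the phrase length over every document
oracle_tdm <- function(docs, ngrams) {
  text <- antmine::normalize_text(paste(docs$title, docs$abstract))
  toks <- strsplit(text, " ", fixed = TRUE)
  m <- matrix(0L, nrow(docs), length(ngrams),
              dimnames = list(docs$doc_id, ngrams))
  for (j in seq_along(ngrams)) {
    ng <- strsplit(ngrams[j], " ", fixed = TRUE)[[1]]
    w <- length(ng)
    for (i in seq_along(toks)) {
      tk <- toks[[i]]
      if (length(tk) < w) next
      for (s in seq_len(length(tk) - w + 1L)) {
        if (all(tk[s:(s + w - 1L)] == ng)) {
          m[i, j] <- 1L
          break
        }
      }
    }
  }
  m
}

# --- SSE oracles ---------------------------------------------------------

# independent pruning implementation: deSolve::lsoda at tight tolerance,
# written against the same E/D equations but sharing no code with the
# package's integrator
oracle_loglik <- function(spec, tree, tip_states, par,
                          constrain_node = 0L, allowed = NULL) {
  r <- antmine::spec_rates(spec, par)
  n <- length(spec$states)
  Q <- r$Q
  diag(Q) <- 0
  qrow <- rowSums(Q)
  deriv <- function(t, y, p) {
    E <- y[1:n]
    D <- y[(n + 1):(2 * n)]
    dE <- r$mu - (r$lambda + r$mu + qrow) * E + as.vector(Q %*% E) +
      r$lambda * E^2
    dD <- -(r$lambda + r$mu + qrow) * D + as.vector(Q %*% D) +
      2 * r$lambda * E * D
    list(c(dE, dD))
  }
  integrate_up <- function(E, D, len) {
    if (len == 0) return(list(E = E, D = D))
    out <- deSolve::lsoda(c(E, D), c(0, len), deriv, NULL,
                          rtol = 1e-11, atol = 1e-13)
    y <- out[2, -1]
    list(E = y[1:n], D = y[(n + 1):(2 * n)])
  }
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  st <- tip_states[tree$tip.label]
  Dn <- vector("list", ntip + tree$Nnode)
  En <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) {
    Dn[[i]] <- spec$f * as.numeric(spec$obs == st[i])
    En[[i]] <- 1 - spec$f
  }
  logcomp <- 0
  nch <- integer(ntip + tree$Nnode)
  for (e in seq_len(nrow(po$edge))) {
    par_n <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    D0 <- Dn[[ch]]
    if (ch == constrain_node) D0 <- D0 * allowed
    up <- integrate_up(En[[ch]], D0, po$edge.length[e])
    if (is.null(Dn[[par_n]])) {
      Dn[[par_n]] <- rep(1, n)
      En[[par_n]] <- rep(0, n)
    }
    s <- sum(up$D)
    Dn[[par_n]] <- Dn[[par_n]] * up$D / s
    logcomp <- logcomp + log(s)
    En[[par_n]] <- up$E
    nch[par_n] <- nch[par_n] + 1L
    if (nch[par_n] == 2L) {
      Dn[[par_n]] <- Dn[[par_n]] * r$lambda
      if (par_n == constrain_node) Dn[[par_n]] <- Dn[[par_n]] * allowed
      s2 <- sum(Dn[[par_n]])
      Dn[[par_n]] <- Dn[[par_n]] / s2
      logcomp <- logcomp + log(s2)
    }
  }
  root <- ntip + 1L
  log(sum(spec$root_weights * Dn[[root]])) + logcomp
}

# closed-form constant-rate birth-death log-likelihood on an ultrametric
# tree with sampling fraction rho, in the same normalization as the
# single-state pruning likelihood (root weight 1, no conditioning):
# along a branch ending at time t before present, D(t) = p1(t) with
# p1(t) = rho (la-mu)^2 e^{-(la-mu)t} / (rho la + (la(1-rho)-mu)
# e^{-(la-mu)t})^2, and every internal node contributes a factor la.
oracle_bd_loglik <- function(tree, lambda, mu, rho = 1) {
  p1 <- function(t) {
    ert <- exp(-(lambda - mu) * t)
    rho * (lambda - mu)^2 * ert /
      (rho * lambda + (lambda * (1 - rho) - mu) * ert)^2
  }
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)   # distance from root
  T <- max(depth)
  age <- T - depth                            # time before present
  ll <- (ntip - 1) * log(lambda)
  for (e in seq_len(nrow(tree$edge))) {
    a <- age[tree$edge[e, 2]]                 # tipward end
    b <- age[tree$edge[e, 1]]                 # rootward end
    ll <- ll + log(p1(b) / p1(a))
  }
  ll + ntip * log(rho)
}

# random binary ultrametric tree fixture
random_tree <- function(n, seed = 1) {
  set.seed(seed)
  ape::rcoal(n, tip.label = sprintf("sp%03d", seq_len(n)))
}
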