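test_that("branch integration matches analytic solutions", {
  # mu = 0, q = 0, one effective state: E stays 0, D decays as e^{-lambda t}
  spec <- make_model("bd", root_state_policy = "given",
                     root_weights = 1)
  out <- branch_integrate(spec, c(1, 0), E0 = 0, D0 = 1, dt = 2)
  expect_equal(unname(out$E), 0, tolerance = 1e-10)
  expect_equal(unname(out$D), exp(-2), tolerance = 1e-8)

  # all rates zero: identity map
  bs <- make_model("bisse")
  out0 <- branch_integrate(bs, rep(0, 6), E0 = c(0.3, 0.4),
                           D0 = c(0.5, 0.6), dt = 5)
  expect_equal(unname(out0$E), c(0.3, 0.4), tolerance = 1e-12)
  expect_equal(unname(out0$D), c(0.5, 0.6), tolerance = 1e-12)

  expect_error(branch_integrate(bs, rep(0, 6), c(0, 0), c(1, 1), -1),
               "non-negative")
})

test_that("branch integration agrees with a fine-tolerance lsoda oracle", {
  skip_if_not_installed("deSolve")
  spec <- make_model("bisse", fractions = list(f0 = 0.7, f1 = 0.9))
  set.seed(42)
  for (i in 1:5) {
    par <- runif(6, 0.01, 1)
    E0 <- runif(2, 0, 0.5)
    D0 <- runif(2, 0.1, 1)
    t <- runif(1, 0.1, 3)
    r <- spec_rates(spec, par)
    Q <- r$Q; diag(Q) <- 0; qrow <- rowSums(Q)
    deriv <- function(tt, y, p) {
      E <- y[1:2]; D <- y[3:4]
      list(c(r$mu - (r$lambda + r$mu + qrow) * E + as.vector(Q %*% E) +
               r$lambda * E^2,
             -(r$lambda + r$mu + qrow) * D + as.vector(Q %*% D) +
               2 * r$lambda * E * D))
    }
    oracle <- deSolve::lsoda(c(E0, D0), c(0, t), deriv, NULL,
                             rtol = 1e-12, atol = 1e-14)[2, -1]
    ours <- branch_integrate(spec, par, E0, D0, t)
    expect_equal(unname(c(ours$E, ours$D)), unname(oracle),
                 tolerance = 1e-7)
  }
})

test_that("the two-tip analytic likelihood is exact", {
  # both tips state 0, t = 1, lambda = 1, mu = q = 0, f = 1, root fixed
  # at 0: lnL = ln(lambda) - 2 lambda t = -2
  tree <- ape::read.tree(text = "(a:1,b:1);")
  spec <- make_model("bisse")
  ll <- tree_loglik(spec, tree, c(a = 0L, b = 0L), c(1, 1, 0, 0, 0, 0))
  expect_equal(ll, -2, tolerance = 1e-8)
})

test_that("tree likelihood matches the independent pruning oracle on small trees", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (n in c(4, 6)) {
    tree <- random_tree(n, seed = n)
    spec <- make_model("bisse", fractions = list(f0 = 0.8, f1 = 0.6))
    st <- setNames(sample(0:1, n, replace = TRUE), tree$tip.label)
    st[1] <- 0L; st[2] <- 1L  # both states present
    for (i in 1:3) {
      par <- runif(6, 0.02, 0.8)
      ll <- tree_loglik(spec, tree, st, par)
      expect_equal(ll, oracle_loglik(spec, tree, st, par),
                   tolerance = 1e-6)
    }
  }
})

test_that("hidden classes with identical rates collapse to the two-state model", {
  sim <- simulate_tree(make_model("bisse"),
                       c(0.2, 0.4, 0.05, 0.05, 0.05, 0.05),
                       target_tips = 40, seed = 5)
  par_b <- c(0.2, 0.4, 0.06, 0.03, 0.04, 0.08)
  ll_b <- tree_loglik(make_model("bisse"), sim$tree, sim$tip_states,
                      par_b)
  hs <- make_model("hisse_full")
  par_h <- setNames(numeric(16), hs$par_names)
  par_h[c("lambda0A", "lambda0B")] <- 0.2
  par_h[c("lambda1A", "lambda1B")] <- 0.4
  par_h[c("mu0A", "mu0B")] <- 0.06
  par_h[c("mu1A", "mu1B")] <- 0.03
  par_h[c("q0A1A", "q0B1B")] <- 0.04
  par_h[c("q1A0A", "q1B0B")] <- 0.08
  for (sw in c(0.001, 0.3, 2)) {  # any positive class-switch rate
    par_h[c("q0A0B", "q0B0A", "q1A1B", "q1B1A")] <- sw
    ll_h <- tree_loglik(hs, sim$tree, sim$tip_states, par_h)
    expect_equal(ll_h, ll_b, tolerance = 1e-6)
  }
})

test_that("relabeling the two states is a symmetry of the likelihood", {
  sim <- simulate_tree(make_model("bisse"),
                       c(0.2, 0.4, 0.05, 0.05, 0.05, 0.05),
                       target_tips = 30, seed = 9)
  par <- c(0.15, 0.45, 0.02, 0.08, 0.03, 0.09)
  spec01 <- make_model("bisse", fractions = list(f0 = 0.7, f1 = 0.4))
  ll1 <- tree_loglik(spec01, sim$tree, sim$tip_states, par)
  # swap states, rates, and fractions; root must follow the relabeling
  swapped <- setNames(1L - sim$tip_states, names(sim$tip_states))
  spec10 <- make_model("bisse", fractions = list(f0 = 0.4, f1 = 0.7),
                       root_state_policy = "given",
                       root_weights = c(0, 1))
  par_sw <- par[c(2, 1, 4, 3, 6, 5)]
  ll2 <- tree_loglik(spec10, sim$tree, swapped, par_sw)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("single-state likelihood equals the closed-form birth-death formula", {
  for (rho in c(1, 0.55)) {
    tree <- random_tree(12, seed = 31)
    spec <- make_model("bd", fractions = list(f0 = rho, f1 = rho),
                       root_state_policy = "given", root_weights = 1)
    st <- setNames(rep(0L, 12), tree$tip.label)
    for (rates in list(c(0.8, 0.3), c(0.5, 0.45), c(1.2, 0))) {
      ll <- tree_loglik(spec, tree, st, rates)
      expect_equal(ll, oracle_bd_loglik(tree, rates[1], rates[2], rho),
                   tolerance = 1e-6)
    }
  }
})

test_that("likelihood scaling leaves lnL invariant under time rescaling", {
  # multiplying branch lengths by c and dividing rates by c must leave
  # the likelihood's AIC ordering (and lnL up to n log c Jacobian-free
  # pruning normalization) consistent: D-products pick up no extra factor
  # beyond the lambda at nodes, so lnL changes by (ntip - 1) log(1/c)
  sim <- simulate_tree(make_model("bisse"),
                       c(0.2, 0.4, 0.05, 0.05, 0.05, 0.05),
                       target_tips = 25, seed = 13)
  spec <- make_model("bisse")
  par <- c(0.2, 0.4, 0.05, 0.02, 0.03, 0.06)
  ll <- tree_loglik(spec, sim$tree, sim$tip_states, par)
  scaled <- sim$tree
  scaled$edge.length <- scaled$edge.length * 10
  ll_s <- tree_loglik(spec, scaled, sim$tip_states, par / 10)
  ntip <- length(sim$tree$tip.label)
  expect_equal(ll_s, ll - (ntip - 1) * log(10), tolerance = 1e-6)
})

test_that("polytomies and missing states are rejected", {
  poly <- ape::read.tree(text = "(a:1,b:1,c:1);")
  spec <- make_model("bisse")
  expect_error(tree_loglik(spec, poly, c(a = 0L, b = 0L, c = 0L),
                           rep(0.1, 6)), "rooted and binary")
  tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  expect_error(tree_loglik(spec, tree, c(a = 0L, b = 1L),
                           rep(0.1, 6)), "state")
})

test_that("marginal ancestral states are proper probabilities with exact limits", {
  sim <- simulate_tree(make_model("bisse"),
                       c(0.3, 0.3, 0.05, 0.05, 0.1, 0.1),
                       target_tips = 12, seed = 3)
  spec <- make_model("bisse")
  par <- c(0.3, 0.3, 0.05, 0.05, 0.1, 0.1)
  asr <- asr_marginal(spec, sim$tree, sim$tip_states, par)
  expect_equal(unname(rowSums(asr)), rep(1, nrow(asr)),
               tolerance = 1e-9)
  # no transitions possible and all tips 0 -> every node certainly 0
  all0 <- setNames(rep(0L, length(sim$tip_states)),
                   names(sim$tip_states))
  asr0 <- asr_marginal(spec, sim$tree, all0,
                       c(0.3, 0.3, 0.05, 0.05, 0, 0))
  expect_equal(unname(asr0[, "0"]), rep(1, nrow(asr0)))
})

test_that("marginal reconstruction agrees with the independent oracle on 4 tips", {
  skip_if_not_installed("deSolve")
  tree <- random_tree(4, seed = 17)
  spec <- make_model("bisse", root_state_policy = "equal")
  st <- setNames(c(0L, 1L, 1L, 0L), tree$tip.label)
  par <- c(0.4, 0.6, 0.1, 0.2, 0.15, 0.25)
  asr <- asr_marginal(spec, tree, st, par)
  for (node in rownames(asr)) {
    ll <- vapply(0:1, function(v)
      oracle_loglik(spec, tree, st, par,
                    constrain_node = as.integer(node),
                    allowed = as.numeric(spec$obs == v)), numeric(1))
    p <- exp(ll - max(ll)); p <- p / sum(p)
    expect_equal(unname(asr[node, ]), p, tolerance = 1e-6)
  }
})

test_that("tip-averaged rates reduce to the common rate under identical classes", {
  sim <- simulate_tree(make_model("bisse"),
                       c(0.2, 0.4, 0.05, 0.05, 0.05, 0.05),
                       target_tips = 15, seed = 8)
  hs <- make_model("hisse_full")
  par_h <- setNames(numeric(16), hs$par_names)
  par_h[1:4] <- 0.35                       # all lambdas equal
  par_h[5:8] <- 0.1                        # all mus equal
  par_h[9:16] <- 0.05
  tr <- tip_rate_average(hs, sim$tree, sim$tip_states, par_h)
  expect_equal(tr$tips$lambda, rep(0.35, nrow(tr$tips)),
               tolerance = 1e-9)
  expect_equal(tr$tips$mu, rep(0.1, nrow(tr$tips)), tolerance = 1e-9)
  expect_equal(tr$tips$div, rep(0.25, nrow(tr$tips)), tolerance = 1e-9)
  # class marginals sum to one per tip
  marg <- as.matrix(tr$tips[, hs$states])
  expect_equal(unname(rowSums(marg)), rep(1, nrow(marg)),
               tolerance = 1e-9)
  # by-state summary covers every observed state present
  expect_setequal(tr$by_state$state, unique(sim$tip_states))
})

test_that("tip class marginals agree with the independent oracle on 4 tips", {
  skip_if_not_installed("deSolve")
  tree <- random_tree(4, seed = 27)
  hs <- make_model("hisse_full")
  st <- setNames(c(0L, 1L, 0L, 1L), tree$tip.label)
  set.seed(2)
  par <- setNames(runif(16, 0.05, 0.6), hs$par_names)
  tr <- tip_rate_average(hs, tree, st, par)
  for (i in 1:4) {
    compat <- which(hs$obs == st[tree$tip.label[i]])
    ll <- vapply(compat, function(s)
      oracle_loglik(hs, tree, st, par, constrain_node = i,
                    allowed = as.numeric(seq_along(hs$states) == s)),
      numeric(1))
    p <- exp(ll - max(ll)); p <- p / sum(p)
    expect_equal(unname(as.numeric(tr$tips[i, hs$states[compat]])), p,
                 tolerance = 1e-6)
  }
})

test_that("extinction probabilities behave like probabilities along a branch", {
  # complete sampling: E starts at 0 and is monotone non-decreasing
  spec <- make_model("bisse")
  par <- c(0.3, 0.5, 0.1, 0.2, 0.05, 0.05)
  prev <- c(0, 0)
  for (t in seq(0.5, 5, by = 0.5)) {
    out <- branch_integrate(spec, par, c(0, 0), c(1, 1), t)
    expect_true(all(out$E >= prev - 1e-9))
    expect_true(all(out$E >= 0 & out$E <= 1))
    prev <- out$E
  }
  # incomplete sampling: E starts at 1 - f and converges monotonically
  # (in one direction) to its equilibrium, staying a probability
  spec2 <- make_model("bisse", fractions = list(f0 = 0.5, f1 = 0.5))
  Es <- t(vapply(seq(0.25, 6, by = 0.25), function(t)
    branch_integrate(spec2, par, c(0.5, 0.5), c(1, 1), t)$E,
    numeric(2)))
  expect_true(all(Es >= 0 & Es <= 1))
  for (j in 1:2) {
    d <- diff(c(0.5, Es[, j]))
    expect_true(all(d >= -1e-9) || all(d <= 1e-9))
  }
})
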