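fake_traits <- function(species, p1 = 0.4, seed = 1) {
  set.seed(seed)
  tab <- data.frame(species = species,
                    domatia = 0L, efn = 0L, food_bodies = 0L,
                    seed_dispersal = rbinom(length(species), 1, p1))
  combine_categories(tab)
}

test_that("pruning keeps the tip/trait intersection and patristic distances", {
  tree <- random_tree(50, seed = 6)
  traits <- fake_traits(sample(tree$tip.label, 30), seed = 2)
  pr <- prune_to_traits(tree, traits)
  expect_setequal(pr$tree$tip.label,
                  intersect(tree$tip.label, traits$species))
  # patristic distances among survivors unchanged
  d_full <- ape::cophenetic.phylo(tree)
  d_sub <- ape::cophenetic.phylo(pr$tree)
  keep <- pr$tree$tip.label
  expect_equal(d_sub[keep, keep], d_full[keep, keep],
               tolerance = 1e-10)
  expect_equal(pr$n_state0 + pr$n_state1, length(keep))
  expect_equal(unname(pr$tip_states[keep[3]]),
               traits$seed_dispersal[traits$species == keep[3]],
               ignore_attr = TRUE)

  # traits covering every tip leave the tree unchanged
  all_tr <- fake_traits(tree$tip.label)
  expect_equal(prune_to_traits(tree, all_tr)$tree$tip.label,
               tree$tip.label)

  expect_error(prune_to_traits(tree, fake_traits("no such species")),
               "fewer than 2")
})

test_that("pruned trees round-trip through Newick", {
  tree <- random_tree(20, seed = 3)
  tree$tip.label <- sub("sp", "genus species", tree$tip.label)
  traits <- fake_traits(sample(tree$tip.label, 12), seed = 4)
  pr <- prune_to_traits(tree, traits)
  f <- tempfile(fileext = ".nwk")
  write_newick(pr$tree, f)
  back <- read_newick(f)
  expect_setequal(back$tip.label, pr$tree$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[pr$tree$tip.label,
                                           pr$tree$tip.label],
               ape::cophenetic.phylo(pr$tree)[pr$tree$tip.label,
                                              pr$tree$tip.label],
               tolerance = 1e-9)
  unlink(f)
})

test_that("state totals scale the dataset proportion to described species", {
  est <- estimate_state_totals(432, 3341, 14416)
  expect_equal(est$N1, 1864)
  expect_equal(est$N0, 12552)
  expect_equal(est$N1 + est$N0, 14416)

  expect_equal(estimate_state_totals(10, 10, 300), list(N1 = 300L,
                                                        N0 = 0L))
  expect_equal(estimate_state_totals(1, 2, 10), list(N1 = 5L, N0 = 5L))
  # conservation holds across random inputs
  set.seed(8)
  for (i in 1:20) {
    n_tot <- sample(50:5000, 1)
    n1 <- sample(n_tot, 1)
    nd <- sample(1000:20000, 1)
    est <- estimate_state_totals(n1, n_tot, nd)
    expect_equal(est$N1 + est$N0, nd)
  }
  expect_error(estimate_state_totals(0, 10, 5), "n_state1")
  expect_error(estimate_state_totals(5, 0, 5), "positive")
})

test_that("sampling fractions divide tips by estimated totals", {
  tips <- c(rep(0L, 600), rep(1L, 195))
  names(tips) <- sprintf("s%03d", seq_along(tips))
  fr <- state_sampling_fractions(tips, N1 = 1864, N0 = 12552)
  expect_equal(fr$f0, 600 / 12552, tolerance = 1e-12)
  expect_equal(fr$f1, 195 / 1864, tolerance = 1e-12)
  expect_equal(round(fr$f0, 5), 0.0478)
  expect_equal(round(fr$f1, 5), 0.10461)

  gl <- state_sampling_fractions(tips, N1 = 1864, N0 = 12552,
                                 mode = "global")
  expect_equal(gl$f0, 795 / 14416, tolerance = 1e-12)
  expect_equal(gl$f1, gl$f0)
  expect_equal(gl$f0, 0.05515, tolerance = 2e-4)

  full <- state_sampling_fractions(c(a = 0L, b = 1L), N1 = 1, N0 = 1)
  expect_equal(full$f0, 1)
  expect_equal(full$f1, 1)

  expect_error(state_sampling_fractions(tips, N1 = 100, N0 = 12552),
               "exceeds 1")
})

test_that("per-genus fractions agree with an independent group-by", {
  tree <- random_tree(40, seed = 12)
  genera <- sprintf("gen%02d", rep(1:8, each = 5))
  tree$tip.label <- paste(genera, sprintf("sp%02d", 1:40))
  set.seed(5)
  totals <- data.frame(genus = unique(genera),
                       n_described = sample(5:30, 8))
  gf <- genus_sampling_fractions(tree, totals)
  # independent recount
  cnt <- table(vapply(strsplit(tree$tip.label, " "), `[[`,
                      character(1), 1))
  for (g in names(cnt)) {
    expect_equal(gf$n_in_tree[gf$genus == g], unname(as.integer(cnt[g])))
    expect_equal(gf$fraction[gf$genus == g],
                 as.integer(cnt[g]) /
                   totals$n_described[totals$genus == g])
  }
  expect_true(all(gf$fraction > 0 & gf$fraction <= 1))
  expect_equal(gf$fraction[gf$n_in_tree == gf$n_described],
               rep(1, sum(gf$n_in_tree == gf$n_described)))

  expect_error(genus_sampling_fractions(tree, totals[-1, ]),
               "gen01")
})
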