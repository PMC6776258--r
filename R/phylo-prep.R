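# Phylogeny preparation: pruning to trait coverage and sampling-fraction
# arithmetic for the diversification models.

#' Read / write Newick trees
#'
#' Thin wrappers over `ape` that optionally map underscores in tip labels
#' to spaces on read (the usual convention for binomials in Newick) and
#' back on write.
#'
#' @param file Path to a Newick file.
#' @param underscores_to_spaces Translate `_` to a space in tip labels.
#' @return `read_newick`: an `ape::phylo`; `write_newick`: the file path,
#'   invisibly.
#' @export
read_newick <- function(file, underscores_to_spaces = TRUE) {
  tree <- ape::read.tree(file)
  if (underscores_to_spaces)
    tree$tip.label <- gsub("_", " ", tree$tip.label, fixed = TRUE)
  tree
}

#' @rdname read_newick
#' @param tree An `ape::phylo`.
#' @export
write_newick <- function(tree, file, underscores_to_spaces = TRUE) {
  if (underscores_to_spaces)
    tree$tip.label <- gsub(" ", "_", tree$tip.label, fixed = TRUE)
  ape::write.tree(tree, file)
  invisible(file)
}

#' Prune a tree to the species with trait data
#'
#' Keeps exactly the intersection of the tree's tips and the trait
#' table's species (degree-2 nodes are suppressed by `ape`, so patristic
#' distances among surviving tips are unchanged) and returns the binary
#' tip states for the requested category aligned to the pruned tree.
#'
#' @param tree An `ape::phylo`.
#' @param traits A `trait_table` (or any data frame with a `species`
#'   column and the category column).
#' @param category Column of `traits` holding the 0/1 states.
#' @return List: `tree` (pruned), `tip_states` (named 0/1 integer vector
#'   over the pruned tips), `n_state0`, `n_state1`.
#' @export
prune_to_traits <- function(tree, traits, category = "mutualist") {
  if (!category %in% names(traits))
    stopf("trait table has no column '%s'", category)
  keep <- intersect(tree$tip.label, traits$species)
  if (length(keep) < 2L)
    stopf("fewer than 2 tips have trait data (%d)", length(keep))
  pruned <- ape::keep.tip(tree, keep)
  st <- traits[[category]][match(pruned$tip.label, traits$species)]
  st <- as.integer(st)
  if (!all(st %in% 0:1)) stopf("tip states must be binary")
  names(st) <- pruned$tip.label
  list(tree = pruned, tip_states = st,
       n_state0 = sum(st == 0L), n_state1 = sum(st == 1L))
}

#' Estimate described-species totals per state
#'
#' Scales the state-1 proportion observed in the trait dataset up to the
#' total number of described species: `N1 = round(n1/n_total * N)`,
#' `N0 = N - N1` (subtraction, so the described total is conserved).
#'
#' @param n_state1_dataset Species scored state 1 in the trait dataset.
#' @param n_total_dataset Total species in the trait dataset.
#' @param n_described Total described species in the group.
#' @return List with `N1` and `N0`.
#' @export
estimate_state_totals <- function(n_state1_dataset, n_total_dataset,
                                  n_described) {
  if (n_total_dataset <= 0 || n_described <= 0)
    stopf("totals must be positive")
  if (n_state1_dataset <= 0 || n_state1_dataset > n_total_dataset)
    stopf("need 0 < n_state1_dataset <= n_total_dataset")
  N1 <- round(n_state1_dataset / n_total_dataset * n_described)
  list(N1 = as.integer(N1), N0 = as.integer(n_described - N1))
}

#' State-specific (or global) sampling fractions
#'
#' `f1` is the number of state-1 tips over the estimated total number of
#' state-1 species, and likewise `f0`; in global mode both equal total
#' tips over total described species.
#'
#' @param tip_states Named 0/1 vector (as from [prune_to_traits()]).
#' @param N1,N0 Estimated species totals per state (see
#'   [estimate_state_totals()]).
#' @param mode `"state_specific"` or `"global"`.
#' @return List of class `sampling_fractions`: `f0`, `f1`, `mode`.
#' @export
state_sampling_fractions <- function(tip_states, N1, N0,
                                     mode = c("state_specific",
                                              "global")) {
  mode <- match.arg(mode)
  n1 <- sum(tip_states == 1L)
  n0 <- sum(tip_states == 0L)
  if (mode == "global") {
    f <- (n0 + n1) / (N0 + N1)
    out <- list(f0 = f, f1 = f, mode = mode)
  } else {
    out <- list(f0 = n0 / N0, f1 = n1 / N1, mode = mode)
  }
  if (out$f0 > 1 || out$f1 > 1)
    stopf("sampling fraction exceeds 1; totals inconsistent with tips")
  if (out$f0 <= 0 || out$f1 <= 0)
    stopf("each state needs at least one sampled tip")
  class(out) <- "sampling_fractions"
  out
}

#' Per-genus sampling fractions
#'
#' Number of tips of each genus in the tree over the described species
#' count of the genus (the clade-wise missing-data proportions used by
#' rate-shift analyses).
#'
#' @param tree An `ape::phylo` with binomial tip labels.
#' @param genus_totals Data frame (genus, n_described) or named vector.
#' @return Data frame: genus, n_in_tree, n_described, fraction.
#' @export
genus_sampling_fractions <- function(tree, genus_totals) {
  if (is.data.frame(genus_totals))
    genus_totals <- setNames(genus_totals$n_described,
                             genus_totals$genus)
  genus <- vapply(strsplit(tree$tip.label, "[ _]"), `[[`, character(1),
                  1L)
  tab <- table(genus)
  missing <- setdiff(names(tab), names(genus_totals))
  if (length(missing))
    stopf("no described-species total for genus: %s",
          paste(missing, collapse = ", "))
  out <- data.frame(genus = names(tab),
                    n_in_tree = as.integer(tab),
                    n_described = as.integer(
                      genus_totals[names(tab)]),
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_in_tree / out$n_described
  if (any(out$fraction > 1 | out$fraction <= 0))
    stopf("per-genus fractions must lie in (0, 1]")
  out
}
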