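#!/usr/bin/env Rscript
# Generate the synthetic study system: a phylogeny whose tips diversified
# under mutualism-dependent rates, and a literature corpus whose planted
# species-trait associations agree with the tip states. Writes everything
# later stages read under results/data/.
#
# The tree has 200 tips; the species dictionary has 500 binomials, so
# (as in real corpora) most trait-scored species are not in the tree.

suppressPackageStartupMessages(library(antmine))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20160401L

## 1. dictionary ---------------------------------------------------------
cfg <- corpus_config(n_species = 500, n_genera = 60, n_docs = 2500,
                     mention_rate = 2.5, trait_doc_rate = 1.5,
                     false_cooccurrence_rate = 0.04,
                     duplicate_fraction = 0.15, seed = seed)
dict <- gen_dictionary(cfg)

## 2. phylogeny: BiSSE with faster speciation for mutualists -------------
# lambda1 > lambda0 plants a detectable mutualism effect; q10 >> q01
# keeps mutualists a minority of tips, as in mined data
truth_rates <- c(lambda0 = 0.10, lambda1 = 0.25, mu0 = 0.03,
                 mu1 = 0.03, q01 = 0.01, q10 = 0.12)
spec <- make_model("bisse")
sim <- simulate_tree(spec, truth_rates, target_tips = 200, seed = seed)
tree <- sim$tree
set.seed(seed + 1)
tree$tip.label <- sample(dict$species, length(tree$tip.label))
tip_state <- setNames(as.integer(sim$tip_states), tree$tip.label)

## 3. per-category true states consistent with the tip states ------------
# mutualists practice >= 1 category; seed dispersal is the most common,
# food bodies the rarest (their relative frequencies mirror mined data)
cats <- trait_categories()
p_cat <- c(domatia = 0.18, efn = 0.30, food_bodies = 0.06,
           seed_dispersal = 0.65)
states <- matrix(0L, nrow(dict), 4, dimnames = list(dict$species, cats))
mut <- logical(nrow(dict))
mut[match(names(tip_state), dict$species)] <- tip_state == 1L
off_tree <- !dict$species %in% names(tip_state)
mut[off_tree] <- runif(sum(off_tree)) < 0.13   # background prevalence
for (sp in dict$species[mut]) {
  picks <- runif(4) < p_cat
  if (!any(picks)) picks[sample.int(4, 1, prob = p_cat)] <- TRUE
  states[sp, ] <- as.integer(picks)
}

## 4. corpus with planted truth, noise, and duplicates -------------------
cp <- gen_corpus(cfg, dictionary = dict, states = states)
write_corpus(cp$docs, file.path(out, "corpus.jsonl"))
write_dictionary(dict, file.path(out, "dictionary.txt"))
write_lexicon(cp$lexicon, file.path(out, "lexicon.yaml"))
write_newick(tree, file.path(out, "tree.nwk"))
write.csv(cp$truth$states, file.path(out, "ground_truth_states.csv"),
          row.names = FALSE)
write.csv(cp$truth$plantings, file.path(out, "ground_truth_plantings.csv"),
          row.names = FALSE)
write.csv(data.frame(species = names(tip_state), state = tip_state),
          file.path(out, "true_tip_states.csv"), row.names = FALSE)
write.csv(data.frame(parameter = names(truth_rates),
                     value = truth_rates),
          file.path(out, "true_rates.csv"), row.names = FALSE)

## 5. hand-compiled seed-disperser list ----------------------------------
hand <- gen_hand_list(cp$truth, "seed_dispersal", coverage = 0.45,
                      extra = 25, seed = seed + 2)
write.csv(hand, file.path(out, "hand_list_seed_dispersal.csv"),
          row.names = FALSE)

n_fp <- sum(cp$truth$plantings$truth == "false")
cat(sprintf(paste0(
  "study system written to %s\n",
  "  tree tips: %d (mutualists: %d)\n",
  "  dictionary: %d species, corpus: %d documents (%d unique)\n",
  "  true mutualists in dictionary: %d; planted false pairs: %d\n",
  "  hand list: %d species (%d outside the corpus)\n"),
  out, length(tip_state), sum(tip_state), nrow(dict), nrow(cp$docs),
  cfg$n_docs, sum(rowSums(states) > 0), n_fp, nrow(hand),
  sum(!hand$in_corpus)))
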