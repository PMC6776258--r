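#!/usr/bin/env Rscript
# Validation of the mined trait data: species accumulation curves per
# category, false-positive audit by co-occurrence count, and the
# comparison of text-mined versus hand-compiled seed dispersers.
# Writes results/validation/.

suppressPackageStartupMessages(library(antmine))

data_dir <- "results/data"
mine_dir <- "results/mining"
out <- "results/validation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

docs <- dedup_corpus(read_corpus(file.path(data_dir, "corpus.jsonl")))
dict <- read_dictionary(file.path(data_dir, "dictionary.txt"))
lex <- read_lexicon(file.path(data_dir, "lexicon.yaml"))
m <- build_term_document_matrix(docs, dict, lex)
tally <- tally_cooccurrence(m, lex)
truth_states <- read.csv(file.path(data_dir, "ground_truth_states.csv"))

## accumulation curves: the four categories, any-mutualism, and the
## non-mutualist curve (species never seen with a trait term)
curves <- do.call(rbind, lapply(
  c(trait_categories(), "mutualist", "none"), function(cc)
    accumulation_curve(m, lex, cc, n_resamples = 100, seed = 99)))
write.csv(curves, file.path(out, "accumulation_curves.csv"),
          row.names = FALSE)
ends <- curves[curves$x == nrow(m), c("category", "mean_species")]
cat("species detected at the full corpus, by curve:\n")
print(ends, row.names = FALSE)

## false-positive audit against generator truth
truth <- structure(list(states = truth_states),
                   class = "ant_ground_truth")
audit <- false_positive_audit(tally, truth, k_max = 5)
write.csv(audit, file.path(out, "fp_audit.csv"), row.names = FALSE)
cat("\nfalse-positive rate by co-occurrence count:\n")
print(audit, row.names = FALSE)
cat(sprintf("fp rate declines monotonically: %s\n",
            attr(audit, "monotone_nonincreasing")))

## text-mined vs hand-compiled seed dispersers
traits_cor <- read_trait_table(file.path(mine_dir,
                                         "traits_corrected.csv"))
hand <- read_hand_list(file.path(data_dir,
                                 "hand_list_seed_dispersal.csv"))
mined_sd <- traits_cor$species[traits_cor$seed_dispersal == 1]
cmp <- compare_datasets(mined_sd, hand$species)
jsonlite::write_json(unclass(cmp), file.path(out, "comparison.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf(paste0(
  "\nseed dispersers: %d text-mined (%d genera), %d hand-compiled ",
  "(%d genera)\n  %d shared; %d mining-only; %d hand-only\n"),
  cmp$n_a, cmp$genus$n_a, cmp$n_b, cmp$genus$n_b, cmp$n_overlap,
  cmp$n_a_only, cmp$n_b_only))
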