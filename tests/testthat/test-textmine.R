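test_that("normalization folds case and punctuation and is idempotent", {
  expect_equal(normalize_text("Atta  cephalotes,"), "atta cephalotes")
  expect_equal(normalize_text(""), "")
  set.seed(1)
  rand <- vapply(1:20, function(i)
    paste(sample(c(LETTERS, letters, c(".", ",", ";", "-", "  ")),
                 30, replace = TRUE), collapse = ""), character(1))
  expect_equal(normalize_text(normalize_text(rand)),
               normalize_text(rand))
})

test_that("jittered duplicates normalize to identical text and dedup removes them", {
  cfg <- corpus_config(n_species = 15, n_genera = 3, n_docs = 80,
                       duplicate_fraction = 0.3, seed = 21)
  cp <- gen_corpus(cfg)
  dup <- cp$truth$duplicates
  txt <- antmine:::doc_text(cp$docs)
  names(txt) <- cp$docs$doc_id
  expect_true(all(txt[dup$doc_id] == txt[dup$dup_of]))

  dd <- dedup_corpus(cp$docs)
  expect_equal(nrow(dd), 80)
  expect_identical(dedup_corpus(dd), dd)

  # exact duplicates too
  docs <- data.frame(doc_id = c("a", "b", "c"),
                     title = c("x", "x", "y"),
                     abstract = c("z", "z", "w"))
  expect_equal(nrow(dedup_corpus(docs)), 2)
  expect_equal(dedup_corpus(docs)$doc_id, c("a", "c"))
})

test_that("term-document matrix equals the brute-force scan oracle", {
  cfg <- corpus_config(n_species = 25, n_genera = 5, n_docs = 120,
                       false_cooccurrence_rate = 0.15, seed = 13)
  cp <- gen_corpus(cfg)
  m <- build_term_document_matrix(cp$docs, cp$dictionary, cp$lexicon)
  o <- oracle_tdm(cp$docs, colnames(m))
  expect_equal(unname(m[, ]), unname(o))
  expect_true(all(m %in% 0:1))
})

test_that("matching is exact whole-token phrase matching", {
  docs <- data.frame(
    doc_id = c("d1", "d2", "d3"),
    title = c("", "", ""),
    abstract = c("the seeds bear elaiosomes here",
                 "atta cephalotes disperses seeds",
                 "myrmecochorousness is not a word match"))
  lex <- list(domatia = "domatia", efn = "efn",
              food_bodies = "food body",
              seed_dispersal = c("elaiosome", "elaiosomes",
                                 "myrmecochorous"))
  m <- build_term_document_matrix(docs, "atta cephalotes", lex)
  expect_equal(m["d1", "elaiosome"], 0L)    # no stemming
  expect_equal(m["d1", "elaiosomes"], 1L)
  expect_equal(m["d2", "atta cephalotes"], 1L)
  expect_equal(m["d3", "myrmecochorous"], 0L)  # substring is not a token

  expect_error(
    build_term_document_matrix(docs, "food body", lex), "overlap")
})

test_that("co-occurrence tally matches a brute-force recount", {
  cfg <- corpus_config(n_species = 20, n_genera = 4, n_docs = 100,
                       false_cooccurrence_rate = 0.1, seed = 17)
  cp <- gen_corpus(cfg)
  m <- build_term_document_matrix(cp$docs, cp$dictionary, cp$lexicon)
  tally <- tally_cooccurrence(m, cp$lexicon)
  term_cat <- attr(m, "term_category")
  for (r in seq_len(nrow(tally$pairs))) {
    s <- tally$pairs$species[r]
    cc <- tally$pairs$category[r]
    terms <- names(term_cat)[term_cat == cc]
    both <- m[, s] == 1L &
      rowSums(m[, terms, drop = FALSE]) > 0L
    expect_equal(tally$pairs$n_docs[r], sum(both))
    expect_setequal(antmine:::split_doc_ids(tally$pairs$doc_ids[r]),
                    rownames(m)[both])
  }
  # species never in any doc are absent
  expect_true(all(tally$species$n_docs_total >= 1))
})

test_that("trait scoring follows the presence/absence rule with overlay correction", {
  # one co-occurring doc marked false-positive, two species-only docs
  docs <- data.frame(
    doc_id = c("d1", "d2", "d3"),
    title = "",
    abstract = c("zelkora fandor visits the domatia",
                 "zelkora fandor in the forest",
                 "zelkora fandor was observed"))
  lex <- list(domatia = "domatia", efn = "efn zzz",
              food_bodies = "food body", seed_dispersal = "elaiosome")
  m <- build_term_document_matrix(docs, "zelkora fandor", lex)
  tally <- tally_cooccurrence(m, lex)
  t_raw <- score_traits(tally)
  expect_equal(t_raw$domatia, 1L)
  ov <- data.frame(species = "zelkora fandor", category = "domatia",
                   doc_id = "d1", verdict = "false-positive")
  t_cor <- score_traits(tally, overlay = ov)
  expect_equal(t_cor$domatia, 0L)     # false positive removed -> absence
  expect_equal(t_cor$mutualist, 0L)
  expect_equal(t_cor$n_docs_total, 3L)

  # 5 co-occurring docs, no overlay -> presence
  docs5 <- data.frame(doc_id = paste0("d", 1:5), title = "",
                      abstract = "zelkora fandor visits the domatia")
  docs5$abstract <- paste(docs5$abstract, letters[1:5])  # distinct text
  m5 <- build_term_document_matrix(docs5, "zelkora fandor", lex)
  t5 <- score_traits(tally_cooccurrence(m5, lex))
  expect_equal(t5$domatia, 1L)

  # min_docs threshold
  t5b <- score_traits(tally_cooccurrence(m5, lex), min_docs = 6L)
  expect_equal(t5b$domatia, 0L)

  # empty tally -> empty table
  empty <- build_term_document_matrix(
    data.frame(doc_id = "d1", title = "", abstract = "nothing here"),
    "zelkora fandor", lex)
  t0 <- score_traits(tally_cooccurrence(empty, lex))
  expect_equal(nrow(t0), 0)

  # unknown overlay pair warns and is ignored
  ov_bad <- data.frame(species = "no such", category = "efn",
                       doc_id = "d9", verdict = "false-positive")
  expect_warning(score_traits(tally, overlay = ov_bad), "unknown")
})

test_that("scoring is monotone in evidence", {
  # adding a co-occurring document never flips 1 -> 0; overlay removal
  # never flips 0 -> 1
  lex <- list(domatia = "domatia", efn = "qqq", food_bodies = "www",
              seed_dispersal = "eee")
  base <- data.frame(doc_id = c("d1", "d2"), title = "",
                     abstract = c("bravon kelda near the domatia",
                                  "bravon kelda foraging"))
  more <- rbind(base, data.frame(doc_id = "d3", title = "",
                                 abstract = "bravon kelda in domatia"))
  s1 <- score_traits(tally_cooccurrence(
    build_term_document_matrix(base, "bravon kelda", lex), lex))
  s2 <- score_traits(tally_cooccurrence(
    build_term_document_matrix(more, "bravon kelda", lex), lex))
  expect_gte(s2$domatia, s1$domatia)
})

test_that("hand-list merge uses set union and recomputes derived columns", {
  tab <- combine_categories(data.frame(
    species = c("ga ha", "gb hb", "gc hc"),
    domatia = c(0L, 0L, 0L), efn = c(0L, 0L, 0L),
    food_bodies = c(0L, 0L, 0L), seed_dispersal = c(1L, 1L, 0L),
    n_docs_total = c(2L, 1L, 4L), n_docs_cooccur = c(1L, 1L, 0L)))
  hand <- c("gb hb", "gd hd")  # 1 shared, 1 new
  merged <- merge_hand_list(tab, hand, "seed_dispersal")
  expect_equal(sum(merged$seed_dispersal), 3)   # 2 + 2 - 1
  expect_true("gd hd" %in% merged$species)
  expect_equal(merged$mutualist[merged$species == "gd hd"], 1L)
  # idempotent
  expect_identical(merge_hand_list(merged, hand, "seed_dispersal"),
                   merged)
  # empty hand list leaves the table unchanged
  expect_identical(merge_hand_list(tab, character(0)), tab)
  # malformed binomials are skipped with a warning
  expect_warning(m2 <- merge_hand_list(tab, c("justoneword"),
                                       "seed_dispersal"), "malformed")
  expect_identical(m2, tab)
})

test_that("derived categories are ORs of the base categories", {
  tab <- data.frame(species = c("a b", "c d", "e f"),
                    domatia = c(0L, 1L, 0L), efn = c(0L, 0L, 0L),
                    food_bodies = c(0L, 0L, 0L),
                    seed_dispersal = c(1L, 0L, 0L))
  out <- combine_categories(tab)
  expect_equal(out$mutualist, c(1L, 1L, 0L))
  expect_equal(out$defense, c(0L, 1L, 0L))
})

test_that("noise-free corpora are mined back to exact ground truth", {
  cfg <- corpus_config(n_species = 60, n_genera = 12, n_docs = 400,
                       false_cooccurrence_rate = 0,
                       duplicate_fraction = 0, seed = 31)
  cp <- gen_corpus(cfg)
  mined <- mine_corpus(cp$docs, cp$dictionary, cp$lexicon)
  truth <- cp$truth$states[cp$truth$states$mineable, ]
  truth <- truth[order(truth$species), ]
  expect_equal(mined$traits$species, truth$species)
  for (cc in trait_categories())
    expect_equal(mined$traits[[cc]], truth[[cc]],
                 info = paste("category", cc))
})

test_that("a complete overlay restores ground truth on noisy corpora", {
  cfg <- corpus_config(n_species = 40, n_genera = 8, n_docs = 300,
                       false_cooccurrence_rate = 0.25,
                       duplicate_fraction = 0.2, seed = 57)
  cp <- gen_corpus(cfg)
  fp <- cp$truth$plantings[cp$truth$plantings$truth == "false", ]
  overlay <- data.frame(species = fp$species, category = fp$category,
                        doc_id = fp$doc_id,
                        verdict = "false-positive")
  mined <- mine_corpus(cp$docs, cp$dictionary, cp$lexicon,
                       overlay = overlay)
  truth <- cp$truth$states[cp$truth$states$mineable, ]
  truth <- truth[order(truth$species), ]
  expect_equal(mined$traits$species, truth$species)
  for (cc in trait_categories())
    expect_equal(mined$traits[[cc]], truth[[cc]],
                 info = paste("category", cc))
})
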