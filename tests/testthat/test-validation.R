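make_valid_corpus <- function(seed = 19, fp_rate = 0) {
  cfg <- corpus_config(n_species = 30, n_genera = 6, n_docs = 150,
                       false_cooccurrence_rate = fp_rate, seed = seed)
  cp <- gen_corpus(cfg)
  cp$matrix <- build_term_document_matrix(cp$docs, cp$dictionary,
                                          cp$lexicon)
  cp$tally <- tally_cooccurrence(cp$matrix, cp$lexicon)
  cp
}

test_that("accumulation curve endpoints and monotonicity hold", {
  cp <- make_valid_corpus()
  for (cc in c("seed_dispersal", "mutualist")) {
    curve <- accumulation_curve(cp$matrix, cp$lexicon, cc,
                                n_resamples = 30, seed = 4)
    expect_equal(curve$mean_species[curve$x == 0], 0)
    expect_equal(curve$sd_species[curve$x == 0], 0)
    # at x = corpus size, mean = total observed species, sd = 0
    n_docs <- nrow(cp$matrix)
    traits <- score_traits(cp$tally)
    total <- if (cc == "mutualist") sum(traits$mutualist)
             else sum(traits[[cc]])
    expect_equal(curve$mean_species[curve$x == n_docs], total)
    expect_equal(curve$sd_species[curve$x == n_docs], 0)
    expect_true(all(diff(curve$mean_species) >= 0))
    expect_true(all(curve$sd_species >= 0))
  }
  expect_error(accumulation_curve(cp$matrix, cp$lexicon, "mutualist",
                                  x_grid = nrow(cp$matrix) + 1),
               "exceed")
})

test_that("accumulation mean matches exhaustive enumeration on a tiny corpus", {
  # 10 documents; exact mean at x = 5 averages all C(10,5) subsets
  cfg <- corpus_config(n_species = 8, n_genera = 2, n_docs = 10,
                       mention_rate = 1.5, trait_doc_rate = 0,
                       trait_prevalence = c(domatia = 0, efn = 0,
                                            food_bodies = 0,
                                            seed_dispersal = 0.5),
                       seed = 23)
  cp <- gen_corpus(cfg)
  m <- build_term_document_matrix(cp$docs, cp$dictionary, cp$lexicon)
  term_cat <- attr(m, "term_category")
  terms <- names(term_cat)[term_cat == "seed_dispersal"]
  species <- attr(m, "species")
  count_subset <- function(rows) {
    has_term <- rowSums(m[rows, terms, drop = FALSE]) > 0L
    sum(colSums(m[rows[has_term], species, drop = FALSE]) > 0L)
  }
  subsets <- utils::combn(10, 5)
  exact <- mean(apply(subsets, 2, count_subset))
  curve <- accumulation_curve(m, cp$lexicon, "seed_dispersal",
                              x_grid = 5, n_resamples = 4000, seed = 2)
  # Monte-Carlo error: 4 sigma of the resample mean
  mc_err <- 4 * curve$sd_species / sqrt(curve$n_resamples)
  expect_lt(abs(curve$mean_species - exact), max(mc_err, 0.05))
})

test_that("false-positive audit is clean on noise-free corpora", {
  cp <- make_valid_corpus(fp_rate = 0)
  audit <- false_positive_audit(cp$tally, cp$truth)
  expect_equal(audit$n_false, rep(0L, 5))
  expect_true(all(audit$fp_rate == 0))
  expect_true(attr(audit, "monotone_nonincreasing"))
})

test_that("audit counts match a brute-force recount and planted singles sit at k = 1", {
  cp <- make_valid_corpus(seed = 77, fp_rate = 0.25)
  audit <- false_positive_audit(cp$tally, cp$truth, k_max = 5)
  # independent recount from the tally and the truth states
  st <- cp$truth$states
  for (k in 1:5) {
    sel <- cp$tally$pairs$n_docs == k
    pairs <- cp$tally$pairs[sel, ]
    truth_false <- vapply(seq_len(nrow(pairs)), function(r)
      st[[pairs$category[r]]][st$species == pairs$species[r]] == 0L,
      logical(1))
    expect_equal(audit$n_pairs[k], nrow(pairs))
    expect_equal(audit$n_false[k], sum(truth_false))
  }
  # the generator plants false pairs as single documents only
  expect_true(all(audit$n_false[2:5] == 0))
  expect_gt(audit$fp_rate[1], 0)
  expect_true(attr(audit, "monotone_nonincreasing"))
})

test_that("audit accepts overlays and errors on unlabeled pairs", {
  cp <- make_valid_corpus(seed = 99, fp_rate = 0.3)
  fp <- cp$truth$plantings[cp$truth$plantings$truth == "false", ]
  # label every co-occurrence document: false plantings false, rest true
  all_pairs <- cp$tally$pairs[cp$tally$pairs$n_docs <= 5, ]
  rows <- lapply(seq_len(nrow(all_pairs)), function(r) {
    ids <- antmine:::split_doc_ids(all_pairs$doc_ids[r])
    data.frame(species = all_pairs$species[r],
               category = all_pairs$category[r], doc_id = ids)
  })
  overlay <- do.call(rbind, rows)
  key_fp <- paste(fp$species, fp$category, fp$doc_id)
  overlay$verdict <- ifelse(
    paste(overlay$species, overlay$category, overlay$doc_id) %in% key_fp,
    "false-positive", "true-association")
  a_overlay <- false_positive_audit(cp$tally, overlay)
  a_truth <- false_positive_audit(cp$tally, cp$truth)
  expect_equal(a_overlay$n_false, a_truth$n_false)

  expect_error(false_positive_audit(cp$tally, overlay[-1, ]),
               "unlabeled")
})

test_that("dataset comparison satisfies inclusion-exclusion", {
  # study-scale arithmetic: |a| = 129, |b| = 268, overlap 85
  a <- sprintf("g%03d s%03d", 1:129, 1:129)
  b <- c(a[1:85], sprintf("h%03d t%03d", 1:183, 1:183))
  cmp <- compare_datasets(a, b)
  expect_equal(cmp$n_overlap, 85)
  expect_equal(cmp$n_a_only, 44)
  expect_equal(cmp$n_b_only, 183)
  expect_equal(cmp$n_a_only, cmp$n_a - cmp$n_overlap)
  expect_equal(cmp$n_b_only, cmp$n_b - cmp$n_overlap)

  same <- compare_datasets(a, a)
  expect_equal(same$n_overlap, 129)
  expect_equal(same$n_a_only, 0)
  expect_equal(same$n_b_only, 0)

  disj <- compare_datasets(a, sprintf("z%d z%d", 1:5, 1:5))
  expect_equal(disj$n_overlap, 0)

  # genus level counts genera, not species
  expect_equal(compare_datasets(c("aa x", "aa y"),
                                c("aa z"))$genus$n_overlap, 1)
})
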