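# Synthetic literature corpora with known species-trait ground truth.
#
# Real trait-mining corpora (bibliographies, publisher APIs) cannot be
# redistributed, so testing the mining and validation stages requires
# corpora whose true species-trait associations are known by construction.
# Documents are sentences of filler tokens, disjoint from the species
# dictionary and the trait lexicon, with binomial names and trait terms
# inserted at random positions; this makes matcher correctness provable.

#' Configuration for synthetic corpus generation
#'
#' @param n_species Number of species binomials in the dictionary.
#' @param n_genera Number of genera the species are spread over.
#' @param n_docs Number of unique documents to generate.
#' @param trait_prevalence Probability that a species truly carries each
#'   trait category; either a single value or a named vector over
#'   [trait_categories()].
#' @param mention_rate Expected number of trait-term-free documents
#'   mentioning each species (Poisson).
#' @param trait_doc_rate Expected number of additional co-occurrence
#'   documents, beyond the guaranteed one, per true species-trait pair
#'   (Poisson). Spreads true pairs over co-occurrence counts so audits by
#'   count have something to bin.
#' @param false_cooccurrence_rate Probability that a species without a
#'   trait is planted into exactly one document containing a term of that
#'   trait's category (a known false positive).
#' @param duplicate_fraction Fraction of documents emitted a second time
#'   with case/punctuation/whitespace jitter.
#' @param seed Integer seed; generation is deterministic given the seed.
#'
#' @return A list of class `corpus_config`.
#' @export
corpus_config <- function(n_species = 120, n_genera = 25, n_docs = 600,
                          trait_prevalence = c(domatia = 0.06, efn = 0.08,
                                               food_bodies = 0.04,
                                               seed_dispersal = 0.12),
                          mention_rate = 3, trait_doc_rate = 1.5,
                          false_cooccurrence_rate = 0,
                          duplicate_fraction = 0, seed = 1) {
  cats <- trait_categories()
  if (length(trait_prevalence) == 1L)
    trait_prevalence <- setNames(rep(trait_prevalence, 4L), cats)
  trait_prevalence <- trait_prevalence[cats]
  if (anyNA(trait_prevalence))
    stopf("trait_prevalence must cover all of: %s",
          paste(cats, collapse = ", "))
  probs <- c(trait_prevalence, false_cooccurrence_rate, duplicate_fraction)
  if (any(probs < 0 | probs > 1))
    stopf("probabilities must lie in [0, 1]")
  if (n_species < n_genera || n_genera < 1L)
    stopf("need n_species >= n_genera >= 1 (got %d, %d)",
          n_species, n_genera)
  if (n_docs < 1L) stopf("n_docs must be >= 1")
  if (mention_rate < 0 || trait_doc_rate < 0)
    stopf("rates must be non-negative")
  structure(list(n_species = as.integer(n_species),
                 n_genera = as.integer(n_genera),
                 n_docs = as.integer(n_docs),
                 trait_prevalence = trait_prevalence,
                 mention_rate = mention_rate,
                 trait_doc_rate = trait_doc_rate,
                 false_cooccurrence_rate = false_cooccurrence_rate,
                 duplicate_fraction = duplicate_fraction,
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Default trait-term lexicon
#'
#' Terms (with explicit plural/singular variants) for the four mutualism
#' categories. Multi-word terms are matched as whole-token phrases.
#'
#' @return Named list: category -> character vector of terms.
#' @export
default_trait_lexicon <- function() {
  list(
    domatia = c("domatia", "domatium", "myrmecodomatia"),
    efn = c("extrafloral nectary", "extrafloral nectaries",
            "extrafloral nectar"),
    food_bodies = c("food body", "food bodies", "beltian body",
                    "beltian bodies", "pearl body", "pearl bodies"),
    seed_dispersal = c("seed dispersal", "seed disperser",
                       "seed dispersers", "myrmecochory",
                       "myrmecochorous", "elaiosome", "elaiosomes")
  )
}

# filler vocabulary for document text; disjoint from generated binomials
# (which are CV-syllable words) is enforced at generation time
filler_vocabulary <- function() {
  c("the", "a", "of", "in", "we", "study", "field", "forest", "canopy",
    "ground", "workers", "colony", "colonies", "foraging", "observed",
    "recorded", "sites", "plots", "during", "season", "wet", "dry",
    "samples", "collected", "activity", "abundance", "density",
    "richness", "temperature", "habitat", "litter", "soil", "plant",
    "plants", "tree", "trees", "interactions", "behavior", "between",
    "among", "with", "and", "for", "results", "show", "that", "species",
    "were", "was", "are", "our", "data", "analysis", "region", "tropical",
    "temperate", "survey", "surveys", "experiment", "experiments")
}

make_pronounceable <- function(n_syl) {
  cons <- c("b", "c", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
            "t", "v", "z", "th", "ph", "br", "tr", "cr")
  vow <- c("a", "e", "i", "o", "u")
  paste0(paste0(sample(cons, n_syl, replace = TRUE),
                sample(vow, n_syl, replace = TRUE), collapse = ""),
         sample(c("us", "a", "ix", "or", "is"), 1L))
}

gen_unique_words <- function(n, reserved, min_syl = 2L, max_syl = 3L) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 50L * n + 1000L) stopf("failed to generate unique words")
    w <- make_pronounceable(sample(min_syl:max_syl, 1L))
    if (!(w %in% reserved) && !(w %in% out)) out <- c(out, w)
  }
  out
}

#' Generate a synthetic species-name dictionary
#'
#' Produces `n_species` unique two-word binomials over `n_genera` genera
#' (every genus gets at least one species). Names are pronounceable
#' synthetic words, never real taxa, and are checked against `reserved`
#' tokens (by default the default lexicon and the filler vocabulary) so
#' dictionary, lexicon, and filler text stay disjoint.
#'
#' @param config A [corpus_config()].
#' @param reserved Tokens the generated words must avoid.
#' @return Data frame with columns `species` (binomial) and `genus`.
#' @export
gen_dictionary <- function(config,
                           reserved = c(unlist(default_trait_lexicon(),
                                               use.names = FALSE),
                                        filler_vocabulary())) {
  stopifnot(inherits(config, "corpus_config"))
  reserved <- unique(unlist(strsplit(reserved, " ", fixed = TRUE)))
  with_seed(config$seed, {
    genera <- gen_unique_words(config$n_genera, reserved)
    # each genus gets one species, the rest assigned uniformly
    extra <- config$n_species - config$n_genera
    counts <- rep(1L, config$n_genera)
    if (extra > 0L) {
      add <- table(factor(sample.int(config$n_genera, extra,
                                     replace = TRUE),
                          levels = seq_len(config$n_genera)))
      counts <- counts + as.integer(add)
    }
    sp <- character(0)
    gn <- character(0)
    for (g in seq_along(genera)) {
      eps <- gen_unique_words(counts[g], c(reserved, genera))
      sp <- c(sp, paste(genera[g], eps))
      gn <- c(gn, rep(genera[g], counts[g]))
    }
    data.frame(species = sp, genus = gn, stringsAsFactors = FALSE)
  })
}

# insert multi-word phrases at random token positions of a filler sentence
compose_doc_text <- function(phrases, n_filler) {
  words <- sample(filler_vocabulary(), n_filler, replace = TRUE)
  for (p in phrases) {
    pos <- sample.int(length(words) + 1L, 1L)
    words <- append(words, p, after = pos - 1L)
  }
  paste(words, collapse = " ")
}

# case/punctuation/whitespace jitter only; word identity never changes,
# so normalization-based dedup must catch every duplicate
jitter_text <- function(x) {
  words <- strsplit(x, " ", fixed = TRUE)[[1]]
  flip <- runif(length(words)) < 0.3
  words[flip] <- vapply(words[flip], function(w) {
    paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
  }, character(1))
  punct <- runif(length(words)) < 0.15
  words[punct] <- paste0(words[punct],
                         sample(c(",", ".", ";"), sum(punct),
                                replace = TRUE))
  if (length(words) > 1L) {
    sep <- ifelse(runif(length(words) - 1L) < 0.2, "  ", " ")
    paste0(paste0(words[-length(words)], sep, collapse = ""),
           words[length(words)])
  } else words
}

#' Generate a synthetic corpus with known ground truth
#'
#' Builds `n_docs` unique documents. Each document is either a
#' *co-occurrence document* (exactly one species binomial plus one term of
#' one trait category, planted either as a true association or as a known
#' false positive) or a *plain document* (zero or more species mentions,
#' no trait terms). Every trait-positive species is guaranteed at least
#' one co-occurrence document per positive category. A configurable
#' fraction of documents is additionally emitted as a jittered duplicate
#' (case, punctuation, and whitespace changes only).
#'
#' @param config A [corpus_config()].
#' @param lexicon Trait lexicon (category -> terms); defaults to
#'   [default_trait_lexicon()].
#' @param dictionary Optional dictionary from [gen_dictionary()];
#'   generated from `config` if missing.
#' @param states Optional preset truth: integer 0/1 matrix (species x
#'   category, rownames = dictionary species, colnames =
#'   [trait_categories()]). When given, per-category prevalences are
#'   ignored and these states are planted instead -- used to couple the
#'   corpus to externally simulated tip states.
#' @return List with elements `docs` (data frame: doc_id, title, abstract,
#'   source), `dictionary`, `lexicon`, and `truth` (class
#'   `ant_ground_truth`: per-species true states, planted mentions,
#'   plantings with true/false labels, duplicate map).
#' @export
gen_corpus <- function(config, lexicon = default_trait_lexicon(),
                       dictionary = NULL, states = NULL) {
  stopifnot(inherits(config, "corpus_config"))
  cats <- trait_categories()
  if (!all(lengths(lexicon[cats]) >= 1L))
    stopf("lexicon needs at least one term per category")
  if (is.null(dictionary))
    dictionary <- gen_dictionary(
      config, reserved = c(unlist(lexicon, use.names = FALSE),
                           filler_vocabulary()))
  species <- dictionary$species
  ns <- length(species)
  if (config$mention_rate == 0 && ns > 0L)
    warnf("mention_rate is 0: species absent from plain documents %s",
          "are recorded as unmineable unless trait-positive")

  with_seed(derive_seed(config$seed, 2L), {
    # 1. true states (drawn, or supplied by the caller)
    if (is.null(states)) {
      states <- sapply(cats, function(cc)
        rbinom(ns, 1L, config$trait_prevalence[[cc]]))
      states <- matrix(states, nrow = ns,
                       dimnames = list(species, cats))
    } else {
      if (!all(species %in% rownames(states)) ||
          !all(cats %in% colnames(states)))
        stopf("preset states must cover every species and category")
      states <- as.matrix(states[species, cats])
      storage.mode(states) <- "integer"
    }

    # 2. plantings: true pairs get 1 + Pois(trait_doc_rate) docs,
    #    false pairs (rate false_cooccurrence_rate) exactly one doc
    plant <- list()
    for (cc in cats) {
      pos <- which(states[, cc] == 1L)
      for (i in pos) {
        k <- 1L + rpois(1L, config$trait_doc_rate)
        plant[[length(plant) + 1L]] <-
          data.frame(species = species[i], category = cc,
                     n = k, truth = "true", stringsAsFactors = FALSE)
      }
      neg <- which(states[, cc] == 0L)
      fp <- neg[runif(length(neg)) < config$false_cooccurrence_rate]
      for (i in fp)
        plant[[length(plant) + 1L]] <-
          data.frame(species = species[i], category = cc,
                     n = 1L, truth = "false", stringsAsFactors = FALSE)
    }
    plant <- if (length(plant)) do.call(rbind, plant) else
      data.frame(species = character(0), category = character(0),
                 n = integer(0), truth = character(0))
    n_cooccur <- sum(plant$n)
    if (n_cooccur > config$n_docs)
      stopf(paste0("n_docs = %d is too small for %d planted ",
                   "co-occurrence documents"),
            config$n_docs, n_cooccur)

    # 3. document slots: co-occurrence docs occupy a random subset
    ids <- sprintf("doc%05d", seq_len(config$n_docs))
    cooccur_slots <- sample.int(config$n_docs, n_cooccur)
    plain_slots <- setdiff(seq_len(config$n_docs), cooccur_slots)

    plantings <- data.frame(doc_id = character(0), species = character(0),
                            category = character(0), term = character(0),
                            truth = character(0), stringsAsFactors = FALSE)
    doc_phrases <- vector("list", config$n_docs)
    slot <- 1L
    if (nrow(plant)) for (r in seq_len(nrow(plant))) {
      for (j in seq_len(plant$n[r])) {
        d <- cooccur_slots[slot]; slot <- slot + 1L
        terms <- lexicon[[plant$category[r]]]
        term <- terms[sample.int(length(terms), 1L)]
        doc_phrases[[d]] <- c(doc_phrases[[d]], plant$species[r], term)
        plantings <- rbind(plantings, data.frame(
          doc_id = ids[d], species = plant$species[r],
          category = plant$category[r], term = term,
          truth = plant$truth[r], stringsAsFactors = FALSE))
      }
    }

    # 4. plain mentions, Poisson per species, into plain slots
    mentions <- data.frame(doc_id = character(0), species = character(0),
                           stringsAsFactors = FALSE)
    if (length(plain_slots)) for (i in seq_len(ns)) {
      m <- rpois(1L, config$mention_rate)
      if (m > 0L) {
        dd <- plain_slots[sample.int(length(plain_slots),
                                     min(m, length(plain_slots)))]
        for (d in dd)
          doc_phrases[[d]] <- c(doc_phrases[[d]], species[i])
        mentions <- rbind(mentions, data.frame(
          doc_id = ids[dd], species = species[i],
          stringsAsFactors = FALSE))
      }
    }

    # 5. compose text
    title <- vapply(seq_len(config$n_docs), function(d)
      compose_doc_text(character(0), sample(4:7, 1L)), character(1))
    abstract <- vapply(seq_len(config$n_docs), function(d)
      compose_doc_text(doc_phrases[[d]] %||% character(0),
                       sample(25:45, 1L)), character(1))
    docs <- data.frame(doc_id = ids, title = title, abstract = abstract,
                       source = "synthetic", stringsAsFactors = FALSE)

    # 6. duplicates with formatting jitter
    n_dup <- round(config$duplicate_fraction * config$n_docs)
    duplicates <- data.frame(doc_id = character(0), dup_of = character(0),
                             stringsAsFactors = FALSE)
    if (n_dup > 0L) {
      take <- sample.int(config$n_docs, n_dup,
                         replace = n_dup > config$n_docs)
      dup <- docs[take, , drop = FALSE]
      duplicates <- data.frame(doc_id = paste0(dup$doc_id, "d"),
                               dup_of = dup$doc_id,
                               stringsAsFactors = FALSE)
      dup$doc_id <- paste0(dup$doc_id, "d")
      dup$title <- vapply(dup$title, jitter_text, character(1))
      dup$abstract <- vapply(dup$abstract, jitter_text, character(1))
      docs <- rbind(docs, dup)
      rownames(docs) <- NULL
    }

    mentioned <- unique(c(mentions$species, plantings$species))
    truth <- structure(list(
      states = data.frame(species = species,
                          as.data.frame(states),
                          mineable = species %in% mentioned,
                          row.names = NULL, stringsAsFactors = FALSE),
      mentions = mentions, plantings = plantings,
      duplicates = duplicates), class = "ant_ground_truth")
    list(docs = docs, dictionary = dictionary, lexicon = lexicon,
         truth = truth)
  })
}

#' True positive species for one category, per the ground truth
#'
#' @param truth An `ant_ground_truth` object.
#' @param category One of [trait_categories()].
#' @param mineable_only Restrict to species appearing in the corpus.
#' @return Character vector of species.
#' @export
truth_positives <- function(truth, category, mineable_only = FALSE) {
  st <- truth$states
  keep <- st[[category]] == 1L
  if (mineable_only) keep <- keep & st$mineable
  st$species[keep]
}

#' Emulate a hand-compiled trait list
#'
#' Samples a fraction of the ground-truth positives for one category, and
#' appends `extra` invented species that carry the trait but appear in no
#' corpus document (emulating taxa described only in papers outside the
#' mined corpus).
#'
#' @param truth An `ant_ground_truth` object.
#' @param category Category the list covers.
#' @param coverage Fraction of corpus true positives sampled into the list.
#' @param extra Number of out-of-corpus species appended.
#' @param seed Integer seed.
#' @return Data frame: `species`, `in_corpus` (logical).
#' @export
gen_hand_list <- function(truth, category = "seed_dispersal",
                          coverage = 1, extra = 0L, seed = 1L) {
  if (coverage < 0 || coverage > 1) stopf("coverage must be in [0, 1]")
  if (extra < 0L) stopf("extra must be non-negative")
  pos <- truth_positives(truth, category)
  with_seed(seed, {
    keep <- pos[runif(length(pos)) < coverage]
    reserved <- unique(unlist(strsplit(
      c(truth$states$species, unlist(default_trait_lexicon()),
        filler_vocabulary()), " ")))
    extra_sp <- if (extra > 0L) {
      g <- gen_unique_words(extra, reserved)
      e <- gen_unique_words(extra, c(reserved, g))
      paste(g, e)
    } else character(0)
    data.frame(species = c(keep, extra_sp),
               in_corpus = c(rep(TRUE, length(keep)),
                             rep(FALSE, length(extra_sp))),
               stringsAsFactors = FALSE)
  })
}
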