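# Dictionary/lexicon n-gram mining of document text into binary traits.
#
# Matching is exact whole-token phrase matching on normalized text: no
# stemming and no abbreviation expansion. Plural/singular equivalence is
# handled by listing explicit variants in the lexicon, never
# algorithmically.

#' Normalize document text
#'
#' Lowercases, maps punctuation to spaces, collapses runs of whitespace,
#' and trims. Idempotent, so jittered duplicates normalize identically.
#'
#' @param raw Character vector.
#' @return Normalized character vector.
#' @export
normalize_text <- function(raw) {
  x <- tolower(raw)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

doc_text <- function(docs) {
  normalize_text(paste(docs$title, docs$abstract))
}

#' Remove duplicate documents
#'
#' Documents whose normalized title+abstract text is identical form an
#' equivalence class; the first occurrence of each class is kept, in the
#' original order.
#'
#' @param docs Data frame with columns `doc_id`, `title`, `abstract`.
#' @return The deduplicated data frame.
#' @export
dedup_corpus <- function(docs) {
  docs[!duplicated(doc_text(docs)), , drop = FALSE]
}

#' Build the binary term-document matrix
#'
#' One row per document, one column per n-gram (species binomials from the
#' dictionary plus trait terms from the lexicon). A cell is 1 iff the
#' n-gram occurs as a contiguous whole-token sequence in the normalized
#' title+abstract.
#'
#' @param docs Deduplicated corpus data frame.
#' @param dictionary Character vector of binomials, or the data frame
#'   returned by [gen_dictionary()].
#' @param lexicon Category -> terms list.
#' @return Integer matrix (documents x n-grams) with `dimnames`
#'   (doc_ids, n-grams) and attributes `species` (dictionary columns),
#'   `term_category` (named vector mapping term columns to categories).
#' @export
build_term_document_matrix <- function(docs, dictionary, lexicon) {
  if (is.data.frame(dictionary)) dictionary <- dictionary$species
  dictionary <- normalize_text(dictionary)
  terms <- normalize_text(unlist(lexicon, use.names = FALSE))
  term_category <- rep(names(lexicon), lengths(lexicon))
  names(term_category) <- terms
  if (!length(dictionary) || !length(terms))
    stopf("dictionary and lexicon must be non-empty")
  overlap <- intersect(dictionary, terms)
  if (length(overlap))
    stopf("dictionary and lexicon overlap: %s",
          paste(head(overlap, 5L), collapse = ", "))
  if (anyDuplicated(docs$doc_id))
    stopf("doc_ids not unique; run dedup_corpus() first")
  text <- paste0(" ", doc_text(docs), " ")
  ngrams <- c(dictionary, terms)
  m <- matrix(0L, nrow = nrow(docs), ncol = length(ngrams),
              dimnames = list(docs$doc_id, ngrams))
  for (j in seq_along(ngrams))
    m[, j] <- as.integer(grepl(paste0(" ", ngrams[j], " "), text,
                               fixed = TRUE))
  attr(m, "species") <- dictionary
  attr(m, "term_category") <- term_category
  m
}

#' Tally species-category co-occurrences
#'
#' For every (species, category) pair, counts the documents in which the
#' species name and at least one term of the category both occur, and
#' keeps the document ids. Also tracks, per species, the total number of
#' documents with the name and the number of those with no trait term of
#' any category.
#'
#' @param matrix Term-document matrix from [build_term_document_matrix()].
#' @param lexicon The lexicon the matrix was built from.
#' @return List of class `cooccurrence_table`: `pairs` (species, category,
#'   n_docs, doc_ids as ";"-joined string), `species` (species,
#'   n_docs_total, n_docs_noterm).
#' @export
tally_cooccurrence <- function(matrix, lexicon) {
  species <- attr(matrix, "species")
  term_category <- attr(matrix, "term_category")
  cats <- intersect(trait_categories(), unique(term_category))
  doc_ids <- rownames(matrix)
  # per-document category presence (any term of the category)
  cat_present <- sapply(cats, function(cc) {
    cols <- names(term_category)[term_category == cc]
    as.integer(rowSums(matrix[, cols, drop = FALSE]) > 0L)
  })
  cat_present <- matrix(cat_present, nrow = nrow(matrix),
                        dimnames = list(doc_ids, cats))
  any_term <- rowSums(cat_present) > 0L
  pairs <- list()
  sp_rows <- list()
  for (s in species) {
    present <- matrix[, s] == 1L
    n_tot <- sum(present)
    if (n_tot == 0L) next
    for (cc in cats) {
      both <- present & cat_present[, cc] == 1L
      if (any(both))
        pairs[[length(pairs) + 1L]] <- data.frame(
          species = s, category = cc, n_docs = sum(both),
          doc_ids = paste(doc_ids[both], collapse = ";"),
          stringsAsFactors = FALSE)
    }
    sp_rows[[length(sp_rows) + 1L]] <- data.frame(
      species = s, n_docs_total = n_tot,
      n_docs_noterm = sum(present & !any_term),
      stringsAsFactors = FALSE)
  }
  empty_pairs <- data.frame(species = character(0),
                            category = character(0),
                            n_docs = integer(0), doc_ids = character(0),
                            stringsAsFactors = FALSE)
  out <- list(pairs = if (length(pairs)) do.call(rbind, pairs)
              else empty_pairs,
              species = if (length(sp_rows)) do.call(rbind, sp_rows)
              else data.frame(species = character(0),
                              n_docs_total = integer(0),
                              n_docs_noterm = integer(0)))
  out$pairs <- out$pairs[order(out$pairs$species, out$pairs$category), ,
                         drop = FALSE]
  out$species <- out$species[order(out$species$species), , drop = FALSE]
  rownames(out$pairs) <- rownames(out$species) <- NULL
  structure(out, class = "cooccurrence_table")
}

split_doc_ids <- function(x) strsplit(x, ";", fixed = TRUE)[[1]]

#' Score binary traits from the co-occurrence tally
#'
#' A species scores 1 for a category iff at least `min_docs` co-occurring
#' documents survive the correction overlay (manual verdicts removing
#' false-positive documents); it scores 0 if it appears in at least one
#' document but has no surviving co-occurrence. Species appearing in no
#' document carry no trait information and are excluded.
#'
#' @param tally A `cooccurrence_table`.
#' @param overlay Optional data frame (species, category, doc_id, verdict)
#'   with verdict in `"true-association"` / `"false-positive"`; only
#'   false-positive rows remove documents.
#' @param min_docs Minimum surviving co-occurrence documents to score 1.
#' @return Data frame of class `trait_table`, sorted by species, with
#'   columns species, the four categories, defense, mutualist,
#'   n_docs_total, n_docs_cooccur.
#' @export
score_traits <- function(tally, overlay = NULL, min_docs = 1L) {
  stopifnot(inherits(tally, "cooccurrence_table"))
  if (min_docs < 1L) stopf("min_docs must be >= 1")
  cats <- trait_categories()
  sp <- tally$species$species
  tab <- data.frame(species = sp, stringsAsFactors = FALSE)
  for (cc in cats) tab[[cc]] <- integer(nrow(tab))
  tab$n_docs_cooccur <- integer(nrow(tab))
  if (!is.null(overlay) && nrow(overlay)) {
    known <- paste(tally$pairs$species, tally$pairs$category)
    bad <- !(paste(overlay$species, overlay$category) %in% known)
    if (any(bad)) {
      warnf("overlay references %d unknown (species, category) pairs%s",
            sum(bad), "; ignoring them")
      overlay <- overlay[!bad, , drop = FALSE]
    }
  }
  if (nrow(tally$pairs)) for (r in seq_len(nrow(tally$pairs))) {
    s <- tally$pairs$species[r]
    cc <- tally$pairs$category[r]
    ids <- split_doc_ids(tally$pairs$doc_ids[r])
    if (!is.null(overlay) && nrow(overlay)) {
      fp <- overlay$doc_id[overlay$species == s &
                             overlay$category == cc &
                             overlay$verdict == "false-positive"]
      ids <- setdiff(ids, fp)
    }
    i <- match(s, tab$species)
    if (length(ids) >= min_docs) tab[[cc]][i] <- 1L
    tab$n_docs_cooccur[i] <- tab$n_docs_cooccur[i] + length(ids)
  }
  tab$n_docs_total <- tally$species$n_docs_total[
    match(tab$species, tally$species$species)]
  tab <- tab[order(tab$species), , drop = FALSE]
  rownames(tab) <- NULL
  combine_categories(tab)
}

#' Recompute the derived trait columns
#'
#' `mutualist` is the OR of all four categories; `defense` is the OR of
#' domatia, efn, and food_bodies (the bodyguard mutualisms).
#'
#' @param table A `trait_table` (the four base category columns must be
#'   present).
#' @return The table with `defense` and `mutualist` recomputed.
#' @export
combine_categories <- function(table) {
  cats <- trait_categories()
  if (!all(cats %in% names(table)))
    stopf("trait table is missing base category columns")
  def <- c("domatia", "efn", "food_bodies")
  table$defense <- as.integer(rowSums(table[, def, drop = FALSE]) > 0L)
  table$mutualist <-
    as.integer(rowSums(table[, cats, drop = FALSE]) > 0L)
  cols <- c("species", cats, "defense", "mutualist")
  extra <- setdiff(names(table), cols)
  table <- table[, c(cols, extra), drop = FALSE]
  class(table) <- c("trait_table", "data.frame")
  table
}

#' Merge a hand-compiled species list into a trait table
#'
#' Species on the hand list are scored 1 for the category; species absent
#' from the table are appended (their other categories 0, no document
#' evidence). Malformed names (not two-word binomials) are skipped with a
#' warning. Derived columns are recomputed.
#'
#' @param table A `trait_table`.
#' @param hand Character vector of binomials, or a data frame with a
#'   `species` column.
#' @param category Category the hand list documents.
#' @return The merged `trait_table`, sorted by species.
#' @export
merge_hand_list <- function(table, hand, category = "seed_dispersal") {
  stopifnot(category %in% trait_categories())
  if (is.data.frame(hand)) hand <- hand$species
  hand <- normalize_text(hand)
  hand <- hand[nzchar(hand)]
  ok <- lengths(strsplit(hand, " ", fixed = TRUE)) == 2L
  if (any(!ok)) {
    for (h in hand[!ok]) warnf("skipping malformed binomial: '%s'", h)
    hand <- hand[ok]
  }
  if (!length(hand)) return(table)
  new <- setdiff(hand, table$species)
  if (length(new)) {
    add <- data.frame(species = new, stringsAsFactors = FALSE)
    for (nm in setdiff(names(table), "species")) add[[nm]] <- 0L
    table <- rbind(table, add[, names(table), drop = FALSE])
  }
  table[[category]][table$species %in% hand] <- 1L
  table <- table[order(table$species), , drop = FALSE]
  rownames(table) <- NULL
  combine_categories(table)
}

#' Mine a corpus into a trait table
#'
#' Convenience composition: dedup -> term-document matrix -> co-occurrence
#' tally -> trait scoring (-> optional hand-list merge).
#'
#' @inheritParams build_term_document_matrix
#' @inheritParams score_traits
#' @param hand Optional hand list merged into `hand_category`.
#' @param hand_category Category for the hand list.
#' @return List: `docs` (deduplicated), `matrix`, `tally`, `traits`.
#' @export
mine_corpus <- function(docs, dictionary, lexicon, overlay = NULL,
                        min_docs = 1L, hand = NULL,
                        hand_category = "seed_dispersal") {
  docs <- dedup_corpus(docs)
  m <- build_term_document_matrix(docs, dictionary, lexicon)
  tally <- tally_cooccurrence(m, lexicon)
  traits <- score_traits(tally, overlay = overlay, min_docs = min_docs)
  if (!is.null(hand))
    traits <- merge_hand_list(traits, hand, hand_category)
  list(docs = docs, matrix = m, tally = tally, traits = traits)
}
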