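# Plain-text interchange: JSON-lines corpora, dictionary/lexicon files,
# and CSV tables.

#' Read and write corpus files (JSON lines)
#'
#' One JSON object per line with fields doc_id, title, abstract, source.
#'
#' @param docs Corpus data frame.
#' @param file Path.
#' @return `read_corpus`: the corpus data frame; `write_corpus`: the
#'   path, invisibly.
#' @export
write_corpus <- function(docs, file) {
  lines <- vapply(seq_len(nrow(docs)), function(i)
    as.character(jsonlite::toJSON(as.list(docs[i, , drop = FALSE]),
                                  auto_unbox = TRUE)),
    character(1))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(file) {
  lines <- readLines(file)
  rows <- lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Read and write species-name dictionaries (one binomial per line)
#'
#' @param dictionary Data frame with a `species` column, or character
#'   vector.
#' @param file Path.
#' @return `read_dictionary`: data frame with `species` and `genus`.
#' @export
write_dictionary <- function(dictionary, file) {
  if (is.data.frame(dictionary)) dictionary <- dictionary$species
  writeLines(dictionary, file)
  invisible(file)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(file) {
  sp <- trimws(readLines(file))
  sp <- sp[nzchar(sp)]
  data.frame(species = sp,
             genus = vapply(strsplit(sp, "[ _]"), `[[`, character(1),
                            1L),
             stringsAsFactors = FALSE)
}

#' Read and write trait lexicons (YAML, category -> term list)
#'
#' @param lexicon Named list of term vectors.
#' @param file Path.
#' @export
write_lexicon <- function(lexicon, file) {
  yaml::write_yaml(lexicon, file)
  invisible(file)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(file) {
  lex <- yaml::read_yaml(file)
  lapply(lex, as.character)
}

#' Write a term-document matrix as sparse triplets
#'
#' CSV with columns doc_id, ngram (only the 1 cells are stored).
#'
#' @param matrix Matrix from [build_term_document_matrix()].
#' @param file Path.
#' @export
write_tdm_triplets <- function(matrix, file) {
  idx <- which(matrix == 1L, arr.ind = TRUE)
  out <- data.frame(doc_id = rownames(matrix)[idx[, 1]],
                    ngram = colnames(matrix)[idx[, 2]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$doc_id, out$ngram), , drop = FALSE]
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Write a co-occurrence tally to CSV
#'
#' @param tally A `cooccurrence_table`.
#' @param file Path for the pair table; the per-species table goes to
#'   `sub(".csv", "_species.csv", file)`.
#' @export
write_cooccurrence <- function(tally, file) {
  write.csv(tally$pairs, file, row.names = FALSE)
  write.csv(tally$species, sub("\\.csv$", "_species.csv", file),
            row.names = FALSE)
  invisible(file)
}

#' Read/write trait tables, overlays, and hand lists (CSV)
#'
#' @param table Trait table.
#' @param file Path.
#' @export
write_trait_table <- function(table, file) {
  write.csv(table, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(file) {
  combine_categories(read.csv(file, stringsAsFactors = FALSE))
}

#' @rdname write_trait_table
#' @export
read_overlay <- function(file) {
  ov <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("species", "category", "doc_id", "verdict")
  if (!all(need %in% names(ov)))
    stopf("overlay needs columns: %s", paste(need, collapse = ", "))
  ov
}

#' @rdname write_trait_table
#' @export
read_hand_list <- function(file) {
  read.csv(file, stringsAsFactors = FALSE)
}
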