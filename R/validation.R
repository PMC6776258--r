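# Quality control for mined trait data: species accumulation curves,
# false-positive audits by co-occurrence count, and comparison against an
# independently compiled dataset.

#' Species accumulation curve
#'
#' At each sub-corpus size `x`, draws `n_resamples` uniform
#' without-replacement samples of `x` documents and counts the unique
#' species scored present for the category within the sample (at least
#' one co-occurrence document in the sample). `category = "none"` counts
#' the non-mutualist curve instead: species that appear in the sample but
#' co-occur with no trait term of any category within it.
#'
#' @param matrix Term-document matrix from [build_term_document_matrix()].
#' @param lexicon Lexicon the matrix was built from.
#' @param category One of [trait_categories()], `"mutualist"` (any
#'   category), or `"none"`.
#' @param x_grid Document sample sizes; default 20 evenly spaced values
#'   from 0 to the corpus size.
#' @param n_resamples Resamples per grid value.
#' @param seed Integer seed.
#' @return Data frame of class `accumulation_curve`: category, x,
#'   mean_species, sd_species (population standard deviation over
#'   resamples), n_resamples.
#' @export
accumulation_curve <- function(matrix, lexicon, category = "mutualist",
                               x_grid = NULL, n_resamples = 100L,
                               seed = 1L) {
  n_docs <- nrow(matrix)
  if (is.null(x_grid))
    x_grid <- unique(round(seq(0, n_docs, length.out = 21L)))
  if (any(x_grid > n_docs)) stopf("x_grid values exceed corpus size")
  if (n_resamples < 1L) stopf("n_resamples must be >= 1")
  species <- attr(matrix, "species")
  term_category <- attr(matrix, "term_category")
  cats <- intersect(trait_categories(), unique(term_category))
  sp_m <- matrix[, species, drop = FALSE]
  cat_m <- sapply(cats, function(cc) {
    cols <- names(term_category)[term_category == cc]
    rowSums(matrix[, cols, drop = FALSE]) > 0L
  })
  cat_m <- matrix(cat_m, nrow = n_docs)
  colnames(cat_m) <- cats
  relevant <- if (category == "none") {
    rowSums(cat_m) == 0L           # docs with no trait term at all
  } else if (category == "mutualist") {
    rowSums(cat_m) > 0L
  } else if (category %in% cats) {
    cat_m[, category]
  } else stopf("unknown category '%s'", category)

  count_in <- function(rows) {
    if (!length(rows)) return(0L)
    if (category == "none") {
      # present in the sample, but never with a trait term in the sample
      with_term <- colSums(sp_m[rows[!relevant[rows]], , drop = FALSE]) > 0L
      without <- colSums(sp_m[rows[relevant[rows]], , drop = FALSE]) > 0L
      sum(without & !with_term)
    } else {
      sum(colSums(sp_m[rows[relevant[rows]], , drop = FALSE]) > 0L)
    }
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  # Nested design: each resample is one random permutation of the corpus
  # and every grid value reads a prefix of it. Prefixes of a uniform
  # permutation are uniform without-replacement samples, and counts are
  # monotone in x within every resample, hence so are the means.
  with_seed(seed, {
    counts <- matrix(0, nrow = n_resamples, ncol = length(x_grid))
    for (i in seq_len(n_resamples)) {
      perm <- sample.int(n_docs)
      counts[i, ] <- vapply(x_grid, function(x)
        as.numeric(count_in(perm[seq_len(x)])), numeric(1))
    }
    exhaustive <- x_grid %in% c(0L, n_docs)
    out <- data.frame(category = category, x = x_grid,
                      mean_species = colMeans(counts),
                      sd_species = ifelse(exhaustive, 0,
                                          apply(counts, 2, pop_sd)),
                      n_resamples = n_resamples,
                      stringsAsFactors = FALSE)
    class(out) <- c("accumulation_curve", "data.frame")
    out
  })
}

#' False-positive audit by co-occurrence count
#'
#' Bins (species, category) pairs by their number of co-occurring
#' documents k = 1..`k_max` and reports the fraction judged to be false
#' associations. Labels come either from a correction overlay (a pair is
#' false iff every one of its co-occurrence documents carries a
#' false-positive verdict) or from generator ground truth (a pair is
#' false iff the species does not truly carry the trait).
#'
#' @param tally A `cooccurrence_table`.
#' @param labels An `ant_ground_truth` object or an overlay data frame
#'   (species, category, doc_id, verdict).
#' @param k_max Largest co-occurrence count audited.
#' @return Data frame of class `fp_audit`: k, n_pairs, n_false, fp_rate;
#'   attribute `monotone_nonincreasing` reports whether fp_rate declines
#'   (weakly) with k over non-empty bins.
#' @export
false_positive_audit <- function(tally, labels, k_max = 5L) {
  stopifnot(inherits(tally, "cooccurrence_table"))
  pairs <- tally$pairs[tally$pairs$n_docs <= k_max, , drop = FALSE]
  is_false <- logical(nrow(pairs))
  if (inherits(labels, "ant_ground_truth")) {
    st <- labels$states
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs$species[r], st$species)
      if (is.na(i))
        stopf("unlabeled pair: (%s, %s)", pairs$species[r],
              pairs$category[r])
      is_false[r] <- st[[pairs$category[r]]][i] == 0L
    }
  } else {
    key <- paste(labels$species, labels$category, labels$doc_id)
    fp <- key[labels$verdict == "false-positive"]
    for (r in seq_len(nrow(pairs))) {
      ids <- split_doc_ids(pairs$doc_ids[r])
      k <- paste(pairs$species[r], pairs$category[r], ids)
      if (!all(k %in% key))
        stopf("unlabeled pair: (%s, %s)", pairs$species[r],
              pairs$category[r])
      is_false[r] <- all(k %in% fp)
    }
  }
  out <- data.frame(k = seq_len(k_max))
  out$n_pairs <- vapply(out$k, function(k) sum(pairs$n_docs == k), 0L)
  out$n_false <- vapply(out$k, function(k)
    sum(is_false[pairs$n_docs == k]), 0L)
  out$fp_rate <- ifelse(out$n_pairs > 0L, out$n_false / out$n_pairs, 0)
  rates <- out$fp_rate[out$n_pairs > 0L]
  attr(out, "monotone_nonincreasing") <-
    length(rates) < 2L || all(diff(rates) <= 1e-12)
  class(out) <- c("fp_audit", "data.frame")
  out
}

#' Compare two species datasets
#'
#' Overlap and set differences at the species level and, via a
#' genus-of-species mapping (default: the first word of the binomial), at
#' the genus level.
#'
#' @param a,b Character vectors of species.
#' @param genus_of Function mapping species names to genus names.
#' @return List of class `dataset_comparison` with species-level counts
#'   (n_a, n_b, n_overlap, n_a_only, n_b_only) and the genus-level
#'   analogues.
#' @export
compare_datasets <- function(a, b,
                             genus_of = function(x)
                               vapply(strsplit(x, "[ _]"), `[[`,
                                      character(1), 1L)) {
  a <- unique(a)
  b <- unique(b)
  ga <- unique(genus_of(a))
  gb <- unique(genus_of(b))
  out <- list(n_a = length(a), n_b = length(b),
              n_overlap = length(intersect(a, b)),
              n_a_only = length(setdiff(a, b)),
              n_b_only = length(setdiff(b, a)),
              genus = list(n_a = length(ga), n_b = length(gb),
                           n_overlap = length(intersect(ga, gb)),
                           n_a_only = length(setdiff(ga, gb)),
                           n_b_only = length(setdiff(gb, ga))))
  class(out) <- "dataset_comparison"
  out
}
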