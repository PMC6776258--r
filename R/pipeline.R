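# End-to-end orchestration: corpus -> traits -> validation -> pruned
# tree -> model battery -> report.

#' Pipeline configuration
#'
#' Inputs may be given as in-memory objects or as file paths (JSON-lines
#' corpus, plain-text dictionary, YAML lexicon, CSV overlay/hand list,
#' Newick tree).
#'
#' @param corpus Corpus data frame or path.
#' @param dictionary Dictionary data frame/vector or path.
#' @param lexicon Lexicon list or path.
#' @param tree `ape::phylo` or Newick path.
#' @param overlay Optional correction overlay (data frame or path).
#' @param hand_list Optional hand-compiled list (data frame or path) for
#'   `hand_category`.
#' @param truth Optional `ant_ground_truth` enabling the false-positive
#'   audit on synthetic corpora.
#' @param category Trait column analyzed: `"mutualist"`, `"defense"`, or
#'   one of [trait_categories()].
#' @param hand_category Category the hand list documents.
#' @param families Model families to fit (see [make_model()]).
#' @param n_described Total described species used to scale sampling
#'   fractions (14,416 valid ant species names).
#' @param min_docs Co-occurrence threshold for trait presence.
#' @param audit_k_max Largest co-occurrence count audited for false
#'   positives; keep within the range the labels cover.
#' @param n_starts Optimizer starts per model.
#' @param n_resamples Resamples per accumulation-curve point.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory (created); `NULL` keeps everything in
#'   memory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus, dictionary, lexicon, tree,
                            overlay = NULL, hand_list = NULL,
                            truth = NULL, category = "mutualist",
                            hand_category = "seed_dispersal",
                            families = c("bisse_null", "bisse", "cid2",
                                         "cid4", "hisse_1hidden",
                                         "hisse_full"),
                            n_described = 14416L, min_docs = 1L,
                            audit_k_max = 5L, n_starts = 5L,
                            n_resamples = 50L, seed = 1L,
                            out_dir = NULL) {
  ok_cat <- c("mutualist", "defense", trait_categories())
  if (!category %in% ok_cat)
    stopf("category must be one of: %s", paste(ok_cat, collapse = ", "))
  bad <- setdiff(families, sse_families())
  if (length(bad)) stopf("unknown families: %s", paste(bad,
                                                       collapse = ", "))
  structure(list(corpus = corpus, dictionary = dictionary,
                 lexicon = lexicon, tree = tree, overlay = overlay,
                 hand_list = hand_list, truth = truth,
                 category = category, hand_category = hand_category,
                 families = families,
                 n_described = as.integer(n_described),
                 min_docs = as.integer(min_docs),
                 audit_k_max = as.integer(audit_k_max),
                 n_starts = as.integer(n_starts),
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stopf("input file not found: %s", x)
    reader(x)
  } else x
}

#' Run the full analysis pipeline
#'
#' Stages: dedup and mine the corpus into a trait table (with optional
#' overlay correction and hand-list merge); accumulation curves and,
#' given labels, the false-positive audit; hand-vs-mined dataset
#' comparison; prune the tree to trait coverage; state totals and
#' sampling fractions; fit the requested model families; AIC ranking;
#' tip-averaged rates under the best hidden-class model. Artifacts and a
#' machine-readable report are written under `out_dir` when given.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `mined`, `curves`, `audit`,
#'   `comparison`, `pruned`, `totals`, `fractions`, `fits`, `aic_table`,
#'   `tip_rates`, `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  corpus <- load_input(config$corpus, read_corpus)
  dictionary <- load_input(config$dictionary, read_dictionary)
  lexicon <- load_input(config$lexicon, read_lexicon)
  tree <- load_input(config$tree, read_newick)
  overlay <- load_input(config$overlay, read_overlay)
  hand <- load_input(config$hand_list, read_hand_list)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name,
            conditionMessage(e)))
  }

  mined <- stage("mine", mine_corpus(corpus, dictionary, lexicon,
                                     overlay = overlay,
                                     min_docs = config$min_docs,
                                     hand = hand,
                                     hand_category =
                                       config$hand_category))
  traits <- mined$traits

  curve_cats <- unique(c(config$category, "none"))
  curve_cats[curve_cats == "defense"] <- "mutualist"
  curves <- stage("validate", do.call(rbind, lapply(
    curve_cats, function(cc)
      accumulation_curve(mined$matrix, lexicon, cc,
                         n_resamples = config$n_resamples,
                         seed = derive_seed(config$seed, 11L)))))
  labels <- config$truth %||% overlay
  audit <- if (!is.null(labels))
    stage("validate", false_positive_audit(mined$tally, labels,
                                           k_max = config$audit_k_max))
  comparison <- if (!is.null(hand)) {
    mined_only <- score_traits(mined$tally, overlay = overlay,
                               min_docs = config$min_docs)
    h <- if (is.data.frame(hand)) hand$species else hand
    stage("validate", compare_datasets(
      mined_only$species[mined_only[[config$hand_category]] == 1L],
      normalize_text(h)))
  }

  pruned <- stage("prune", prune_to_traits(tree, traits,
                                           config$category))
  totals <- stage("fractions", estimate_state_totals(
    sum(traits[[config$category]]), nrow(traits), config$n_described))
  fractions <- stage("fractions", state_sampling_fractions(
    pruned$tip_states, totals$N1, totals$N0))

  fits <- lapply(config$families, function(fam) stage(
    paste0("fit:", fam), {
      spec <- make_model(fam, fractions)
      fit_mle(spec, pruned$tree, pruned$tip_states,
              n_starts = config$n_starts,
              seed = derive_seed(config$seed, 23L))
    }))
  names(fits) <- config$families
  aic_table <- stage("compare", compare_models(fits))

  hidden_fams <- intersect(c("hisse_full", "hisse_1hidden", "cid2",
                             "cid4"), aic_table$model)
  tip_rates <- if (length(hidden_fams)) {
    best_h <- hidden_fams[which.min(
      aic_table$AIC[match(hidden_fams, aic_table$model)])]
    f <- fits[[best_h]]
    stage("tip_rates", tip_rate_average(f$spec, pruned$tree,
                                        pruned$tip_states, f$par))
  }

  report <- list(
    category = config$category,
    n_docs_unique = nrow(mined$docs),
    n_species_with_traits = nrow(traits),
    n_state1 = sum(traits[[config$category]]),
    n_state0 = sum(traits[[config$category]] == 0L),
    trait_counts = as.list(colSums(
      traits[, c(trait_categories(), "defense", "mutualist")])),
    n_tips = length(pruned$tree$tip.label),
    n_tips_state1 = pruned$n_state1,
    n_tips_state0 = pruned$n_state0,
    totals = totals,
    fractions = list(f0 = fractions$f0, f1 = fractions$f1),
    aic_table = aic_table,
    best_model = aic_table$model[1],
    rates = lapply(fits, function(f)
      list(lambda = as.list(f$rates$lambda), mu = as.list(f$rates$mu),
           div = as.list(f$ndiv), lnL = f$lnL, k = f$k, AIC = f$AIC)),
    tip_rates_by_state = if (!is.null(tip_rates)) tip_rates$by_state,
    comparison = if (!is.null(comparison)) unclass(comparison),
    seed = config$seed)

  out <- list(mined = mined, curves = curves, audit = audit,
              comparison = comparison, pruned = pruned,
              totals = totals, fractions = fractions, fits = fits,
              aic_table = aic_table, tip_rates = tip_rates,
              report = report)
  class(out) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

format_report_text <- function(report) {
  lines <- c(
    sprintf("Trait category analyzed: %s", report$category),
    sprintf("Species with trait data: %d (state 1: %d, state 0: %d)",
            report$n_species_with_traits, report$n_state1,
            report$n_state0),
    sprintf("Tips after pruning: %d (state 1: %d, state 0: %d)",
            report$n_tips, report$n_tips_state1, report$n_tips_state0),
    sprintf("Estimated totals: N1 = %d, N0 = %d", report$totals$N1,
            report$totals$N0),
    sprintf("Sampling fractions: f0 = %.5f, f1 = %.5f",
            report$fractions$f0, report$fractions$f1),
    "", "Model comparison (AIC ascending):",
    sprintf("  %-14s %10s %4s %12s %8s", "model", "lnL", "k", "AIC",
            "dAIC"))
  at <- report$aic_table
  for (i in seq_len(nrow(at)))
    lines <- c(lines, sprintf("  %-14s %10.3f %4d %12.3f %8.2f",
                              at$model[i], at$lnL[i], at$k[i],
                              at$AIC[i], at$dAIC[i]))
  lines <- c(lines, "", "Per-state rates (lambda / mu / div):")
  for (fam in names(report$rates)) {
    r <- report$rates[[fam]]
    lines <- c(lines, sprintf("  %s:", fam))
    for (s in names(r$lambda))
      lines <- c(lines, sprintf("    %-3s %10.5f %10.5f %10.5f", s,
                                r$lambda[[s]], r$mu[[s]], r$div[[s]]))
  }
  lines
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_trait_table(out$mined$traits, p("traits.csv"))
  write_cooccurrence(out$mined$tally, p("cooccurrence.csv"))
  write.csv(out$curves, p("accumulation_curves.csv"),
            row.names = FALSE)
  if (!is.null(out$audit))
    write.csv(out$audit, p("fp_audit.csv"), row.names = FALSE)
  write_newick(out$pruned$tree, p("pruned_tree.nwk"))
  write.csv(data.frame(species = names(out$pruned$tip_states),
                       state = as.integer(out$pruned$tip_states)),
            p("tip_states.csv"), row.names = FALSE)
  write.csv(out$aic_table, p("aic_table.csv"), row.names = FALSE)
  report <- out$report
  md5 <- tools::md5sum(c(p("traits.csv"), p("pruned_tree.nwk"),
                         p("tip_states.csv")))
  names(md5) <- basename(names(md5))
  report$input_md5 <- as.list(md5)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  writeLines(format_report_text(out$report), p("report.txt"))
  writeLines(sprintf("run completed %s | seed %d | antmine %s",
                     format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                     config$seed,
                     as.character(utils::packageVersion("antmine"))),
             p("run.log"))
  invisible(out)
}
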