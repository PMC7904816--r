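#' Run both extractors over a corpus
#'
#' Applies the tree-pattern extractor and the dependency-rule extractor to
#' the given sentences (by default the gold-positive ones, mirroring a
#' pipeline in which the relation detector has already filtered
#' non-asserting sentences).
#'
#' @param corpus An `mdlink_corpus`.
#' @param patterns TPE pattern list (the shipped patterns by default).
#' @param which `"positive"` (gold-positive sentences) or `"all"`.
#' @return List with triplet tibbles `tpe` and `dbe`.
#' @export
extract_corpus <- function(corpus, patterns = mdlink_patterns(),
                           which = c("positive", "all")) {
  which <- match.arg(which)
  keep_ids <- if (which == "positive") {
    unique(corpus$gold_pairs$sentence_id[corpus$gold_pairs$label == 1L])
  } else {
    vapply(corpus$parsed, function(p) p$sentence$sentence_id, "")
  }
  parsed <- Filter(function(p) p$sentence$sentence_id %in% keep_ids,
                   corpus$parsed)
  list(tpe = dplyr::bind_rows(lapply(parsed, extract_triplets, patterns = patterns)),
       dbe = dplyr::bind_rows(lapply(parsed, extract_dbe)))
}

#' Label extracted triplets against gold triplets
#'
#' A triplet is correct when its (sentence, microbe, disease, stemmed
#' relation word) tuple appears in the gold standard.
#'
#' @param triplets Triplet tibble.
#' @param gold Gold triplet tibble (`sentence_id`, `microbe`, `disease`,
#'   `relation`).
#' @return `triplets` with a logical `correct` column.
#' @export
label_extractions <- function(triplets, gold) {
  key <- function(d) paste(d$sentence_id, d$microbe, d$disease, d$relation,
                           sep = "\r")
  dplyr::mutate(triplets, correct = key(triplets) %in% key(gold))
}

#' Compare TPE-only, DBE-only and ensemble extraction
#'
#' Splits the corpus sentences in two halves: pattern reliability
#' statistics are fitted on the labelled extractions of the first half, and
#' macro-averaged precision/recall/F of the three methods (each thresholded
#' on its confidence) are computed on the second half.
#'
#' @param corpus An `mdlink_corpus`.
#' @param patterns TPE patterns.
#' @param threshold Confidence threshold (0.5 by default).
#' @param seed Seed for the half split.
#' @param alpha Smoothing for [fit_stats()].
#' @return List with `metrics` (tibble: method, precision, recall, f1),
#'   `stats` (the fitted `mdlink_pattern_stats`) and `n_eval` (number of
#'   evaluation-half gold triplets).
#' @export
compare_extractors <- function(corpus, patterns = mdlink_patterns(),
                               threshold = 0.5, seed = 1L, alpha = 1) {
  ex <- extract_corpus(corpus, patterns)
  pos_ids <- sort(unique(corpus$gold_pairs$sentence_id[corpus$gold_pairs$label == 1L]))
  half <- cv_folds(pos_ids, folds = 2L, seed = seed)
  fit_ids <- names(half)[half == 1L]
  eval_ids <- names(half)[half == 2L]

  labelled <- dplyr::bind_rows(ex$tpe, ex$dbe) |>
    dplyr::filter(.data$sentence_id %in% fit_ids) |>
    label_extractions(corpus$gold_triplets) |>
    split_provenance()
  stats <- fit_stats(labelled, alpha = alpha)

  gold_eval <- corpus$gold_triplets[corpus$gold_triplets$sentence_id %in% eval_ids, ]
  tpe_eval <- ex$tpe[ex$tpe$sentence_id %in% eval_ids, ]
  dbe_eval <- ex$dbe[ex$dbe$sentence_id %in% eval_ids, ]
  none <- tpe_eval[0, ]

  one <- function(method, tpe_t, dbe_t) {
    merged <- merge_extractions(tpe_t, dbe_t, stats, threshold)
    dplyr::mutate(macro_prf(merged, gold_eval)$macro, method = method,
                  .before = 1L)
  }
  metrics <- dplyr::bind_rows(
    one("TPE", tpe_eval, none),
    one("DBE", none, dbe_eval),
    one("ensemble", tpe_eval, dbe_eval)
  )
  list(metrics = metrics, stats = stats, n_eval = nrow(gold_eval))
}

#' End-to-end association mining over raw text
#'
#' The full pipeline on plain sentences: dictionary NER, parse lookup,
#' candidate-pair enumeration, relation detection with a trained model,
#' relation-word extraction by both extractors on detector-positive
#' sentences, ensemble scoring, and aggregation into an association table.
#'
#' @param texts Tibble with `sentence_id` and `text`.
#' @param microbe_lex,disease_lex Lexicons.
#' @param provider An `mdlink_provider` with parses for every sentence.
#' @param model A trained `mdlink_detector`.
#' @param emb Word embeddings used at training time.
#' @param stats Fitted `mdlink_pattern_stats`.
#' @param patterns TPE patterns.
#' @param threshold Ensemble confidence threshold.
#' @return List with `pairs` (detector predictions), `triplets` (scored,
#'   thresholded) and `associations` (aggregated table).
#' @export
mine_associations <- function(texts, microbe_lex, disease_lex, provider,
                              model, emb, stats,
                              patterns = mdlink_patterns(), threshold = 0.5) {
  parsed <- lapply(seq_len(nrow(texts)), function(i) {
    s <- tag_entities(texts$text[i], microbe_lex, disease_lex,
                      sentence_id = texts$sentence_id[i])
    provide(s, provider)
  })
  pairs <- unlist(lapply(parsed, enumerate_pairs), recursive = FALSE)
  if (length(pairs) == 0L) {
    return(list(pairs = tibble::tibble(), triplets = tibble::tibble(),
                associations = tibble::tibble()))
  }
  pred <- predict(model, pairs, emb)
  pos_ids <- unique(pred$sentence_id[pred$predicted == 1L])
  keep <- Filter(function(p) p$sentence$sentence_id %in% pos_ids, parsed)
  tpe <- dplyr::bind_rows(lapply(keep, extract_triplets, patterns = patterns))
  dbe <- dplyr::bind_rows(lapply(keep, extract_dbe))
  triplets <- merge_extractions(tpe, dbe, stats, threshold)
  list(pairs = pred, triplets = triplets,
       associations = aggregate_associations(triplets))
}
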