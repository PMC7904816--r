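#' Fit pattern reliability statistics
#'
#' The confidence model treats every extraction pattern (TPE pattern ids
#' and dependency-rule ids alike) as a noisy annotator. From labelled
#' extractions it estimates, with add-alpha smoothing over the relation-word
#' vocabulary:
#'
#' * `Pr(p)` -- the prior that pattern p extracts correctly (its precision),
#'   `(n_correct + alpha) / (n + 2 alpha)`;
#' * `Pr(r | p)` -- how often relation word r appears among p's correct
#'   extractions;
#' * `Pr(r | not p)` -- how often r appears among p's incorrect ones.
#'
#' @param labelled Tibble with columns `pattern_id` (one id per row; rows
#'   with comma-joined provenance should be split beforehand, see
#'   [split_provenance()]), `relation` (stemmed relation word) and `correct`
#'   (logical gold correctness).
#' @param alpha Smoothing constant (add-one by default).
#' @return An `mdlink_pattern_stats` object.
#' @export
fit_stats <- function(labelled, alpha = 1) {
  stopifnot(all(c("pattern_id", "relation", "correct") %in% names(labelled)))
  vocab <- sort(unique(labelled$relation))
  V <- length(vocab) + 1L  # one slot for unseen relation words
  per_pattern <- labelled |>
    dplyr::group_by(.data$pattern_id) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     .groups = "drop")
  rel_counts <- labelled |>
    dplyr::count(.data$pattern_id, .data$relation, .data$correct)
  structure(list(per_pattern = per_pattern, rel_counts = rel_counts,
                 alpha = alpha, vocab_size = V),
            class = "mdlink_pattern_stats")
}

#' @export
print.mdlink_pattern_stats <- function(x, ...) {
  cat(sprintf("<mdlink_pattern_stats: %d patterns, alpha=%g>\n",
              nrow(x$per_pattern), x$alpha))
  invisible(x)
}

.pattern_prior <- function(stats, pattern_id) {
  row <- stats$per_pattern[stats$per_pattern$pattern_id == pattern_id, ]
  a <- stats$alpha
  if (nrow(row) == 0L) {
    warning("pattern '", pattern_id, "' has no recorded extractions; ",
            "using the pure-smoothing prior 0.5")
    return(0.5)
  }
  (row$n_correct + a) / (row$n + 2 * a)
}

.rel_likelihood <- function(stats, pattern_id, relation, correct) {
  a <- stats$alpha
  row <- stats$per_pattern[stats$per_pattern$pattern_id == pattern_id, ]
  denom_n <- if (nrow(row) == 0L) 0 else if (correct) row$n_correct else row$n - row$n_correct
  rc <- stats$rel_counts
  hit <- rc[rc$pattern_id == pattern_id & rc$relation == relation &
            rc$correct == correct, ]
  cnt <- if (nrow(hit)) hit$n else 0
  (cnt + a) / (denom_n + a * stats$vocab_size)
}

#' Posterior that a pattern extracted a relation word correctly
#'
#' Bayes' rule with the pattern precision as prior:
#' `Pr(p | r) = Pr(r|p) Pr(p) / (Pr(r|p) Pr(p) + Pr(r|not p) Pr(not p))`.
#'
#' @param stats An `mdlink_pattern_stats`.
#' @param pattern_id Pattern identifier.
#' @param relation Stemmed relation word.
#' @return Posterior probability in \[0, 1\].
#' @export
pattern_posterior <- function(stats, pattern_id, relation) {
  prior <- .pattern_prior(stats, pattern_id)
  l1 <- .rel_likelihood(stats, pattern_id, relation, TRUE)
  l0 <- .rel_likelihood(stats, pattern_id, relation, FALSE)
  posterior_from(prior, l1, l0)
}

#' @rdname pattern_posterior
#' @param prior `Pr(p)`.
#' @param lik_correct `Pr(r | p)`.
#' @param lik_incorrect `Pr(r | not p)`.
#' @export
posterior_from <- function(prior, lik_correct, lik_incorrect) {
  num <- lik_correct * prior
  den <- num + lik_incorrect * (1 - prior)
  if (den == 0) return(prior)  # uninformative likelihoods
  num / den
}

#' Confidence of an extracted triplet
#'
#' The maximum, over the patterns that produced the triplet, of the
#' per-pattern posterior for its relation word.
#'
#' @param stats An `mdlink_pattern_stats`.
#' @param pattern_ids Character vector of contributing pattern ids.
#' @param relation Stemmed relation word.
#' @return List with `confidence` and the per-pattern `posteriors`.
#' @export
confidence <- function(stats, pattern_ids, relation) {
  post <- vapply(pattern_ids, pattern_posterior, 0, stats = stats,
                 relation = relation)
  list(confidence = max(post), posteriors = post)
}

#' Split comma-joined provenance into one row per pattern
#' @param triplets Triplet tibble with a `pattern_ids` column.
#' @return The same tibble with one `pattern_id` per row.
#' @export
split_provenance <- function(triplets) {
  triplets |>
    dplyr::mutate(pattern_id = strsplit(.data$pattern_ids, ",", fixed = TRUE)) |>
    tidyr::unnest("pattern_id") |>
    dplyr::select(-"pattern_ids")
}

#' Merge and score extractions from both extractors
#'
#' Takes the union of the TPE and dependency-based triplet streams keyed by
#' (sentence, microbe, disease, stemmed relation word), merges provenance,
#' scores each merged triplet with the maximum per-pattern posterior, and
#' drops triplets whose confidence falls below the threshold. At threshold
#' 0 the result is exactly the deduplicated union.
#'
#' @param tpe_triplets,dbe_triplets Triplet tibbles from
#'   [extract_triplets()] / [extract_dbe()].
#' @param stats An `mdlink_pattern_stats`.
#' @param threshold Confidence cutoff (default 0.5, the value at which the
#'   ensemble F-score peaks in the reference evaluation).
#' @return Scored triplet tibble with `confidence` and merged `pattern_ids`.
#' @export
merge_extractions <- function(tpe_triplets, dbe_triplets, stats,
                              threshold = 0.5) {
  all_t <- dplyr::bind_rows(tpe_triplets, dbe_triplets)
  if (nrow(all_t) == 0L) {
    return(dplyr::mutate(all_t, confidence = numeric(0)))
  }
  merged <- all_t |>
    split_provenance() |>
    dplyr::group_by(.data$sentence_id, .data$microbe, .data$disease,
                    .data$relation) |>
    dplyr::summarise(relation_surface = .data$relation_surface[1L],
                     extractor = paste(sort(unique(.data$extractor)), collapse = "+"),
                     pattern_ids = paste(sort(unique(.data$pattern_id)), collapse = ","),
                     .groups = "drop")
  merged$confidence <- vapply(seq_len(nrow(merged)), function(i) {
    ids <- strsplit(merged$pattern_ids[i], ",", fixed = TRUE)[[1]]
    confidence(stats, ids, merged$relation[i])$confidence
  }, 0)
  merged[merged$confidence >= threshold, ]
}

#' Macro-averaged precision / recall / F over relation-word classes
#'
#' Per relation-word class present in the gold set, triplets are compared
#' as exact (microbe, disease, relation) tuples within sentences; the macro
#' scores are the unweighted means over those classes.
#'
#' @param predicted,gold Triplet tibbles with columns `sentence_id`,
#'   `microbe`, `disease`, `relation`.
#' @return List with `by_class` (per-class tibble) and `macro` (one-row
#'   tibble of macro precision/recall/F).
#' @export
macro_prf <- function(predicted, gold) {
  key <- function(d) paste(d$sentence_id, d$microbe, d$disease, d$relation,
                           sep = "\r")
  classes <- sort(unique(gold$relation))
  rows <- lapply(classes, function(cl) {
    pk <- unique(key(predicted[predicted$relation == cl, ]))
    gk <- unique(key(gold[gold$relation == cl, ]))
    tp <- length(intersect(pk, gk))
    dplyr::mutate(prf_from_counts(tp, length(pk) - tp, length(gk) - tp),
                  relation = cl, .before = 1L)
  })
  by_class <- dplyr::bind_rows(rows)
  macro <- tibble::tibble(precision = mean(by_class$precision),
                          recall = mean(by_class$recall),
                          f1 = mean(by_class$f1))
  list(by_class = by_class, macro = macro)
}

#' Sentence-level fold assignment for cross-validation
#' @param sentence_ids Character vector (one per pair or sentence).
#' @param folds Number of folds.
#' @param seed RNG seed (fold assignment is deterministic given the seed).
#' @return Named integer vector: fold of each distinct sentence id.
#' @export
cv_folds <- function(sentence_ids, folds = 10L, seed = 1L) {
  ids <- unique(sentence_ids)
  withr::with_seed(seed, {
    shuffled <- sample(ids)
  })
  fold <- rep(seq_len(folds), length.out = length(shuffled))
  stats::setNames(fold[match(ids, shuffled)], ids)
}

#' Tenfold cross-validation of the relation detector
#'
#' Sentences (not pairs) are split into folds so that all candidate pairs
#' of one sentence stay together; each fold serves once as validation data.
#' Features are computed once and reused across folds.
#'
#' @param pairs List of `mdlink_pair` objects.
#' @param labels 0/1 gold labels, one per pair.
#' @param emb An `mdlink_embeddings`.
#' @param config A [detector_config()].
#' @param folds Number of folds (10 by default).
#' @param seed Seed for fold assignment and per-fold training.
#' @param level `"pair"`, `"sentence"`, or both; each fold's model is
#'   trained once and scored at every requested level.
#' @return List with `per_fold` (tibble of fold metrics) and `mean`
#'   (per-level tibble of mean precision/recall/F).
#' @export
cv_detector <- function(pairs, labels, emb, config = detector_config(),
                        folds = 10L, seed = 1L, level = "pair") {
  level <- match.arg(level, c("pair", "sentence"), several.ok = TRUE)
  labels <- as.integer(labels)
  ids <- vapply(pairs, `[[`, "", "sentence_id")
  assignment <- cv_folds(ids, folds, seed)
  fold_of <- assignment[ids]
  vocabs <- build_vocabs(unique_parsed(pairs))
  features <- lapply(pairs, featurize, emb = emb, config = config,
                     vocabs = vocabs)
  per_fold <- lapply(seq_len(folds), function(k) {
    tr <- fold_of != k; te <- !tr
    cfg <- config; cfg$seed <- config$seed + k
    model <- train_detector(pairs[tr], labels[tr], emb, cfg, vocabs = vocabs,
                            features = features[tr])
    dplyr::bind_rows(lapply(level, function(lv) {
      dplyr::mutate(evaluate_detector(model, pairs[te], labels[te], emb,
                                      level = lv, features = features[te]),
                    fold = k, .before = 1L)
    }))
  })
  per_fold <- dplyr::bind_rows(per_fold)
  means <- per_fold |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(precision = mean(.data$precision),
                     recall = mean(.data$recall), f1 = mean(.data$f1),
                     .groups = "drop")
  list(per_fold = per_fold,
       mean = means[means$level == level[1L],
                    c("precision", "recall", "f1")],
       mean_by_level = means)
}
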