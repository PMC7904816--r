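#' Initialize a relation-detector model
#'
#' The model holds trainable POS and dependency-tag embedding tables, four
#' bottom bi-LSTMs (the three sentence segments and the shortest dependency
#' path), a top bi-LSTM over six time steps
#' \[Seq1, E1, Seq2, E2, Seq3, SDP\], and a linear + softmax head over two
#' classes. Weights start uniform in \[-0.08, 0.08\] with forget-gate biases
#' at 1; initialization is deterministic given `config$seed`.
#'
#' @param config A [detector_config()].
#' @param vocabs From [build_vocabs()].
#' @return An `mdlink_detector` (untrained).
#' @export
init_detector <- function(config, vocabs) {
  H <- config$hidden
  D <- config$word_dim + config$pos_dim + config$dep_dim + 20L
  withr::with_seed(config$seed, {
    u <- function(r, c) matrix(stats::runif(r * c, -0.08, 0.08), r, c)
    lstm_init <- function(din) {
      b <- rep(0, 4 * H); b[(H + 1):(2 * H)] <- 1  # forget-gate bias
      list(Wf = u(4 * H, din), Uf = u(4 * H, H), bf = b,
           Wb = u(4 * H, din), Ub = u(4 * H, H), bb = b)
    }
    params <- list(pos_emb = u(vocabs$n_pos, config$pos_dim),
                   dep_emb = u(vocabs$n_dep, config$dep_dim))
    for (nm in c("s1", "s2", "s3", "sdp")) {
      li <- lstm_init(D)
      names(li) <- paste(nm, names(li), sep = "_")
      params <- c(params, li)
    }
    li <- lstm_init(2L * H)
    names(li) <- paste("top", names(li), sep = "_")
    params <- c(params, li)
    params$ff_W <- u(2L, 2L * H)
    params$ff_b <- rep(0, 2L)
  })
  structure(list(params = params, config = config, vocabs = vocabs,
                 loss_trace = numeric(0), trained = FALSE),
            class = "mdlink_detector")
}

#' Forward pass for one candidate pair
#'
#' Inference-mode forward (no dropout); deterministic, two calls on the
#' same input are identical.
#'
#' @param model An `mdlink_detector`.
#' @param feat Output of [featurize()] for one pair.
#' @param internals Also return the bottom-layer matrix (4 x 2*hidden), the
#'   top-LSTM input (6 x 2*hidden) and the top output (2*hidden).
#' @return List with `prob` (probability of an asserted association),
#'   `probs` (both class scores, summing to 1), and optionally the
#'   internals.
#' @export
detector_forward <- function(model, feat, internals = FALSE) {
  res <- cpp_hlstm_forward(model$params, .features_for_cpp(feat), internals)
  out <- list(prob = res$probs[2L], probs = as.numeric(res$probs))
  if (internals) {
    out$bottom <- res$bottom
    out$top_input <- res$top_input
    out$top_output <- as.numeric(res$top_output)
  }
  out
}

#' Train the relation detector
#'
#' Per-example Adam on the binary cross-entropy, with inverted dropout on
#' the input features and the top output. Deterministic given
#' `config$seed`.
#'
#' @param pairs List of `mdlink_pair` objects.
#' @param labels Integer 0/1 vector, one per pair (both classes required).
#' @param emb An `mdlink_embeddings`.
#' @param config A [detector_config()].
#' @param vocabs Optional [build_vocabs()] result; computed from the pairs'
#'   sentences when omitted.
#' @param features Optional precomputed `lapply(pairs, featurize, ...)`.
#' @return A trained `mdlink_detector` with a per-epoch mean-loss trace.
#' @export
train_detector <- function(pairs, labels, emb, config = detector_config(),
                           vocabs = NULL, features = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(pairs) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes")
  }
  if (is.null(vocabs)) {
    parsed <- unique_parsed(pairs)
    vocabs <- build_vocabs(parsed)
  }
  model <- init_detector(config, vocabs)
  if (is.null(features)) {
    features <- lapply(pairs, featurize, emb = emb, config = config,
                       vocabs = vocabs)
  }
  keep <- .keep_probs(config)
  res <- cpp_hlstm_train(model$params, lapply(features, .features_for_cpp),
                         labels, config$learning_rate, config$epochs,
                         keep$input, keep$output, config$seed,
                         config$batch_size)
  model$params <- res$params
  model$loss_trace <- as.numeric(res$loss_trace)
  model$trained <- TRUE
  model
}

unique_parsed <- function(pairs) {
  ids <- vapply(pairs, `[[`, "", "sentence_id")
  lapply(split(seq_along(pairs), ids), function(ix) pairs[[ix[1L]]]$parsed) |>
    unname()
}

#' Predict association probabilities
#'
#' @param object A trained `mdlink_detector`.
#' @param pairs List of `mdlink_pair` objects.
#' @param emb An `mdlink_embeddings`.
#' @param features Optional precomputed features.
#' @param ... Unused.
#' @return Tibble with `sentence_id`, `microbe`, `disease`, `prob`,
#'   `predicted` (1 when `prob > 0.5`; a tie at exactly 0.5 predicts the
#'   negative class).
#' @export
predict.mdlink_detector <- function(object, pairs, emb, features = NULL, ...) {
  if (is.null(features)) {
    features <- lapply(pairs, featurize, emb = emb, config = object$config,
                       vocabs = object$vocabs)
  }
  probs <- cpp_hlstm_predict(object$params, lapply(features, .features_for_cpp))
  dplyr::mutate(pairs_tibble(pairs)[, c("sentence_id", "microbe", "disease")],
                prob = as.numeric(probs),
                predicted = as.integer(.data$prob > 0.5))
}

#' Precision / recall / F-score of the detector
#'
#' Pair level treats every candidate pair as one binary decision. Sentence
#' level reduces each sentence to "asserts at least one association": the
#' gold label is whether any pair is positive, the prediction whether any
#' pair is predicted positive.
#'
#' @param model A trained `mdlink_detector`.
#' @param pairs,labels Evaluation data.
#' @param emb An `mdlink_embeddings`.
#' @param level `"pair"` or `"sentence"`.
#' @param features Optional precomputed features.
#' @return One-row tibble: `level`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_detector <- function(model, pairs, labels, emb,
                              level = c("pair", "sentence"),
                              features = NULL) {
  level <- match.arg(level)
  pred <- predict(model, pairs, emb, features = features)
  gold <- as.integer(labels)
  if (level == "sentence") {
    ids <- vapply(pairs, `[[`, "", "sentence_id")
    gold <- as.integer(tapply(gold, ids, max))
    predicted <- as.integer(tapply(pred$predicted, ids, max))
  } else {
    predicted <- pred$predicted
  }
  dplyr::mutate(binary_prf(predicted, gold), level = level, .before = 1L)
}

#' Binary precision/recall/F from predicted and gold 0/1 vectors
#' @param predicted,gold Integer 0/1 vectors of equal length.
#' @return One-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
binary_prf <- function(predicted, gold) {
  stopifnot(length(predicted) == length(gold))
  tp <- sum(predicted == 1L & gold == 1L)
  fp <- sum(predicted == 1L & gold == 0L)
  fn <- sum(predicted == 0L & gold == 1L)
  prf_from_counts(tp, fp, fn)
}

prf_from_counts <- function(tp, fp, fn) {
  p <- if (tp + fp == 0L) { if (fn == 0L) 1 else 0 } else tp / (tp + fp)
  r <- if (tp + fn == 0L) { if (fp == 0L) 1 else 0 } else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f)
}

#' @export
print.mdlink_detector <- function(x, ...) {
  cat(sprintf("<mdlink_detector: hidden=%d, %strained>\n", x$config$hidden,
              if (x$trained) "" else "un"))
  if (length(x$loss_trace)) {
    cat(sprintf("  final epoch mean loss: %.4f\n", utils::tail(x$loss_trace, 1L)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training loss of a detector
#' @param x A trained `mdlink_detector`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `loss`.
#' @export
tidy.mdlink_detector <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' One-row summary of a detector
#' @param x An `mdlink_detector`.
#' @param ... Unused.
#' @return Tibble with model dimensions and final loss.
#' @export
glance.mdlink_detector <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 0L))
  tibble::tibble(hidden = x$config$hidden, epochs_run = length(x$loss_trace),
                 n_parameters = n_par,
                 final_loss = if (length(x$loss_trace)) utils::tail(x$loss_trace, 1L) else NA_real_)
}

#' Save / load a detector checkpoint
#'
#' A single JSON file holding config, vocabularies and weights. Loading a
#' checkpoint whose configuration disagrees with `config` (when supplied)
#' is an error.
#'
#' @param model An `mdlink_detector`.
#' @param path Checkpoint path.
#' @return `path` invisibly / the restored model.
#' @export
save_detector <- function(model, path) {
  payload <- list(config = unclass(model$config),
                  vocabs = model$vocabs,
                  params = lapply(model$params, function(p) {
                    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                    else list(dim = NULL, data = as.numeric(p))
                  }),
                  loss_trace = model$loss_trace, trained = model$trained)
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_detector
#' @param config Optional config to validate against the checkpoint.
#' @export
load_detector <- function(path, config = NULL) {
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyVector = TRUE)
  cfg <- do.call(detector_config, payload$config[names(payload$config) != ""])
  if (!is.null(config)) {
    same <- identical(unclass(cfg)[order(names(cfg))],
                      unclass(config)[order(names(config))])
    if (!same) stop("checkpoint configuration does not match the supplied config")
  }
  params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[[1L]], p$dim[[2L]]) else p$data
  })
  vocabs <- payload$vocabs
  vocabs$pos <- unlist(vocabs$pos); vocabs$dep <- unlist(vocabs$dep)
  structure(list(params = params, config = cfg, vocabs = vocabs,
                 loss_trace = as.numeric(payload$loss_trace),
                 trained = isTRUE(payload$trained)),
            class = "mdlink_detector")
}
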