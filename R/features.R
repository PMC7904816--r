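#' Word embeddings
#'
#' Word vectors are pluggable: either loaded from a word2vec text file or
#' generated deterministically per word (a seeded hash of the word drives a
#' normal draw), so that out-of-vocabulary words always receive the same
#' fixed vector and no pretrained model is required for testing.
#'
#' @param dim Vector dimension (200 by default).
#' @param seed Seed mixed into the per-word hash.
#' @return An `mdlink_embeddings` object.
#' @export
random_embeddings <- function(dim = 200L, seed = 42L) {
  structure(list(dim = as.integer(dim), seed = as.integer(seed),
                 table = new.env(parent = emptyenv())),
            class = "mdlink_embeddings")
}

#' @rdname random_embeddings
#' @param path word2vec text file: `token v1 v2 ... vdim`, one per line; an
#'   optional leading `n dim` header line is skipped.
#' @export
read_word2vec <- function(path, seed = 42L) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  first <- strsplit(lines[[1L]], "\\s+")[[1]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1L]
  }
  parts <- strsplit(lines, "\\s+")
  dim <- length(parts[[1L]]) - 1L
  emb <- random_embeddings(dim = dim, seed = seed)
  for (p in parts) {
    if (length(p) != dim + 1L) stop("malformed word2vec row for token '", p[[1L]], "'")
    assign(tolower(p[[1L]]), as.numeric(p[-1L]), envir = emb$table)
  }
  emb
}

# deterministic per-word hash, independent of insertion order
.word_hash <- function(word, seed) {
  codes <- utf8ToInt(word)
  h <- 104729
  for (cd in codes) h <- (h * 131 + cd) %% 2147483647
  as.integer((h + seed * 48271) %% 2147483646) + 1L
}

#' Look up word vectors
#' @param emb An `mdlink_embeddings`.
#' @param words Character vector (matched case-insensitively).
#' @return Matrix `length(words)` x `dim`.
#' @export
embed_words <- function(emb, words) {
  out <- matrix(0, nrow = length(words), ncol = emb$dim)
  for (i in seq_along(words)) {
    w <- tolower(words[[i]])
    v <- get0(w, envir = emb$table, inherits = FALSE)
    if (is.null(v)) {
      v <- withr::with_seed(.word_hash(w, emb$seed),
                            stats::rnorm(emb$dim) / sqrt(emb$dim))
      assign(w, v, envir = emb$table)
    }
    out[i, ] <- v
  }
  out
}

#' Entity embedding
#'
#' The mean of the word vectors of the canonical name's constituent words
#' (underscore-separated).
#'
#' @param emb An `mdlink_embeddings`.
#' @param canonical Canonical entity name, e.g. `"Pseudomonas_aeruginosa"`.
#' @return Numeric vector of length `emb$dim`.
#' @export
entity_embedding <- function(emb, canonical) {
  parts <- strsplit(canonical, "_", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  colMeans(embed_words(emb, parts))
}

#' Entity-based attention weights
#'
#' Each word is weighted by how close it lies to the two entities in
#' embedding space: per entity, the softmax over the dot products of the
#' word vectors with that entity's vector; the final weight is the mean of
#' the two per-entity weight vectors. Each per-entity weight vector sums to
#' one, hence so does the average. The weights are invariant to adding a
#' constant to all dot products (softmax shift invariance).
#'
#' @param word_vecs Matrix `m x dim` of word vectors (one row per word).
#' @param e1_vec,e2_vec Entity vectors of length `dim`.
#' @return Numeric weight vector of length `m`.
#' @export
attention_weights <- function(word_vecs, e1_vec, e2_vec) {
  word_vecs <- rbind(word_vecs)
  m <- nrow(word_vecs)
  if (m == 0L) stop("attention_weights: empty word sequence")
  softmax <- function(x) { z <- exp(x - max(x)); z / sum(z) }
  th1 <- softmax(as.numeric(word_vecs %*% e1_vec))
  th2 <- softmax(as.numeric(word_vecs %*% e2_vec))
  (th1 + th2) / 2
}

#' Detector configuration
#'
#' Defaults follow the reference training setup: 60 time steps for each
#' sentence segment and 12 for the shortest dependency path, hidden size
#' 100 per LSTM direction, learning rate 0.001, 30 epochs, input-layer
#' dropout 0.7 and output-layer dropout 0.5 (interpreted as
#' keep-probabilities by default; set `dropout_semantics = "drop"` to read
#' them as drop rates). Word/POS/dependency-tag/position feature widths are
#' 200/10/10/20.
#'
#' @param seg_time_steps,sdp_time_steps Sequence budgets (padding/truncation).
#' @param hidden Hidden units per LSTM direction; the bi-LSTM outputs
#'   `2 * hidden`, which must equal `word_dim` so entity embeddings align
#'   with bottom-layer outputs in the top LSTM.
#' @param learning_rate,epochs,batch_size Adam settings (gradients averaged
#'   over minibatches).
#' @param input_dropout,output_dropout Dropout parameters, see
#'   `dropout_semantics`.
#' @param dropout_semantics `"keep"` or `"drop"`.
#' @param word_dim,pos_dim,dep_dim Embedding widths.
#' @param seed Training/initialization seed.
#' @return A `detector_config` list.
#' @export
detector_config <- function(seg_time_steps = 60L, sdp_time_steps = 12L,
                            hidden = 100L, learning_rate = 0.001,
                            epochs = 30L, batch_size = 16L,
                            input_dropout = 0.7,
                            output_dropout = 0.5,
                            dropout_semantics = c("keep", "drop"),
                            word_dim = 200L, pos_dim = 10L, dep_dim = 10L,
                            seed = 1L) {
  dropout_semantics <- match.arg(dropout_semantics)
  cfg <- list(seg_time_steps = as.integer(seg_time_steps),
              sdp_time_steps = as.integer(sdp_time_steps),
              hidden = as.integer(hidden),
              learning_rate = learning_rate, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              input_dropout = input_dropout, output_dropout = output_dropout,
              dropout_semantics = dropout_semantics,
              word_dim = as.integer(word_dim), pos_dim = as.integer(pos_dim),
              dep_dim = as.integer(dep_dim), seed = as.integer(seed))
  stopifnot(cfg$seg_time_steps > 0L, cfg$sdp_time_steps > 0L, cfg$hidden > 0L,
            cfg$learning_rate > 0, cfg$epochs > 0L, cfg$batch_size > 0L,
            cfg$input_dropout >= 0, cfg$input_dropout <= 1,
            cfg$output_dropout >= 0, cfg$output_dropout <= 1)
  if (2L * cfg$hidden != cfg$word_dim) {
    stop("2 * hidden must equal word_dim (entity embeddings and bottom ",
         "bi-LSTM outputs share the top-LSTM input width)")
  }
  structure(cfg, class = "detector_config")
}

.keep_probs <- function(config) {
  if (config$dropout_semantics == "keep") {
    list(input = config$input_dropout, output = config$output_dropout)
  } else {
    list(input = 1 - config$input_dropout, output = 1 - config$output_dropout)
  }
}

#' POS / dependency-tag vocabularies
#' @param parsed_list List of `mdlink_parsed` sentences.
#' @return List with named integer maps `pos` and `dep`; id 1 is the
#'   unknown tag.
#' @export
build_vocabs <- function(parsed_list) {
  pos <- sort(unique(unlist(lapply(parsed_list, function(p) ctree_leaves(p$ctree)$pos))))
  dep <- sort(unique(unlist(lapply(parsed_list, function(p) p$dtree$deprel))))
  list(pos = stats::setNames(seq_along(pos) + 1L, pos),
       dep = stats::setNames(seq_along(dep) + 1L, dep),
       n_pos = length(pos) + 1L, n_dep = length(dep) + 1L)
}

.vocab_id <- function(map, keys) {
  id <- unname(map[keys])
  id[is.na(id)] <- 1L
  as.integer(id)
}

# truncate a token-index vector to budget L, dropping the end farthest from
# the nearest entity: seq1 keeps its tail (abuts e1), seq3 its head (abuts
# e2), seq2 and the SDP keep both ends and lose the middle
.truncate_span <- function(idx, L, kind) {
  n <- length(idx)
  if (n <= L) return(idx)
  switch(kind,
         seq1 = idx[(n - L + 1L):n],
         seq3 = idx[1:L],
         {
           a <- ceiling(L / 2); b <- L - a
           c(idx[seq_len(a)], if (b > 0L) idx[(n - b + 1L):n])
         })
}

#' Featurize a candidate pair
#'
#' Builds the four padded feature sequences (three segments + SDP) the
#' detector consumes. Per token the features are the attention-weighted
#' word vector, POS and dependency-tag embedding ids (the tables themselves
#' are trained in the model), and the 20-dim position feature: two
#' concatenated 10-bin one-hots of the token's distance to each entity,
#' clipped to \[-4, +5\]. Sequences are padded with all-zero entries to the
#' configured time-step budgets; over-long sequences are truncated away
#' from the entities.
#'
#' @param pair An `mdlink_pair`.
#' @param emb An `mdlink_embeddings`.
#' @param config A [detector_config()].
#' @param vocabs From [build_vocabs()].
#' @return List with `segs` (four lists of `word`, `pos`, `dep`, `posf`,
#'   `len`), `e1`, `e2`.
#' @export
featurize <- function(pair, emb, config, vocabs) {
  tokens <- pair$parsed$sentence$tokens
  leaves <- ctree_leaves(pair$parsed$ctree)
  pos_tags <- leaves$pos
  dep_tags <- pair$parsed$dtree$deprel
  e1v <- entity_embedding(emb, tokens[pair$e1_token])
  e2v <- entity_embedding(emb, tokens[pair$e2_token])

  spans <- list(seq1 = pair$seq1, seq2 = pair$seq2, seq3 = pair$seq3,
                sdp = pair$sdp)
  budgets <- c(config$seg_time_steps, config$seg_time_steps,
               config$seg_time_steps, config$sdp_time_steps)
  segs <- vector("list", 4L)
  for (s in seq_len(4L)) {
    kind <- names(spans)[s]
    idx <- .truncate_span(spans[[s]], budgets[s], kind)
    Tb <- budgets[s]
    word <- matrix(0, Tb, config$word_dim)
    posf <- matrix(0, Tb, 20L)
    pos_id <- integer(Tb); dep_id <- integer(Tb)
    m <- length(idx)
    if (m > 0L) {
      wv <- embed_words(emb, tokens[idx])
      th <- attention_weights(wv, e1v, e2v)
      word[seq_len(m), ] <- wv * th
      pos_id[seq_len(m)] <- .vocab_id(vocabs$pos, pos_tags[idx])
      dep_id[seq_len(m)] <- .vocab_id(vocabs$dep, dep_tags[idx])
      d1 <- pmin(pmax(idx - pair$e1_token, -4L), 5L) + 5L
      d2 <- pmin(pmax(idx - pair$e2_token, -4L), 5L) + 5L
      posf[cbind(seq_len(m), d1)] <- 1
      posf[cbind(seq_len(m), 10L + d2)] <- 1
    }
    segs[[s]] <- list(word = word, pos = pos_id, dep = dep_id, posf = posf,
                      len = m)
  }
  list(segs = segs, e1 = e1v, e2 = e2v)
}

# strip padding for the C++ core (many-to-one masking: only the true-length
# prefix of each sequence is consumed, so extra padding never changes output)
.features_for_cpp <- function(feat) {
  segs <- lapply(feat$segs, function(sg) {
    m <- sg$len
    list(word = sg$word[seq_len(m), , drop = FALSE],
         pos = sg$pos[seq_len(m)], dep = sg$dep[seq_len(m)],
         posf = sg$posf[seq_len(m), , drop = FALSE])
  })
  list(segs = segs, e1 = feat$e1, e2 = feat$e2)
}
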