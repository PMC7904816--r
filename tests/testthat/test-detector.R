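# a tiny random example in the detector's feature format
rand_example <- function(cfg, vocabs, lens = c(3L, 2L, 4L, 1L)) {
  mkseg <- function(T, budget) {
    word <- matrix(0, budget, cfg$word_dim)
    posf <- matrix(0, budget, 20L)
    pos <- integer(budget); dep <- integer(budget)
    if (T > 0L) {
      word[seq_len(T), ] <- matrix(stats::rnorm(T * cfg$word_dim), T)
      posf[cbind(seq_len(T), sample(10L, T, TRUE))] <- 1
      posf[cbind(seq_len(T), 10L + sample(10L, T, TRUE))] <- 1
      pos[seq_len(T)] <- sample(vocabs$n_pos, T, TRUE)
      dep[seq_len(T)] <- sample(vocabs$n_dep, T, TRUE)
    }
    list(word = word, pos = pos, dep = dep, posf = posf, len = T)
  }
  budgets <- c(rep(cfg$seg_time_steps, 3L), cfg$sdp_time_steps)
  list(segs = purrr::map2(lens, budgets, mkseg),
       e1 = stats::rnorm(cfg$word_dim), e2 = stats::rnorm(cfg$word_dim))
}

tiny_vocabs <- list(pos = c(NN = 2L, VBZ = 3L), dep = c(nsubj = 2L, obj = 3L),
                    n_pos = 3L, n_dep = 3L)

test_that("forward produces the documented layer shapes with hidden 100", {
  cfg <- detector_config(epochs = 1L)  # hidden 100, word_dim 200
  model <- init_detector(cfg, tiny_vocabs)
  set.seed(1)
  feat <- rand_example(cfg, tiny_vocabs)
  out <- detector_forward(model, feat, internals = TRUE)
  expect_equal(dim(out$bottom), c(4L, 200L))     # bottom layer: 4 x 200
  expect_equal(dim(out$top_input), c(6L, 200L))  # top input: 6 x 200
  expect_length(out$top_output, 200L)            # top output: length 200
  expect_equal(sum(out$probs), 1)
  expect_true(all(out$probs > 0 & out$probs < 1))
  # entity embeddings occupy rows 2 and 4 of the top input, sentence order
  expect_equal(out$top_input[2, ], feat$e1)
  expect_equal(out$top_input[4, ], feat$e2)
})

test_that("the top-LSTM input width constraint is enforced", {
  expect_error(detector_config(hidden = 64L, word_dim = 200L),
               "2 \\* hidden")
})

test_that("inference is deterministic and invariant to extra padding", {
  cfg <- small_config()
  model <- init_detector(cfg, tiny_vocabs)
  set.seed(2)
  feat <- rand_example(cfg, tiny_vocabs)
  p1 <- detector_forward(model, feat)$prob
  p2 <- detector_forward(model, feat)$prob
  expect_identical(p1, p2)

  # enlarge the padded area without touching true lengths
  grown <- feat
  for (s in 1:4) {
    sg <- grown$segs[[s]]
    sg$word <- rbind(sg$word, matrix(0, 5, ncol(sg$word)))
    sg$posf <- rbind(sg$posf, matrix(0, 5, 20)); sg$pos <- c(sg$pos, rep(0L, 5))
    sg$dep <- c(sg$dep, rep(0L, 5))
    grown$segs[[s]] <- sg
  }
  expect_identical(detector_forward(model, grown)$prob, p1)
})

test_that("analytic gradients match finite differences", {
  cfg <- small_config()
  model <- init_detector(cfg, tiny_vocabs)
  set.seed(3)
  feat <- rand_example(cfg, tiny_vocabs, lens = c(2L, 1L, 3L, 1L))
  ex <- mdlink:::.features_for_cpp(feat)
  g <- mdlink:::cpp_hlstm_grad(model$params, ex, 1L)
  p <- model$params
  eps <- 1e-6
  worst <- 0
  for (name in names(p)) {
    for (rep in 1:3) {
      if (is.matrix(p[[name]])) {
        i <- sample(nrow(p[[name]]), 1); j <- sample(ncol(p[[name]]), 1)
        analytic <- g$grads[[name]][i, j]
        up <- p; up[[name]][i, j] <- up[[name]][i, j] + eps
        dn <- p; dn[[name]][i, j] <- dn[[name]][i, j] - eps
      } else {
        i <- sample(length(p[[name]]), 1)
        analytic <- g$grads[[name]][i]
        up <- p; up[[name]][i] <- up[[name]][i] + eps
        dn <- p; dn[[name]][i] <- dn[[name]][i] - eps
      }
      numeric <- (mdlink:::cpp_hlstm_loss(up, ex, 1L) -
                    mdlink:::cpp_hlstm_loss(dn, ex, 1L)) / (2 * eps)
      worst <- max(worst, abs(analytic - numeric) /
                     max(1e-4, abs(analytic) + abs(numeric)))
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("training is deterministic given a seed and reduces the loss", {
  corp <- test_corpus(60)
  cp <- corpus_pairs(corp)
  emb <- test_embeddings()
  cfg <- detector_config(epochs = 3L, seed = 5L)
  idx <- 1:40
  m1 <- train_detector(cp$pairs[idx], cp$labels[idx], emb, cfg)
  m2 <- train_detector(cp$pairs[idx], cp$labels[idx], emb, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_lt(m1$loss_trace[3], m1$loss_trace[1])

  cfg2 <- detector_config(epochs = 3L, seed = 6L)
  m3 <- train_detector(cp$pairs[idx], cp$labels[idx], emb, cfg2)
  expect_false(identical(m1$params, m3$params))
})

test_that("single-class training data is rejected", {
  corp <- test_corpus(60)
  cp <- corpus_pairs(corp)
  pos <- which(cp$labels == 1L)[1:10]
  expect_error(train_detector(cp$pairs[pos], cp$labels[pos],
                              test_embeddings(), detector_config(epochs = 1L)),
               "both classes")
})

test_that("evaluation computes the textbook precision/recall/F formulas", {
  expect_equal(binary_prf(c(1, 1, 0, 1), c(1, 1, 1, 0)),
               tibble::tibble(tp = 2L, fp = 1L, fn = 1L, precision = 2 / 3,
                              recall = 2 / 3, f1 = 2 / 3))
  perfect <- binary_prf(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
})

test_that("sentence-level evaluation ORs the pair decisions per sentence", {
  corp <- test_corpus(60)
  cp <- corpus_pairs(corp)
  emb <- test_embeddings()
  cfg <- detector_config(epochs = 3L, seed = 5L)
  model <- train_detector(cp$pairs, cp$labels, emb, cfg)
  pair_lvl <- evaluate_detector(model, cp$pairs, cp$labels, emb)
  sent_lvl <- evaluate_detector(model, cp$pairs, cp$labels, emb,
                                level = "sentence")
  ids <- vapply(cp$pairs, `[[`, "", "sentence_id")
  expect_equal(sent_lvl$tp + sent_lvl$fn,
               sum(tapply(cp$labels, ids, max) == 1L))
  expect_lte(pair_lvl$tp, sum(cp$labels))
})

test_that("detector checkpoints round-trip and reject mismatched configs", {
  corp <- test_corpus(60)
  cp <- corpus_pairs(corp)
  emb <- test_embeddings()
  cfg <- detector_config(epochs = 2L, seed = 5L)
  model <- train_detector(cp$pairs[1:30], cp$labels[1:30], emb, cfg)
  path <- withr::local_tempfile()
  save_detector(model, path)
  back <- load_detector(path)
  feats <- lapply(cp$pairs[31:35], featurize, emb = emb, config = cfg,
                  vocabs = model$vocabs)
  p_orig <- vapply(feats, function(f) detector_forward(model, f)$prob, 0)
  p_back <- vapply(feats, function(f) detector_forward(back, f)$prob, 0)
  expect_equal(p_orig, p_back, tolerance = 1e-12)
  expect_error(load_detector(path, config = detector_config(epochs = 9L)),
               "does not match")
})

test_that("tidy and glance summarize a fitted detector", {
  corp <- test_corpus(60)
  cp <- corpus_pairs(corp)
  cfg <- detector_config(epochs = 2L, seed = 5L)
  model <- train_detector(cp$pairs[1:30], cp$labels[1:30], test_embeddings(),
                          cfg)
  td <- tidy(model)
  expect_equal(td$epoch, 1:2)
  expect_true(all(is.finite(td$loss)))
  gl <- glance(model)
  expect_equal(gl$hidden, 100L)
  expect_gt(gl$n_parameters, 1e6)
})
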