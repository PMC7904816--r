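toy_labelled <- function() {
  tibble::tibble(
    pattern_id = c(rep("p_good", 8), rep("p_bad", 6)),
    relation = c(rep("cause", 6), "associate", "associate",
                 rep("cause", 2), rep("appos", 4)),
    correct = c(rep(TRUE, 8), TRUE, TRUE, rep(FALSE, 4))
  )
}

test_that("the Bayes posterior reproduces hand-computed values", {
  # Pr(p)=0.8, Pr(r|p)=0.5, Pr(r|~p)=0.25 -> 8/9
  expect_equal(posterior_from(0.8, 0.5, 0.25), 8 / 9)
  # equal likelihoods: posterior equals the prior
  expect_equal(posterior_from(0.37, 0.4, 0.4), 0.37)
  # perfect pattern: posterior 1 whenever Pr(r|p) > 0
  expect_equal(posterior_from(1, 0.01, 0.9), 1)
  # impossible pattern: posterior 0
  expect_equal(posterior_from(0, 0.5, 0.5), 0)
})

test_that("posteriors stay in [0,1] and are monotone in the prior", {
  set.seed(11)
  for (i in 1:200) {
    prior <- stats::runif(1); l1 <- stats::runif(1); l0 <- stats::runif(1)
    post <- posterior_from(prior, l1, l0)
    expect_gte(post, 0); expect_lte(post, 1)
  }
  priors <- seq(0, 1, by = 0.05)
  posts <- vapply(priors, posterior_from, 0, lik_correct = 0.6,
                  lik_incorrect = 0.3)
  expect_true(all(diff(posts) >= 0))
})

test_that("fitted statistics implement add-alpha smoothing", {
  st <- fit_stats(toy_labelled(), alpha = 1)
  # Pr(p_good) = (8+1)/(8+2) = 0.9
  expect_equal(mdlink:::.pattern_prior(st, "p_good"), 0.9)
  # Pr(p_bad) = (2+1)/(6+2) = 0.375
  expect_equal(mdlink:::.pattern_prior(st, "p_bad"), 0.375)
  # vocab: cause, associate, appos -> V = 4
  # Pr(cause | p_good correct) = (6+1)/(8+4)
  expect_equal(mdlink:::.rel_likelihood(st, "p_good", "cause", TRUE), 7 / 12)
  # unseen relation word gets pure smoothing mass
  expect_equal(mdlink:::.rel_likelihood(st, "p_good", "zzz", TRUE), 1 / 12)
  # unknown pattern: prior 0.5 with a warning
  expect_warning(pr <- mdlink:::.pattern_prior(st, "ghost"), "no recorded")
  expect_equal(pr, 0.5)
})

test_that("triplet confidence is the max over contributing patterns", {
  st <- fit_stats(toy_labelled())
  cf <- confidence(st, c("p_good", "p_bad"), "cause")
  expect_equal(cf$confidence, max(cf$posteriors))
  expect_length(cf$posteriors, 2L)
  expect_gt(cf$posteriors[["p_good"]], cf$posteriors[["p_bad"]])
})

mk_triplet <- function(sid, m, d, r, extractor, pids) {
  tibble::tibble(sentence_id = sid, microbe = m, disease = d,
                 relation = stem_word(r), relation_surface = r,
                 extractor = extractor, pattern_ids = pids)
}

test_that("merging unions the streams, keeps the max posterior, thresholds", {
  st <- fit_stats(toy_labelled())
  tpe <- mk_triplet("s1", "x", "y", "causes", "TPE", "p_good")
  dbe <- dplyr::bind_rows(
    mk_triplet("s1", "x", "y", "causes", "DBE", "p_bad"),
    mk_triplet("s1", "x", "y", "appos", "DBE", "p_bad"))
  merged <- merge_extractions(tpe, dbe, st, threshold = 0)
  expect_equal(nrow(merged), 2L)
  shared <- merged[merged$relation == "cause", ]
  expect_equal(shared$pattern_ids, "p_bad,p_good")
  expect_equal(shared$confidence,
               confidence(st, c("p_good", "p_bad"), "cause")$confidence)

  # at threshold 0.5 the unreliable appos triplet is dropped
  merged5 <- merge_extractions(tpe, dbe, st, threshold = 0.5)
  expect_equal(merged5$relation, "cause")

  # threshold 0 is exactly the deduplicated union (of stemmed triplets)
  expect_setequal(paste(merged$microbe, merged$disease, merged$relation),
                  c("x y cause", paste("x y", stem_word("appos"))))
})

test_that("raising the threshold never decreases precision on a scored set", {
  corp <- test_corpus(150)
  ex <- extract_corpus(corp)
  labelled <- label_extractions(dplyr::bind_rows(ex$tpe, ex$dbe),
                                corp$gold_triplets) |> split_provenance()
  st <- fit_stats(labelled)
  gold <- corp$gold_triplets
  prev <- -Inf
  for (thr in c(0, 0.25, 0.5, 0.75)) {
    kept <- merge_extractions(ex$tpe, ex$dbe, st, thr)
    if (nrow(kept) == 0L) break
    key <- function(d) paste(d$sentence_id, d$microbe, d$disease, d$relation)
    prec <- mean(key(kept) %in% key(gold))
    expect_gte(prec, prev - 1e-12)
    prev <- prec
  }
})

test_that("macro scores average per-relation-class metrics over gold classes", {
  gold <- dplyr::bind_rows(
    mk_triplet("s1", "x", "y", "cause", "G", "g"),
    mk_triplet("s2", "x", "z", "associate", "G", "g"))
  # one class perfect, one fully missed -> macro recall 0.5
  pred <- mk_triplet("s1", "x", "y", "cause", "TPE", "p")
  res <- macro_prf(pred, gold)
  expect_equal(res$macro$recall, 0.5)
  expect_equal(nrow(res$by_class), 2L)

  perfect <- macro_prf(gold, gold)
  expect_equal(unlist(perfect$macro), c(precision = 1, recall = 1, f1 = 1))

  # randomized sets agree with a per-class oracle
  set.seed(19)
  rels <- c("cause", "associate", "implicate")
  rand_set <- function(n) tibble::tibble(
    sentence_id = sample(paste0("s", 1:6), n, TRUE),
    microbe = sample(c("m1", "m2"), n, TRUE),
    disease = sample(c("d1", "d2"), n, TRUE),
    relation = sample(rels, n, TRUE)) |> dplyr::distinct()
  for (i in 1:20) {
    gold_r <- rand_set(8); pred_r <- rand_set(8)
    got <- macro_prf(pred_r, gold_r)$macro
    oracle <- vapply(sort(unique(gold_r$relation)), function(cl) {
      key <- function(d) paste(d$sentence_id, d$microbe, d$disease)
      g <- key(gold_r[gold_r$relation == cl, ])
      p <- key(pred_r[pred_r$relation == cl, ])
      tp <- length(intersect(g, p))
      prec <- if (length(p)) tp / length(p) else if (length(g)) 0 else 1
      rec <- if (length(g)) tp / length(g) else 1
      f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      c(prec, rec, f)
    }, numeric(3))
    expect_equal(got$precision, mean(oracle[1, ]))
    expect_equal(got$recall, mean(oracle[2, ]))
    expect_equal(got$f1, mean(oracle[3, ]))
  }
})

test_that("cross-validation folds split at sentence level deterministically", {
  ids <- rep(paste0("s", 1:30), each = 3)
  f1 <- cv_folds(ids, folds = 10L, seed = 4L)
  f2 <- cv_folds(ids, folds = 10L, seed = 4L)
  expect_identical(f1, f2)
  expect_equal(sort(unique(unname(f1))), 1:10)
  # all pairs of one sentence share a fold by construction
  expect_length(f1, 30L)
  f3 <- cv_folds(ids, folds = 10L, seed = 5L)
  expect_false(identical(f1, f3))
})
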