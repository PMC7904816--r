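test_that("lexicon loading applies default canonicalization and catches conflicts", {
  path <- withr::local_tempfile(lines = c(
    "# comment line",
    "Pseudomonas aeruginosa",
    "E. coli\tEscherichia_coli",
    "Escherichia coli\tEscherichia_coli"
  ))
  lex <- load_lexicon(path, "MICROBE")
  expect_equal(lex$canonical[lex$surface == "Pseudomonas aeruginosa"],
               "Pseudomonas_aeruginosa")
  # two surfaces, one canonical
  expect_equal(sum(lex$canonical == "Escherichia_coli"), 2L)

  empty <- withr::local_tempfile(lines = "# only a comment")
  expect_error(load_lexicon(empty, "MICROBE"), "empty lexicon")

  conflict <- withr::local_tempfile(lines = c("E. coli\tEscherichia_coli",
                                              "E. coli\tEnterococcus"))
  expect_error(load_lexicon(conflict, "MICROBE"), "E. coli")
})

test_that("tagging collapses mentions into prefixed single tokens", {
  s <- tag_entities(
    "Pseudomonas aeruginosa is a pathogen that frequently causes acute lung injury.",
    tiny_microbe_lex(), tiny_disease_lex())
  expect_true("BAC00Pseudomonas_aeruginosa" %in% s$tokens)
  expect_true("DIS00acute_lung_injury" %in% s$tokens)
  expect_equal(nrow(s$mentions), 2L)
  expect_setequal(s$mentions$entity_class, c("MICROBE", "DISEASE"))
  # tagged tokens sit at the recorded positions
  expect_equal(s$tokens[s$mentions$token], s$mentions$tagged_token)
})

test_that("a sentence with no lexicon hits has zero mentions", {
  s <- tag_entities("the patient recovered", tiny_microbe_lex(),
                    tiny_disease_lex())
  expect_equal(nrow(s$mentions), 0L)
  expect_equal(s$tokens, c("the", "patient", "recovered"))
})

test_that("longest match wins over a shorter prefix entry", {
  s <- tag_entities("Escherichia coli was cultured", tiny_microbe_lex(),
                    tiny_disease_lex())
  expect_equal(nrow(s$mentions), 1L)
  expect_equal(s$mentions$canonical, "Escherichia_coli")

  # exhaustive check against all candidate spans: no retained span may be
  # extendable to a longer lexicon match starting at the same token
  toks <- tolower(md_tokenize("Escherichia coli was cultured"))
  lex <- tiny_microbe_lex()
  spans <- vapply(lex$tokens, paste, "", collapse = " ")
  hits <- vapply(seq_along(toks), function(i) {
    lens <- which(vapply(seq_along(toks) - i + 1L, function(L) {
      L >= 1L && paste(toks[i:(i + L - 1L)], collapse = " ") %in% spans
    }, TRUE))
    if (length(lens)) max(lens) else 0L
  }, 0L)
  expect_equal(max(hits), 2L)  # the two-token match is the longest anywhere
})

test_that("tagging is idempotent and mention spans are disjoint", {
  corp <- test_corpus(60)
  for (p in corp$parsed[1:25]) {
    s <- p$sentence
    again <- tag_entities(paste(s$tokens, collapse = " "), corp$microbe_lex,
                          corp$disease_lex, sentence_id = s$sentence_id)
    expect_equal(again$tokens, s$tokens)  # collapsed mentions stay collapsed
  }
  # disjoint original spans on a dense sentence
  s <- tag_entities("Vibrio vulnificus vulnificus sepsis sepsis",
                    tiny_microbe_lex(), tiny_disease_lex())
  spans <- mapply(seq, s$mentions$orig_start, s$mentions$orig_end,
                  SIMPLIFY = FALSE)
  expect_equal(anyDuplicated(unlist(spans)), 0L)
})

test_that("microbe-first priority resolves cross-class overlaps", {
  mic <- lexicon("wound infection", "MICROBE")  # artificial overlap
  dis <- lexicon("infection", "DISEASE")
  s <- tag_entities("severe wound infection", mic, dis)
  expect_equal(s$mentions$entity_class, "MICROBE")
  s2 <- tag_entities("severe wound infection", mic, dis,
                     priority = "disease")
  expect_true("DISEASE" %in% s2$mentions$entity_class)
})

test_that("all-uppercase single-token entries match case-sensitively", {
  mic <- lexicon(c("MRSA", "Vibrio"), "MICROBE")
  dis <- lexicon("sepsis", "DISEASE")
  hit <- tag_entities("MRSA caused sepsis", mic, dis)
  expect_true("BAC00MRSA" %in% hit$tokens)
  miss <- tag_entities("mrsa caused sepsis", mic, dis)
  expect_false(any(startsWith(miss$tokens, "BAC00")))
  # ordinary entries stay case-insensitive
  expect_true("BAC00Vibrio" %in% tag_entities("VIBRIO sp.", mic, dis)$tokens)
})

test_that("annotated sentences round-trip through JSON lines", {
  corp <- test_corpus(60)
  sents <- lapply(corp$parsed[1:5], `[[`, "sentence")
  path <- withr::local_tempfile()
  write_annotated(sents, path)
  back <- read_annotated(path)
  expect_equal(length(back), 5L)
  for (i in 1:5) {
    expect_equal(back[[i]]$tokens, sents[[i]]$tokens)
    expect_equal(back[[i]]$mentions$canonical, sents[[i]]$mentions$canonical)
  }
})

test_that("surface text reconstructs the original token stream", {
  corp <- test_corpus(60)
  for (p in corp$parsed[1:20]) {
    s <- p$sentence
    # substitute each mention's surface back in, retokenize, and compare
    # with tokenizing the original surface sentence
    toks <- s$tokens
    toks[s$mentions$token] <- s$mentions$surface
    rebuilt <- md_tokenize(paste(toks, collapse = " "))
    expect_equal(rebuilt, md_tokenize(s$text))
  }
})

test_that("stemming matches the printed relation-word stems and is idempotent", {
  expect_equal(stem_word("causes"), "cause")
  expect_equal(stem_word("associated"), "associate")
  expect_equal(stem_word("implicated"), "implicate")
  expect_equal(stem_word("common_cause"), "common_cause")
  words <- c("causes", "caused", "causing", "induces", "induced", "triggers",
             "associated", "implicated", "linked", "cause", "sources",
             "drivers", "is", "was", "infections")
  stems <- stem_word(words)
  expect_equal(stem_word(stems), stems)  # idempotent on this vocabulary
})
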