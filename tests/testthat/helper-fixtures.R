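# shared in-code fixtures: tiny lexicons, the worked-example sentences with
# gold trees, and a memoized mid-size synthetic corpus

tiny_microbe_lex <- function() {
  lexicon(c("Pseudomonas aeruginosa", "Vibrio vulnificus", "vulnificus",
            "Escherichia", "Escherichia coli", "Helicobacter pylori"),
          "MICROBE")
}

tiny_disease_lex <- function() {
  lexicon(c("acute lung injury", "infection", "sepsis", "gastritis",
            "pneumonia"), "DISEASE")
}

mk_sentence <- function(id, tokens, mention_tokens, classes, canonicals) {
  mentions <- tibble::tibble(
    entity_class = classes, token = as.integer(mention_tokens),
    canonical = canonicals, tagged_token = tokens[mention_tokens],
    surface = canonicals, orig_start = NA_integer_, orig_end = NA_integer_
  )
  structure(list(sentence_id = id, tokens = tokens, mentions = mentions,
                 text = paste(tokens, collapse = " ")),
            class = "mdlink_sentence")
}

# "additionally , in otherwise healthy people , vulnificus causes wound
#  infection that can require amputation or lead to sepsis": 1 microbe and
# 2 disease mentions; the gold dependency tree routes the microbe-infection
# path through "causes" and "wound"
vulnificus_parsed <- function() {
  toks <- c("additionally", ",", "in", "otherwise", "healthy", "people", ",",
            "BAC00vulnificus", "causes", "wound", "DIS00infection", "that",
            "can", "require", "amputation", "or", "lead", "to", "DIS00sepsis")
  sent <- mk_sentence("vuln", toks, c(8L, 11L, 19L),
                      c("MICROBE", "DISEASE", "DISEASE"),
                      c("vulnificus", "infection", "sepsis"))
  ct <- parse_bracketed(paste0(
    "(S (ADVP (RB additionally)) (, ,) ",
    "(PP (IN in) (NP (RB otherwise) (JJ healthy) (NNS people))) (, ,) ",
    "(NP (NN BAC00vulnificus)) ",
    "(VP (VBZ causes) (NP (NN wound) (NN DIS00infection) ",
    "(SBAR (WDT that) (S (VP (MD can) (VP (VB require) (NP (NN amputation)) ",
    "(CC or) (VP (VB lead) (PP (TO to) (NP (NN DIS00sepsis)))))))))) )"))
  dt <- dtree(toks,
    head   = c(9, 9, 6, 5, 6, 9, 9, 9, 0, 9, 10, 14, 14, 11, 14, 17, 14, 19, 17),
    deprel = c("advmod", "punct", "case", "advmod", "amod", "obl", "punct",
               "nsubj", "root", "obj", "dep", "nsubj", "aux", "acl:relcl",
               "obj", "cc", "conj:or", "case", "obl"))
  parsed_sentence(sent, ct, dt)
}

# appositive + passive-participle sentence in the shape of the worked
# pattern-matching example: both shipped TPE patterns fire exactly once
fig3_parsed <- function() {
  toks <- c("BAC00Klebsiella_pneumoniae", ",", "a", "common", "cause", "of",
            "DIS00sepsis", ",", "is", "associated", "with", "DIS00pneumonia",
            ".")
  sent <- mk_sentence("fig3", toks, c(1L, 7L, 12L),
                      c("MICROBE", "DISEASE", "DISEASE"),
                      c("Klebsiella_pneumoniae", "sepsis", "pneumonia"))
  ct <- parse_bracketed(paste0(
    "(S (NP (NN BAC00Klebsiella_pneumoniae)) (, ,) ",
    "(NP (DT a) (JJ common) (NN cause) (PP (IN of) (NP (NN DIS00sepsis)))) ",
    "(, ,) (VP (VBZ is) (VBN associated) ",
    "(PP (IN with) (NP (NN DIS00pneumonia)))) (. .))"))
  dt <- dtree(toks,
    head   = c(10, 5, 5, 5, 1, 7, 5, 5, 10, 0, 12, 10, 10),
    deprel = c("nsubj:pass", "punct", "det", "amod", "appos", "case",
               "nmod:of", "punct", "aux:pass", "root", "case", "obl:with",
               "punct"))
  parsed_sentence(sent, ct, dt)
}

# "BAC00Stenotrophomonas_maltophilia is an emerging pathogen implicated in
#  an increasing number of DIS00severe_pulmonary_infections ."
steno_parsed <- function() {
  toks <- c("BAC00Stenotrophomonas_maltophilia", "is", "an", "emerging",
            "pathogen", "implicated", "in", "an", "increasing", "number",
            "of", "DIS00severe_pulmonary_infections", ".")
  sent <- mk_sentence("steno", toks, c(1L, 12L), c("MICROBE", "DISEASE"),
                      c("Stenotrophomonas_maltophilia",
                        "severe_pulmonary_infections"))
  ct <- parse_bracketed(paste0(
    "(S (NP (NN BAC00Stenotrophomonas_maltophilia)) (VP (VBZ is) ",
    "(NP (NP (DT an) (JJ emerging) (NN pathogen)) (VP (VBN implicated) ",
    "(PP (IN in) (NP (NP (DT an) (JJ increasing) (NN number)) ",
    "(PP (IN of) (NP (NN DIS00severe_pulmonary_infections)))))))) (. .))"))
  dt <- dtree(toks,
    head   = c(5, 5, 5, 5, 0, 5, 10, 10, 10, 6, 12, 10, 5),
    deprel = c("nsubj", "cop", "det", "amod", "root", "acl", "case", "det",
               "amod", "obl", "case", "nmod:of", "punct"))
  parsed_sentence(sent, ct, dt)
}

# "BAC00Streptococcus_pneumoniae , the pneumococcus , is the most common
#  cause of DIS00sepsis and DIS00meningitis ."
strep_parsed <- function() {
  toks <- c("BAC00Streptococcus_pneumoniae", ",", "the", "pneumococcus", ",",
            "is", "the", "most", "common", "cause", "of", "DIS00sepsis",
            "and", "DIS00meningitis", ".")
  sent <- mk_sentence("strep", toks, c(1L, 12L, 14L),
                      c("MICROBE", "DISEASE", "DISEASE"),
                      c("Streptococcus_pneumoniae", "sepsis", "meningitis"))
  ct <- parse_bracketed(paste0(
    "(S (NP (NP (NN BAC00Streptococcus_pneumoniae)) (, ,) ",
    "(NP (DT the) (NN pneumococcus)) (, ,)) (VP (VBZ is) ",
    "(NP (NP (DT the) (RBS most) (JJ common) (NN cause)) (PP (IN of) ",
    "(NP (NP (NN DIS00sepsis)) (CC and) (NP (NN DIS00meningitis)))))) (. .))"))
  dt <- dtree(toks,
    head   = c(10, 4, 4, 1, 4, 10, 10, 9, 10, 0, 12, 10, 14, 12, 10),
    deprel = c("nsubj", "punct", "det", "appos", "punct", "cop", "det",
               "advmod", "amod", "root", "case", "nmod:of", "cc", "conj:and",
               "punct"))
  parsed_sentence(sent, ct, dt)
}

# memoized mid-size corpus shared across test files
.test_corpus_cache <- new.env(parent = emptyenv())
test_corpus <- function(n = 150L, seed = 7L) {
  key <- paste0("n", n, "_s", seed)
  if (is.null(.test_corpus_cache[[key]])) {
    .test_corpus_cache[[key]] <- generate_corpus(
      fixtures_config(n_sentences = n, seed = seed))
  }
  .test_corpus_cache[[key]]
}

test_embeddings <- function() random_embeddings(200L, 42L)

# small detector configuration for fast unit tests (full architecture is
# exercised separately with the default sizes)
small_config <- function(...) {
  detector_config(hidden = 4L, word_dim = 8L, pos_dim = 3L, dep_dim = 3L,
                  seg_time_steps = 6L, sdp_time_steps = 4L, epochs = 2L, ...)
}
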