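#' Synthetic corpus configuration
#'
#' The generator emulates the statistical shape of a manually annotated
#' microbe-disease corpus: roughly a thousand sentences in which some 60%
#' of candidate entity pairs assert an association, built from a handful of
#' construction families (active relation verb, passive participle,
#' appositive set off by commas, copular of-chunk, coordinated diseases)
#' plus non-asserting co-mention distractors. Gold constituency and
#' dependency trees are emitted from hand-written schemas per template, so
#' every pipeline stage can be tested without an external parser.
#'
#' @param n_sentences Number of sentences.
#' @param positive_fraction Fraction of sentences asserting a relation.
#' @param noise Fraction of positive sentences whose relation word is
#'   swapped for an out-of-inventory synonym, making detector metrics
#'   non-degenerate.
#' @param n_microbes,n_diseases Vocabulary sizes (extra names are
#'   synthesized when the built-in inventories run out).
#' @param seed RNG seed; identical seeds yield byte-identical bundles.
#' @return A `fixtures_config` list.
#' @export
fixtures_config <- function(n_sentences = 1000L, positive_fraction = 0.6,
                            noise = 0.1, n_microbes = 20L, n_diseases = 16L,
                            seed = 7L) {
  stopifnot(n_sentences >= 1L, positive_fraction >= 0, positive_fraction <= 1,
            noise >= 0, noise <= 1, n_microbes >= 1L)
  if (n_diseases < 2L) {
    stop("the coordination template needs at least two distinct diseases")
  }
  structure(list(n_sentences = as.integer(n_sentences),
                 positive_fraction = positive_fraction, noise = noise,
                 n_microbes = as.integer(n_microbes),
                 n_diseases = as.integer(n_diseases), seed = as.integer(seed)),
            class = "fixtures_config")
}

.builtin_microbes <- c(
  "Helicobacter pylori", "Escherichia coli", "Pseudomonas aeruginosa",
  "Streptococcus pneumoniae", "Staphylococcus aureus", "Klebsiella pneumoniae",
  "Haemophilus influenzae", "Mycobacterium tuberculosis",
  "Clostridium difficile", "Moraxella catarrhalis", "Vibrio vulnificus",
  "Stenotrophomonas maltophilia", "Listeria monocytogenes",
  "Campylobacter jejuni", "Salmonella enterica", "Bacteroides fragilis",
  "Enterococcus faecalis", "Neisseria meningitidis",
  "Chlamydophila pneumoniae", "Fusobacterium nucleatum")

.builtin_diseases <- c(
  "gastritis", "pneumonia", "sepsis", "meningitis", "otitis media",
  "cystic fibrosis", "bacteremia", "endocarditis", "periodontitis",
  "sinusitis", "gastroenteritis", "colitis", "peritonitis", "osteomyelitis",
  "acute lung injury", "stomach neoplasms")

.take_names <- function(builtin, n, synth_prefix) {
  if (n <= length(builtin)) return(builtin[seq_len(n)])
  c(builtin, paste(synth_prefix, seq_len(n - length(builtin))))
}

# ---- template schemas ---------------------------------------------------
# each returns tokens (tagged), a bracketed constituency tree string, a
# dependency tree, the planted relation word (surface), and the pair labels

.tpl_active <- function(B, D, verb) {
  toks <- c(B, verb, D, "in", "hospitalized", "patients", ".")
  ct <- sprintf(paste0("(S (NP (NN %s)) (VP (VBZ %s) (NP (NN %s)) ",
                       "(PP (IN in) (NP (JJ hospitalized) (NNS patients)))) (. .))"),
                B, verb, D)
  dt <- dtree(toks, head = c(2, 0, 2, 6, 6, 2, 2),
              deprel = c("nsubj", "root", "obj", "case", "amod", "obl", "punct"),
              upos = c("NN", "VBZ", "NN", "IN", "JJ", "NNS", "."))
  list(tokens = toks, ctree = ct, dtree = dt, relation = verb)
}

.tpl_adverb <- function(B, D, verb) {
  toks <- c("Moreover", ",", B, verb, D, ".")
  ct <- sprintf("(S (ADVP (RB Moreover)) (, ,) (NP (NN %s)) (VP (VBZ %s) (NP (NN %s))) (. .))",
                B, verb, D)
  dt <- dtree(toks, head = c(4, 4, 4, 0, 4, 4),
              deprel = c("advmod", "punct", "nsubj", "root", "obj", "punct"),
              upos = c("RB", ",", "NN", "VBZ", "NN", "."))
  list(tokens = toks, ctree = ct, dtree = dt, relation = verb)
}

.tpl_participle <- function(B, D, vbn, prep) {
  toks <- c(B, "is", vbn, prep, D, ".")
  ct <- sprintf("(S (NP (NN %s)) (VP (VBZ is) (VBN %s) (PP (IN %s) (NP (NN %s)))) (. .))",
                B, vbn, prep, D)
  dt <- dtree(toks, head = c(3, 3, 0, 5, 3, 3),
              deprel = c("nsubj:pass", "aux:pass", "root", "case",
                         paste0("obl:", prep), "punct"),
              upos = c("NN", "VBZ", "VBN", "IN", "NN", "."))
  list(tokens = toks, ctree = ct, dtree = dt, relation = vbn)
}

.tpl_appositive <- function(B, D, noun, amod = "common") {
  toks <- c(B, ",", "a", amod, noun, "of", D, ",", "was", "reported", ".")
  ct <- sprintf(paste0("(S (NP (NN %s)) (, ,) (NP (DT a) (JJ %s) (NN %s) ",
                       "(PP (IN of) (NP (NN %s)))) (, ,) ",
                       "(VP (VBD was) (VBN reported)) (. .))"),
                B, amod, noun, D)
  dt <- dtree(toks, head = c(10, 5, 5, 5, 1, 7, 5, 5, 10, 0, 10),
              deprel = c("nsubj:pass", "punct", "det", "amod", "appos",
                         "case", "nmod:of", "punct", "aux:pass", "root", "punct"),
              upos = c("NN", ",", "DT", "JJ", "NN", "IN", "NN", ",", "VBD", "VBN", "."))
  list(tokens = toks, ctree = ct, dtree = dt, relation = noun)
}

.tpl_copular <- function(B, D, noun, amod = "common") {
  toks <- c(B, "is", "the", "most", amod, noun, "of", D, ".")
  ct <- sprintf(paste0("(S (NP (NN %s)) (VP (VBZ is) (NP (NP (DT the) (RBS most) ",
                       "(JJ %s) (NN %s)) (PP (IN of) (NP (NN %s))))) (. .))"),
                B, amod, noun, D)
  dt <- dtree(toks, head = c(6, 6, 6, 5, 6, 0, 8, 6, 6),
              deprel = c("nsubj", "cop", "det", "advmod", "amod", "root",
                         "case", "nmod:of", "punct"),
              upos = c("NN", "VBZ", "DT", "RBS", "JJ", "NN", "IN", "NN", "."))
  list(tokens = toks, ctree = ct, dtree = dt,
       relation = paste(amod, noun, sep = "_"))
}

.tpl_coord <- function(B, D, D2, noun, amod = "common") {
  toks <- c(B, "is", "the", "most", amod, noun, "of", D, "and", D2, ".")
  ct <- sprintf(paste0("(S (NP (NN %s)) (VP (VBZ is) (NP (NP (DT the) (RBS most) ",
                       "(JJ %s) (NN %s)) (PP (IN of) (NP (NP (NN %s)) (CC and) ",
                       "(NP (NN %s)))))) (. .))"),
                B, amod, noun, D, D2)
  dt <- dtree(toks, head = c(6, 6, 6, 5, 6, 0, 8, 6, 10, 8, 6),
              deprel = c("nsubj", "cop", "det", "advmod", "amod", "root",
                         "case", "nmod:of", "cc", "conj:and", "punct"),
              upos = c("NN", "VBZ", "DT", "RBS", "JJ", "NN", "IN", "NN",
                       "CC", "NN", "."))
  list(tokens = toks, ctree = ct, dtree = dt,
       relation = paste(amod, noun, sep = "_"))
}

.tpl_neg_coord <- function(B, D) {
  toks <- c(B, "and", D, "were", "discussed", "in", "the", "recent",
            "review", ".")
  ct <- sprintf(paste0("(S (NP (NP (NN %s)) (CC and) (NP (NN %s))) ",
                       "(VP (VBD were) (VBN discussed) (PP (IN in) ",
                       "(NP (DT the) (JJ recent) (NN review)))) (. .))"),
                B, D)
  dt <- dtree(toks, head = c(5, 3, 1, 5, 0, 9, 9, 9, 5, 5),
              deprel = c("nsubj:pass", "cc", "conj:and", "aux:pass", "root",
                         "case", "det", "amod", "obl", "punct"),
              upos = c("NN", "CC", "NN", "VBD", "VBN", "IN", "DT", "JJ",
                       "NN", "."))
  list(tokens = toks, ctree = ct, dtree = dt, relation = NA_character_)
}

.tpl_neg_screen <- function(B, D) {
  toks <- c("Patients", "with", D, "were", "screened", "for", B, ".")
  ct <- sprintf(paste0("(S (NP (NNS Patients) (PP (IN with) (NP (NN %s)))) ",
                       "(VP (VBD were) (VBN screened) (PP (IN for) ",
                       "(NP (NN %s)))) (. .))"), D, B)
  dt <- dtree(toks, head = c(5, 3, 1, 5, 0, 7, 5, 5),
              deprel = c("nsubj:pass", "case", "nmod:with", "aux:pass",
                         "root", "case", "obl", "punct"),
              upos = c("NNS", "IN", "NN", "VBD", "VBN", "IN", "NN", "."))
  list(tokens = toks, ctree = ct, dtree = dt, relation = NA_character_)
}

.tpl_neg_clause <- function(B, D) {
  toks <- c(B, "was", "cultured", "from", "samples", ",", "whereas", D,
            "was", "assessed", "separately", ".")
  ct <- sprintf(paste0("(S (S (NP (NN %s)) (VP (VBD was) (VBN cultured) ",
                       "(PP (IN from) (NP (NNS samples))))) (, ,) ",
                       "(SBAR (IN whereas) (S (NP (NN %s)) (VP (VBD was) ",
                       "(VBN assessed) (ADVP (RB separately))))) (. .))"), B, D)
  dt <- dtree(toks, head = c(3, 3, 0, 5, 3, 10, 10, 10, 10, 3, 10, 3),
              deprel = c("nsubj:pass", "aux:pass", "root", "case", "obl",
                         "punct", "mark", "nsubj:pass", "aux:pass", "advcl",
                         "advmod", "punct"),
              upos = c("NN", "VBD", "VBN", "IN", "NNS", ",", "IN", "NN",
                       "VBD", "VBN", "RB", "."))
  list(tokens = toks, ctree = ct, dtree = dt, relation = NA_character_)
}

# clean relation inventories and their out-of-inventory "noise" synonyms;
# the noise pools are wide enough that a corrupted relation word essentially
# never recurs, so it stays unseen for a detector trained on the other folds
.verb_active <- c("causes", "induces", "triggers")
.verb_active_noise <- c(
  "provokes", "precipitates", "aggravates", "elicits", "generates",
  "accelerates", "underlies", "drives", "fuels", "worsens", "instigates",
  "engenders", "potentiates", "amplifies", "evokes", "fosters", "incites",
  "perpetuates", "propagates", "exacerbates")
.vbn_prep <- list(c("associated", "with"), c("implicated", "in"))
.vbn_prep_noise <- list(
  c("correlated", "with"), c("entangled", "in"), c("intertwined", "with"),
  c("interlinked", "with"), c("enmeshed", "in"), c("affiliated", "with"),
  c("interrelated", "with"), c("interwoven", "with"), c("coupled", "with"),
  c("conflated", "with"), c("cooccurring", "with"), c("codetected", "in"),
  c("coenriched", "in"), c("overrepresented", "in"), c("clustered", "with"),
  c("comingled", "with"))
# non-asserting verbs reusing the positive construction shapes, so the
# label is decided by the relation word, not by sentence structure alone
.verb_neg_active <- c("accompanies", "parallels", "predates")
.vbn_prep_neg <- list(c("detected", "in"), c("measured", "in"))
.appos_noun <- c("cause", "source")
.appos_noun_noise <- c(
  "driver", "contributor", "determinant", "instigator", "culprit",
  "mediator", "modulator", "catalyst", "facilitator", "promoter",
  "amplifier", "originator", "precursor", "perpetrator", "accelerant",
  "potentiator")

#' Generate a synthetic annotated corpus
#'
#' Deterministic under `config$seed`: the same configuration always yields
#' an identical bundle. Positive sentences instantiate one of five
#' relation-asserting construction templates with a planted relation word;
#' negative sentences co-mention a microbe and a disease without asserting
#' a relation. Gold parse trees follow hand-written schemas per template.
#'
#' @param config A [fixtures_config()].
#' @return An `mdlink_corpus`: list with `parsed` (list of `mdlink_parsed`),
#'   `texts` (tibble `sentence_id`, `text` -- the untagged surface
#'   sentences), `gold_pairs` (tibble `sentence_id`, `microbe`, `disease`,
#'   `label`, `relation` -- stemmed gold relation word, `NA` for negative
#'   pairs), `gold_triplets`, `microbe_lex`, `disease_lex`, `config`.
#' @export
generate_corpus <- function(config = fixtures_config()) {
  mic_surface <- .take_names(.builtin_microbes, config$n_microbes,
                             "Microbacterium strain")
  dis_surface <- .take_names(.builtin_diseases, config$n_diseases, "syndrome")
  microbe_lex <- lexicon(mic_surface, "MICROBE")
  disease_lex <- lexicon(dis_surface, "DISEASE")

  pos_templates <- c("active", "adverb", "participle", "appositive",
                     "copular", "coord")
  neg_templates <- c("neg_coord", "neg_screen", "neg_clause", "neg_active",
                     "neg_participle")

  res <- withr::with_seed(config$seed, {
    parsed <- vector("list", config$n_sentences)
    texts <- character(config$n_sentences)
    pair_rows <- vector("list", config$n_sentences)
    for (i in seq_len(config$n_sentences)) {
      sid <- sprintf("s%04d", i)
      positive <- stats::runif(1) < config$positive_fraction
      mic <- microbe_lex[sample.int(nrow(microbe_lex), 1L), ]
      dpick <- disease_lex[sample.int(nrow(disease_lex), 2L), ]
      B <- paste0("BAC00", mic$canonical)
      D <- paste0("DIS00", dpick$canonical[1L])
      D2 <- paste0("DIS00", dpick$canonical[2L])
      noisy <- positive && stats::runif(1) < config$noise

      if (positive) {
        tpl <- sample(pos_templates, 1L)
        inst <- switch(tpl,
          active = .tpl_active(B, D, sample(if (noisy) .verb_active_noise
                                            else .verb_active, 1L)),
          adverb = .tpl_adverb(B, D, sample(if (noisy) .verb_active_noise
                                            else .verb_active, 1L)),
          participle = {
            pool <- if (noisy) .vbn_prep_noise else .vbn_prep
            vp <- pool[[sample.int(length(pool), 1L)]]
            .tpl_participle(B, D, vp[[1L]], vp[[2L]])
          },
          appositive = .tpl_appositive(B, D, sample(if (noisy) .appos_noun_noise
                                                    else .appos_noun, 1L)),
          copular = .tpl_copular(B, D, sample(if (noisy) .appos_noun_noise
                                              else .appos_noun, 1L)),
          coord = .tpl_coord(B, D, D2, sample(if (noisy) .appos_noun_noise
                                              else .appos_noun, 1L))
        )
        diseases <- if (tpl == "coord") dpick$canonical else dpick$canonical[1L]
        pair_rows[[i]] <- tibble::tibble(
          sentence_id = sid, microbe = mic$canonical, disease = diseases,
          label = 1L, relation = stem_word(inst$relation)
        )
      } else {
        tpl <- sample(neg_templates, 1L)
        inst <- switch(tpl,
          neg_coord = .tpl_neg_coord(B, D),
          neg_screen = .tpl_neg_screen(B, D),
          neg_clause = .tpl_neg_clause(B, D),
          neg_active = .tpl_active(B, D, sample(.verb_neg_active, 1L)),
          neg_participle = {
            vp <- .vbn_prep_neg[[sample.int(length(.vbn_prep_neg), 1L)]]
            .tpl_participle(B, D, vp[[1L]], vp[[2L]])
          }
        )
        inst$relation <- NA_character_
        pair_rows[[i]] <- tibble::tibble(
          sentence_id = sid, microbe = mic$canonical,
          disease = dpick$canonical[1L], label = 0L,
          relation = NA_character_
        )
      }

      sent <- .corpus_sentence(sid, inst$tokens, microbe_lex, disease_lex)
      parsed[[i]] <- parsed_sentence(sent, parse_bracketed(inst$ctree),
                                     inst$dtree)
      texts[i] <- .surface_text(inst$tokens, microbe_lex, disease_lex)
    }
    list(parsed = parsed, texts = texts,
         gold_pairs = dplyr::bind_rows(pair_rows))
  })

  gold_triplets <- res$gold_pairs |>
    dplyr::filter(.data$label == 1L) |>
    dplyr::select("sentence_id", "microbe", "disease", "relation")
  structure(list(parsed = res$parsed,
                 texts = tibble::tibble(
                   sentence_id = vapply(res$parsed, function(p) p$sentence$sentence_id, ""),
                   text = res$texts),
                 gold_pairs = res$gold_pairs, gold_triplets = gold_triplets,
                 microbe_lex = microbe_lex, disease_lex = disease_lex,
                 config = config),
            class = "mdlink_corpus")
}

# build the annotated sentence for a template token stream
.corpus_sentence <- function(sid, tokens, microbe_lex, disease_lex) {
  rows <- list()
  for (t in seq_along(tokens)) {
    tok <- tokens[[t]]
    if (startsWith(tok, "BAC00") || startsWith(tok, "DIS00")) {
      cls <- if (startsWith(tok, "BAC00")) "MICROBE" else "DISEASE"
      lex <- if (cls == "MICROBE") microbe_lex else disease_lex
      canonical <- strip_entity_tag(tok)
      surf <- lex$surface[match(canonical, lex$canonical)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        entity_class = cls, token = t, canonical = canonical,
        tagged_token = tok, surface = surf,
        orig_start = NA_integer_, orig_end = NA_integer_
      )
    }
  }
  mentions <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(entity_class = character(), token = integer(),
                   canonical = character(), tagged_token = character(),
                   surface = character(), orig_start = integer(),
                   orig_end = integer())
  structure(list(sentence_id = sid, tokens = tokens, mentions = mentions,
                 text = .surface_text(tokens, microbe_lex, disease_lex)),
            class = "mdlink_sentence")
}

.surface_text <- function(tokens, microbe_lex, disease_lex) {
  out <- vapply(tokens, function(tok) {
    if (startsWith(tok, "BAC00")) {
      microbe_lex$surface[match(strip_entity_tag(tok), microbe_lex$canonical)]
    } else if (startsWith(tok, "DIS00")) {
      disease_lex$surface[match(strip_entity_tag(tok), disease_lex$canonical)]
    } else tok
  }, "")
  paste(out, collapse = " ")
}

#' @export
print.mdlink_corpus <- function(x, ...) {
  cat(sprintf("<mdlink_corpus: %d sentences, %d gold pairs (%d positive)>\n",
              length(x$parsed), nrow(x$gold_pairs),
              sum(x$gold_pairs$label == 1L)))
  invisible(x)
}

#' Candidate pairs and labels of a corpus
#'
#' Enumerates candidate pairs for every sentence and aligns them with the
#' gold pair labels.
#'
#' @param corpus An `mdlink_corpus`.
#' @return List with `pairs` (list of `mdlink_pair`) and `labels` (0/1).
#' @export
corpus_pairs <- function(corpus) {
  pairs <- unlist(lapply(corpus$parsed, enumerate_pairs), recursive = FALSE)
  key <- vapply(pairs, function(p) paste(p$sentence_id, p$microbe, p$disease,
                                         sep = "\r"), "")
  gp <- corpus$gold_pairs
  gold_key <- paste(gp$sentence_id, gp$microbe, gp$disease, sep = "\r")
  labels <- gp$label[match(key, gold_key)]
  if (anyNA(labels)) stop("candidate pairs and gold pairs disagree")
  list(pairs = pairs, labels = as.integer(labels))
}

#' Write a corpus bundle to a directory
#'
#' Layout: `sentences.tsv` (id, untagged text), `microbes.tsv`,
#' `diseases.tsv` (lexicons), `trees.mrg`, `trees.conllu` (gold parses in
#' corpus order), `gold_pairs.tsv`, `gold_triplets.tsv`.
#'
#' @param corpus An `mdlink_corpus`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(paste(corpus$texts$sentence_id, corpus$texts$text, sep = "\t"),
             file.path(dir, "sentences.tsv"), useBytes = TRUE)
  write_lexicon(corpus$microbe_lex, file.path(dir, "microbes.tsv"))
  write_lexicon(corpus$disease_lex, file.path(dir, "diseases.tsv"))
  writeLines(vapply(corpus$parsed, function(p) write_bracketed(p$ctree), ""),
             file.path(dir, "trees.mrg"), useBytes = TRUE)
  write_conllu(lapply(corpus$parsed, `[[`, "dtree"),
               file.path(dir, "trees.conllu"))
  utils::write.table(corpus$gold_pairs, file.path(dir, "gold_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$gold_triplets, file.path(dir, "gold_triplets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
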