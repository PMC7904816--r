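mentions_for <- function(parsed) parsed$sentence$mentions

test_that("of/with chunking merges the governing word's modifiers", {
  p <- strep_parsed()
  ck <- chunk(p$dtree, mentions_for(p))
  expect_true("common_cause" %in% ck$nodes$form)
  # entity stays a separate node governed by the merged chunk
  sepsis <- ck$nodes[ck$nodes$canonical %in% "sepsis", ]
  expect_equal(ck$nodes$form[ck$nodes$node_id == sepsis$head], "common_cause")
  # every original token sits in exactly one node
  expect_setequal(unlist(ck$nodes$tokens), seq_len(nrow(p$dtree)))
  expect_equal(anyDuplicated(unlist(ck$nodes$tokens)), 0L)
})

test_that("trees without of/with or compound context are left unchanged", {
  d <- dtree(c("BAC00x", "causes", "DIS00y"), c(2, 0, 2),
             c("nsubj", "root", "obj"))
  m <- tibble::tibble(entity_class = c("MICROBE", "DISEASE"),
                      token = c(1L, 3L), canonical = c("x", "y"))
  ck <- chunk(d, m)
  expect_equal(nrow(ck$nodes), 3L)
  expect_equal(ck$nodes$form, d$form)
})

test_that("nested merges preserve single-headedness and acyclicity", {
  # "a growing common cause of DIS00x": two amod merges into the same head
  d <- dtree(c("growing", "common", "cause", "of", "DIS00x"),
             head = c(3, 3, 0, 5, 3),
             deprel = c("amod", "amod", "root", "case", "nmod:of"))
  m <- tibble::tibble(entity_class = "DISEASE", token = 5L, canonical = "x")
  ck <- chunk(d, m)
  expect_true("growing_common_cause" %in% ck$nodes$form)
  expect_equal(sum(ck$nodes$head == 0L), 1L)
  # still a tree: chains terminate
  head <- mdlink:::.chunk_head(ck)
  for (id in ck$nodes$node_id) {
    seen <- integer(0); j <- id
    while (j != 0L) { expect_false(j %in% seen); seen <- c(seen, j); j <- head[j] }
  }
})

test_that("tree distance skips coordination-type edges and is symmetric", {
  # path of 3 plain edges
  d <- dtree(c("a", "b", "c", "d"), c(2, 3, 4, 0),
             c("nsubj", "obl", "acl", "root"))
  ck <- chunk(d, NULL)
  expect_equal(tree_distance(ck, 1L, 4L), 3L)
  expect_equal(tree_distance(ck, 4L, 1L), 3L)
  expect_equal(tree_distance(ck, 2L, 2L), 0L)

  # 2 plain + 3 conj:and edges count as 2
  d2 <- dtree(paste0("w", 1:6), head = c(2, 3, 4, 5, 6, 0),
              deprel = c("conj:and", "conj:and", "conj:and", "nsubj", "obl",
                         "root"))
  ck2 <- chunk(d2, NULL)
  expect_equal(tree_distance(ck2, 1L, 6L), 2L)
})

test_that("tree distance matches the igraph path oracle on random pairs", {
  corp <- test_corpus(150)
  uncounted <- c("conj", "conj:and", "conj:or", "compound", "appos")
  set.seed(13)
  for (p in sample(corp$parsed, 40)) {
    ck <- chunk(p$dtree, mentions_for(p))
    ids <- ck$nodes$node_id
    ab <- sample(ids, 2L)
    expect_equal(tree_distance(ck, ab[1], ab[2]),
                 oracle_distance(ck, ab[1], ab[2], uncounted))
  }
})

test_that("preposition rule extracts listed connectors only", {
  mk <- function(deprel_edge, case_form = NULL) {
    if (is.null(case_form)) {
      d <- dtree(c("BAC00x", "DIS00y"), c(0, 1), c("root", deprel_edge))
    } else {
      d <- dtree(c("BAC00x", case_form, "DIS00y"), c(0, 3, 1),
                 c("root", "case", deprel_edge))
    }
    m <- tibble::tibble(entity_class = c("MICROBE", "DISEASE"),
                        token = c(1L, nrow(d)), canonical = c("x", "y"))
    ck <- chunk(d, m)
    prep_relation(ck, node_of_token(ck, 1L), node_of_token(ck, nrow(d)))
  }
  expect_equal(mk("nmod:due_to")$relation, "due_to")
  expect_equal(mk("nmod:between")$relation, "between")
  expect_equal(mk("nmod:due_to")$rule, "PREP_SIMPLE")
  expect_equal(mk("nmod", "with")$relation, "with")
  expect_null(mk("nmod:toward"))  # not a listed connector

  # verb-linked entities are not a preposition relation
  d <- dtree(c("BAC00x", "causes", "DIS00y"), c(2, 0, 2),
             c("nsubj", "root", "obj"))
  m <- tibble::tibble(entity_class = c("MICROBE", "DISEASE"),
                      token = c(1L, 3L), canonical = c("x", "y"))
  ck <- chunk(d, m)
  expect_null(prep_relation(ck, 1L, 3L))
})

test_that("the LCA child rule recovers 'implicated' in the worked example", {
  p <- steno_parsed()
  ck <- chunk(p$dtree, mentions_for(p))
  a <- node_of_token(ck, 1L); b <- node_of_token(ck, 12L)
  expect_equal(tree_distance(ck, a, b), 4L)  # boundary value is retained
  res <- lca_relation(ck, a, b)
  expect_equal(res$relation, "implicated")
  expect_equal(res$rule, "LCA_CHILD")
  # and the full extractor keeps the pair at max_distance = 4
  trip <- extract_dbe(p)
  expect_true("implicated" %in% trip$relation_surface)
})

test_that("without a qualifying child the LCA's own word is the relation", {
  p <- strep_parsed()
  ck <- chunk(p$dtree, mentions_for(p))
  res <- lca_relation(ck, node_of_token(ck, 1L), node_of_token(ck, 12L))
  expect_equal(res$relation, "common_cause")
  expect_equal(res$rule, "LCA_NODE")
})

test_that("qualifying children are chosen by label priority then position", {
  # LCA with an amod child before and an acl child after: acl wins
  d <- dtree(c("BAC00x", "emerging", "pathogen", "implicated", "DIS00y"),
             head = c(3, 3, 0, 3, 4),
             deprel = c("nsubj", "amod", "root", "acl", "obl"))
  m <- tibble::tibble(entity_class = c("MICROBE", "DISEASE"),
                      token = c(1L, 5L), canonical = c("x", "y"))
  ck <- chunk(d, m)
  expect_equal(lca_relation(ck, 1L, 5L)$relation, "implicated")
  # two children with the same label: leftmost wins
  d2 <- dtree(c("BAC00x", "linked", "pathogen", "implicated", "DIS00y"),
              head = c(3, 3, 0, 3, 4),
              deprel = c("nsubj", "acl", "root", "acl", "obl"))
  ck2 <- chunk(d2, m)
  expect_equal(lca_relation(ck2, 1L, 5L)$relation, "linked")
})

test_that("LCA agrees with the ancestor-set oracle on random entity pairs", {
  corp <- test_corpus(150)
  set.seed(23)
  for (p in sample(corp$parsed, 40)) {
    ck <- chunk(p$dtree, mentions_for(p))
    ids <- ck$nodes$node_id
    ab <- sample(ids, 2L)
    path <- mdlink:::.chunk_path(ck, ab[1], ab[2])
    expect_equal(path$lca, oracle_lca(ck, ab[1], ab[2]))
  }
})

test_that("inheritance propagates along coordination chains", {
  p <- strep_parsed()
  trip <- extract_dbe(p)
  cc <- trip[trip$relation == "common_cause", ]
  expect_setequal(cc$disease, c("sepsis", "meningitis"))
  expect_true(any(grepl("INHERIT", trip$pattern_ids)))

  # chain of three coordinated diseases all inherit
  toks <- c("BAC00x", "is", "the", "most", "common", "cause", "of",
            "DIS00a", ",", "DIS00b", "and", "DIS00c", ".")
  sent <- mk_sentence("chain", toks, c(1L, 8L, 10L, 12L),
                      c("MICROBE", "DISEASE", "DISEASE", "DISEASE"),
                      c("x", "a", "b", "c"))
  ct <- parse_bracketed(paste0(
    "(S (NP (NN BAC00x)) (VP (VBZ is) (NP (NP (DT the) (RBS most) ",
    "(JJ common) (NN cause)) (PP (IN of) (NP (NP (NN DIS00a)) (, ,) ",
    "(NP (NN DIS00b)) (CC and) (NP (NN DIS00c)))))) (. .))"))
  dt <- dtree(toks, head = c(6, 6, 6, 5, 6, 0, 8, 6, 8, 8, 12, 10, 6),
              deprel = c("nsubj", "cop", "det", "advmod", "amod", "root",
                         "case", "nmod:of", "punct", "conj:and", "cc",
                         "conj:and", "punct"))
  ps <- parsed_sentence(sent, ct, dt)
  trip2 <- extract_dbe(ps)
  cc2 <- trip2[trip2$relation == "common_cause", ]
  expect_setequal(cc2$disease, c("a", "b", "c"))

  # no same-class chain: nothing inherited
  p2 <- steno_parsed()
  expect_false(any(grepl("INHERIT", extract_dbe(p2)$pattern_ids)))
})

test_that("disabling inheritance never changes non-INHERIT triplets", {
  for (p in list(strep_parsed(), steno_parsed(), fig3_parsed())) {
    with_inh <- extract_dbe(p, apply_inherit = TRUE)
    without <- extract_dbe(p, apply_inherit = FALSE)
    non_inh <- with_inh[!grepl("INHERIT", with_inh$pattern_ids) |
                          grepl(",", with_inh$pattern_ids), ]
    key <- function(d) paste(d$microbe, d$disease, d$relation)
    expect_true(all(key(without) %in% key(with_inh)))
    expect_true(all(key(non_inh) %in% key(without)))
  }
})

test_that("pairs beyond the dependency-distance cutoff are skipped", {
  # entity chain with 5 plain edges between the entities
  toks <- c("BAC00x", "w1", "w2", "w3", "w4", "DIS00y")
  d <- dtree(toks, head = c(2, 3, 4, 5, 6, 0),
             deprel = c("nsubj", "acl", "obl", "acl", "obl", "root"))
  sent <- mk_sentence("far", toks, c(1L, 6L), c("MICROBE", "DISEASE"),
                      c("x", "y"))
  ct <- parse_bracketed(
    "(S (NN BAC00x) (NN w1) (NN w2) (NN w3) (NN w4) (NN DIS00y))")
  ps <- parsed_sentence(sent, ct, d)
  expect_equal(nrow(extract_dbe(ps)), 0L)
  expect_gt(nrow(extract_dbe(ps, max_distance = 5L)), 0L)
})

test_that("an entity that dominates the other uses its chunk or the edge", {
  # compound-chunked entity as ancestor: the absorbed word is the relation
  toks <- c("wound", "DIS00y", "of", "BAC00x")
  d <- dtree(toks, head = c(2, 0, 4, 2),
             deprel = c("compound", "root", "case", "nmod:of"))
  m <- tibble::tibble(entity_class = c("DISEASE", "MICROBE"),
                      token = c(2L, 4L), canonical = c("y", "x"))
  ck <- chunk(d, m)
  res <- lca_relation(ck, node_of_token(ck, 4L), node_of_token(ck, 2L))
  expect_equal(res$rule, "NO_LCA_CHUNK")
  expect_equal(res$relation, "wound")

  # un-chunked dominating entity: the connecting edge label is emitted
  p <- fig3_parsed()
  ck2 <- chunk(p$dtree, mentions_for(p))
  res2 <- lca_relation(ck2, node_of_token(ck2, 1L), node_of_token(ck2, 7L))
  expect_equal(res2$rule, "LCA_SELF_EDGE")
  expect_equal(res2$relation, "appos")
})
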