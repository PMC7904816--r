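toy_table <- function() {
  tibble::tibble(
    microbe = c("m1", "m2", "m3", "m4"),
    disease = c("d1", "d1", "d2", "d3"),
    count = c(6L, 6L, 2L, 2L),
    relations = "cause"
  )
}

test_that("aggregation counts relation instances per association", {
  trips <- tibble::tibble(
    microbe = c("m1", "m1", "m2"), disease = c("d1", "d1", "d2"),
    relation = c("cause", "associate", "cause"))
  tab <- aggregate_associations(trips)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$count[tab$microbe == "m1"], 2L)
  expect_equal(tab$relations[tab$microbe == "m1"], "associate,cause")
})

test_that("the mean-count filter drops below-average associations", {
  # counts {6,6,2,2}: mean 4, the two count-2 records are dropped
  out <- apply_filters(toy_table(), exclude_terms = character(0))
  expect_equal(nrow(out), 2L)
  expect_setequal(out$count, 6L)
  expect_equal(attr(out, "mean_count"), 4)

  # equal counts: nothing dropped
  eq <- dplyr::mutate(toy_table(), count = 3L)
  expect_equal(nrow(apply_filters(eq, exclude_terms = character(0))), 4L)
})

test_that("the generic 'infection' disease is excluded before the mean filter", {
  tab <- dplyr::bind_rows(
    toy_table(),
    tibble::tibble(microbe = "m9", disease = "infection", count = 100L,
                   relations = "cause"))
  out <- apply_filters(tab)
  expect_false("infection" %in% out$disease)
  # the infected record's count must not inflate the mean: mean is still 4
  expect_equal(attr(out, "mean_count"), 4)
})

test_that("jaccard similarity follows |A.B|/|A+B| with a min-shared cutoff", {
  tab <- tibble::tibble(
    microbe = c("m1", "m2", "m1", "m2", "m3", "m9"),
    disease = c("dA", "dA", "dB", "dB", "dB", "dC"),
    count = 5L, relations = "cause")
  edges <- jaccard_similarity(tab)
  expect_equal(nrow(edges), 1L)  # dC shares nothing; dA-dB share 2
  expect_equal(edges$jaccard, 2 / 3)
  expect_equal(edges$shared, 2L)

  # identical sets: jaccard 1
  tab2 <- tibble::tibble(microbe = rep(c("m1", "m2"), 2),
                         disease = rep(c("dA", "dB"), each = 2),
                         count = 5L, relations = "x")
  expect_equal(jaccard_similarity(tab2)$jaccard, 1)

  # disjoint sets: no edge at all
  tab3 <- tibble::tibble(microbe = c("m1", "m2"), disease = c("dA", "dB"),
                         count = 5L, relations = "x")
  expect_equal(nrow(jaccard_similarity(tab3)), 0L)
})

test_that("the printed 4-of-5 shared-microbe pair scores 0.8 and survives 0.6", {
  shared <- c("Streptococcus_pneumoniae", "Haemophilus_influenzae",
              "Moraxella_catarrhalis", "Pseudomonas_aeruginosa")
  tab <- tibble::tibble(
    microbe = c(shared, shared, "Staphylococcus_aureus"),
    disease = c(rep("respiratory_tract_infections", 4),
                rep("otitis_media", 5)),
    count = 10L, relations = "cause")
  edges <- jaccard_similarity(tab)
  expect_equal(edges$shared, 4L)
  expect_equal(edges$union_size, 5L)
  expect_equal(edges$jaccard, 0.8)
  g <- build_network(edges, tab, threshold = 0.6)
  expect_equal(igraph::ecount(g), 1L)
  expect_setequal(igraph::V(g)$name,
                  c("otitis_media", "respiratory_tract_infections"))
  expect_equal(igraph::E(g)$weight, 0.8)
})

test_that("jaccard is symmetric, bounded, and node degrees are bounded", {
  corp <- test_corpus(150)
  trips <- dplyr::bind_rows(extract_corpus(corp)$dbe)
  tab <- apply_filters(aggregate_associations(trips),
                       min_count_policy = "none")
  edges <- jaccard_similarity(tab, min_shared = 1L)
  if (nrow(edges) > 0L) {
    expect_true(all(edges$jaccard >= 0 & edges$jaccard <= 1))
    expect_true(all(edges$disease_a < edges$disease_b))  # stored once
    g <- build_network(edges, tab, threshold = 0)
    expect_true(all(igraph::degree(g) <= igraph::vcount(g) - 1L))
  }
})

test_that("networks export deterministically and carry node sizes", {
  tab <- tibble::tibble(microbe = rep(c("m1", "m2"), 2),
                        disease = rep(c("dA", "dB"), each = 2),
                        count = 5L, relations = "x")
  g <- build_network(jaccard_similarity(tab), tab, threshold = 0.6,
                     category_map = tibble::tibble(
                       disease = c("dA", "dB"), category = c("C1", "C2")))
  expect_equal(igraph::V(g)$n_microbes, c(2L, 2L))
  expect_equal(igraph::V(g)$category, c("C1", "C2"))
  dir <- withr::local_tempdir()
  paths <- write_network(g, file.path(dir, "net"))
  expect_true(file.exists(file.path(dir, "net.graphml")))
  lines <- readLines(file.path(dir, "net_edges.tsv"))
  expect_equal(lines[1], "disease_a\tdisease_b\tjaccard")
  expect_equal(length(lines), 2L)
  p <- autoplot(g)
  expect_s3_class(p, "ggplot")
})

test_that("category maps load from two-column TSV", {
  path <- withr::local_tempfile(lines = c(
    "# disease\tcategory", "pneumonia\tRespiratory Tract Diseases",
    "pneumonia\tInfections", "sepsis\tInfections"))
  cm <- read_category_map(path)
  expect_equal(nrow(cm), 3L)
  expect_equal(sum(cm$disease == "pneumonia"), 2L)
})
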