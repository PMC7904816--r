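#' Aggregate triplets into a microbe-disease association table
#'
#' @param triplets Triplet tibble (columns `microbe`, `disease`,
#'   `relation`; one row per extracted relation instance).
#' @return Tibble with one row per (microbe, disease): `count` and the bag
#'   of relation words (`relations`, comma-joined with multiplicity
#'   preserved).
#' @export
aggregate_associations <- function(triplets) {
  triplets |>
    dplyr::group_by(.data$microbe, .data$disease) |>
    dplyr::summarise(count = dplyr::n(),
                     relations = paste(sort(.data$relation), collapse = ","),
                     .groups = "drop")
}

#' Filter an association table
#'
#' Applies, in this order: (1) exclusion of uninformative disease names
#' (the generic entity *infection* by default, which names an outcome, not
#' a disease); (2) a reliability filter dropping associations whose count
#' falls strictly below the mean count of the remaining records. The mean
#' is always computed from the data at hand, never hard-coded.
#'
#' @param table From [aggregate_associations()].
#' @param exclude_terms Disease canonical names to exclude (matched
#'   case-insensitively).
#' @param min_count_policy `"mean"` (drop below-average counts) or
#'   `"none"`.
#' @return Filtered association table; the applied mean threshold is
#'   attached as attribute `mean_count`.
#' @export
apply_filters <- function(table, exclude_terms = "infection",
                          min_count_policy = c("mean", "none")) {
  min_count_policy <- match.arg(min_count_policy)
  out <- table[!(tolower(table$disease) %in% tolower(exclude_terms)), ]
  mean_count <- NA_real_
  if (min_count_policy == "mean" && nrow(out) > 0L) {
    mean_count <- mean(out$count)
    out <- out[out$count >= mean_count, ]
  }
  attr(out, "mean_count") <- mean_count
  out
}

#' Jaccard similarity between diseases over shared microbes
#'
#' Each disease is represented by its set of associated microbes in the
#' (filtered) association table; for every unordered disease pair sharing
#' at least `min_shared` microbes the Jaccard index
#' `|A intersect B| / |A union B|` is computed. Pairs sharing fewer
#' microbes are excluded as unreliable.
#'
#' @param table Filtered association table.
#' @param min_shared Minimum number of shared microbes (default 2: pairs
#'   backed by a single common bacterium are dropped).
#' @return Tibble with `disease_a`, `disease_b` (alphabetical within pair),
#'   `shared` (count), `shared_microbes` (comma-joined), `union_size`,
#'   `jaccard`.
#' @export
jaccard_similarity <- function(table, min_shared = 2L) {
  sets <- split(table$microbe, table$disease)
  sets <- lapply(sets, unique)
  ds <- sort(names(sets))
  rows <- list()
  if (length(ds) >= 2L) {
    for (i in seq_len(length(ds) - 1L)) {
      for (j in seq.int(i + 1L, length(ds))) {
        A <- sets[[ds[i]]]; B <- sets[[ds[j]]]
        inter <- intersect(A, B)
        if (length(inter) < min_shared) next
        uni <- union(A, B)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          disease_a = ds[i], disease_b = ds[j], shared = length(inter),
          shared_microbes = paste(sort(inter), collapse = ","),
          union_size = length(uni),
          jaccard = length(inter) / length(uni)
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(disease_a = character(), disease_b = character(),
                          shared = integer(), shared_microbes = character(),
                          union_size = integer(), jaccard = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Build the disease-similarity network
#'
#' Keeps edges whose Jaccard similarity meets the threshold (0.6 by
#' default: diseases sharing 60% or more of their microbes are connected)
#' and returns an igraph graph whose nodes carry their microbe counts and
#' optional top-level disease categories.
#'
#' @param edges From [jaccard_similarity()].
#' @param table The association table (for node microbe counts).
#' @param threshold Minimum Jaccard similarity for an edge.
#' @param category_map Optional two-column data frame (`disease`,
#'   `category`) attaching category labels to nodes.
#' @return An `igraph` graph; nodes ordered alphabetically, edge attribute
#'   `weight` = Jaccard similarity.
#' @export
build_network <- function(edges, table = NULL, threshold = 0.6,
                          category_map = NULL) {
  kept <- edges[edges$jaccard >= threshold, ]
  nodes <- sort(unique(c(kept$disease_a, kept$disease_b)))
  vert <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (!is.null(table)) {
    n_microbes <- vapply(nodes, function(d) {
      length(unique(table$microbe[table$disease == d]))
    }, 0L)
    vert$n_microbes <- n_microbes
  }
  if (!is.null(category_map)) {
    vert$category <- category_map$category[match(nodes, category_map$disease)]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = kept$disease_a, to = kept$disease_b,
               weight = kept$jaccard, stringsAsFactors = FALSE),
    directed = FALSE, vertices = vert
  )
  class(g) <- c("mdlink_network", class(g))
  g
}

#' Read a disease-category lookup table
#'
#' Two-column TSV `disease <TAB> category` ('#' comments allowed); a
#' disease may appear under several categories.
#'
#' @param path TSV path.
#' @return Tibble with `disease` and `category`.
#' @export
read_category_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(disease = vapply(parts, `[[`, "", 1L),
                 category = vapply(parts, `[[`, "", 2L))
}

#' Export a network
#'
#' Writes the graph as GraphML plus a plain edge-list TSV
#' (`disease_a`, `disease_b`, `jaccard`), with rows in deterministic
#' (alphabetical) order.
#'
#' @param graph From [build_network()].
#' @param out_prefix Path prefix; writes `<prefix>.graphml` and
#'   `<prefix>_edges.tsv`.
#' @return The two paths, invisibly.
#' @export
write_network <- function(graph, out_prefix) {
  gml <- paste0(out_prefix, ".graphml")
  tsv <- paste0(out_prefix, "_edges.tsv")
  igraph::write_graph(graph, gml, format = "graphml")
  el <- igraph::as_data_frame(graph, what = "edges")
  el <- el[order(el$from, el$to), ]
  writeLines(c("disease_a\tdisease_b\tjaccard",
               sprintf("%s\t%s\t%g", el$from, el$to, el$weight)),
             tsv, useBytes = TRUE)
  invisible(c(gml, tsv))
}

#' Plot a disease-similarity network
#'
#' A ggplot rendering with node size proportional to the number of
#' associated microbes and edge width to the Jaccard similarity.
#'
#' @param object An `mdlink_network` from [build_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.mdlink_network <- function(object, ...) {
  lay <- igraph::layout_with_fr(object)
  nd <- data.frame(name = igraph::V(object)$name, x = lay[, 1], y = lay[, 2])
  size <- igraph::vertex_attr(object, "n_microbes")
  nd$n_microbes <- if (is.null(size)) 1 else size
  ed <- igraph::as_data_frame(object, what = "edges")
  ed$x <- nd$x[match(ed$from, nd$name)]; ed$y <- nd$y[match(ed$from, nd$name)]
  ed$xend <- nd$x[match(ed$to, nd$name)]; ed$yend <- nd$y[match(ed$to, nd$name)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "grey60") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$n_microbes),
                        colour = "steelblue") +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "microbes", linewidth = "Jaccard")
}
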