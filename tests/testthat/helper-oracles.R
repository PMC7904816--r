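# independent brute-force oracles used to validate the fast implementations

# --- exhaustive TPE embedding oracle ------------------------------------
# child-sequence alignment by enumerating ALL composition vectors (how many
# children each matcher consumes: gaps 0..n, everything else exactly 1) and
# validating each assignment; no backtracking shared with the implementation
oracle_compositions <- function(lens, total) {
  if (length(lens) == 0L) {
    return(if (total == 0L) list(integer(0)) else list())
  }
  out <- list()
  for (k in lens[[1L]]) {
    if (k > total) next
    for (rest in oracle_compositions(lens[-1L], total - k)) {
      out[[length(out) + 1L]] <- c(k, rest)
    }
  }
  out
}

oracle_node <- function(node, m) {
  re <- function(r, x) grepl(r, x, perl = TRUE)
  if (m$type == "star") return(list(list()))
  if (m$type == "leaf") {
    if (!mdlink:::is_cleaf(node)) return(list())
    if (!re(m$pos_re, node$pos) || !re(m$word_re, node$word)) return(list())
    b <- list()
    if (!is.na(m$capture)) b[[as.character(m$capture)]] <- node$word
    return(list(b))
  }
  if (mdlink:::is_cleaf(node)) return(list())
  if (!re(m$label_re, node$label)) return(list())
  ms <- m$children
  ns <- node$children
  lens <- lapply(ms, function(mm) if (mm$type == "gap") 0:length(ns) else 1L)
  out <- list()
  for (comp in oracle_compositions(lens, length(ns))) {
    pos <- cumsum(c(0L, comp))
    partial <- list(list())
    ok <- TRUE
    for (k in seq_along(ms)) {
      if (ms[[k]]$type == "gap") next
      child <- ns[[pos[k] + 1L]]
      bs <- oracle_node(child, ms[[k]])
      if (length(bs) == 0L) { ok <- FALSE; break }
      new_partial <- list()
      for (p in partial) for (b in bs) new_partial[[length(new_partial) + 1L]] <- c(p, b)
      partial <- new_partial
    }
    if (ok) out <- c(out, partial)
  }
  out
}

oracle_match_tpe <- function(tree, pattern) {
  nodes <- mdlink:::.tree_nodes_preorder(tree)
  rows <- list()
  for (i in seq_along(nodes)) {
    for (b in oracle_node(nodes[[i]], pattern$root)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pattern_id = pattern$pattern_id, anchor = i,
        microbe = b[["1"]] %||% NA_character_,
        disease = b[["2"]] %||% NA_character_,
        relation = b[["3"]] %||% NA_character_)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(pattern_id = character(), anchor = integer(),
                          microbe = character(), disease = character(),
                          relation = character()))
  }
  dplyr::distinct(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- random trees and patterns for the sweep ----------------------------
random_ctree <- function(max_nodes = 12L) {
  labels <- c("S", "NP", "VP", "PP")
  poss <- c("NN", "VBZ", "IN", "JJ")
  words <- c("BAC00x", "DIS00y", "causes", "in", "mild", "cohort")
  count <- 0L
  gen <- function(depth) {
    count <<- count + 1L
    if (depth >= 3L || count >= max_nodes || stats::runif(1) < 0.45) {
      return(mdlink:::.ct_leaf(sample(poss, 1L), sample(words, 1L)))
    }
    n_children <- sample(1:3, 1L)
    mdlink:::.ct_node(sample(labels, 1L),
                      lapply(seq_len(n_children), function(i) gen(depth + 1L)))
  }
  root <- gen(0L)
  if (mdlink:::is_cleaf(root)) mdlink:::.ct_node("S", list(root)) else root
}

random_tpe <- function(max_matchers = 6L) {
  labels <- c("S", "NP", "VP", ".+", "[SN].*")
  poss <- c("NN", "N.+", ".+", "VBZ")
  words <- c(".+", "BAC00.+", "DIS00.+", "causes", "c.*", "1#BAC00.+",
             "2#DIS00.+", "3#.+")
  count <- 0L
  gen_item <- function(depth) {
    count <<- count + 1L
    r <- stats::runif(1)
    if (depth > 0L && r < 0.2) return("*")
    if (depth > 0L && r < 0.45) return("**")
    if (depth >= 2L || count >= max_matchers || r < 0.75) {
      return(sprintf("<%s %s>", sample(poss, 1L), sample(words, 1L)))
    }
    kids <- vapply(seq_len(sample(0:2, 1L)), function(i) gen_item(depth + 1L), "")
    sprintf("{%s %s}", sample(labels, 1L), paste(kids, collapse = " "))
  }
  repeat {
    count <- 0L
    kids <- vapply(seq_len(sample(0:3, 1L)), function(i) gen_item(1L), "")
    src <- sprintf("{%s %s}", sample(labels, 1L), paste(kids, collapse = " "))
    ok <- tryCatch({ parse_tpe(src); TRUE }, error = function(e) FALSE)
    if (ok) return(parse_tpe(src, pattern_id = "rnd"))
  }
}

# --- dependency-tree oracles (igraph-based) -----------------------------
dtree_igraph <- function(dtree) {
  edges <- dtree[dtree$head != 0L, c("id", "head", "deprel")]
  igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$id), to = as.character(edges$head),
               label = edges$deprel),
    directed = FALSE,
    vertices = data.frame(name = as.character(dtree$id)))
}

oracle_sdp <- function(dtree, a, b) {
  g <- dtree_igraph(dtree)
  p <- igraph::shortest_paths(g, as.character(a), as.character(b))$vpath[[1]]
  ids <- as.integer(igraph::V(g)$name[as.integer(p)])
  sort(setdiff(ids, c(a, b)))
}

# ancestor-set LCA oracle on a chunked tree
oracle_lca <- function(chunked, a, b) {
  head <- mdlink:::.chunk_head(chunked)
  anc <- function(i) { out <- integer(0); j <- i
    while (j != 0L) { out <- c(out, j); j <- head[j] }; out }
  common <- intersect(anc(a), anc(b))
  depth <- vapply(common, function(i) length(anc(i)), 0L)
  common[which.max(depth)]
}

oracle_distance <- function(chunked, a, b, uncounted) {
  if (a == b) return(0L)
  nodes <- chunked$nodes
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(nodes$node_id[nodes$head != 0L]),
               to = as.character(nodes$head[nodes$head != 0L]),
               deprel = nodes$deprel[nodes$head != 0L]),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node_id)))
  p <- igraph::shortest_paths(g, as.character(a), as.character(b),
                              output = "epath")$epath[[1]]
  sum(!(igraph::edge_attr(g, "deprel", p) %in% uncounted))
}
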