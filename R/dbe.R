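#' Dependency-tree chunking
#'
#' Two merge rules simplify the dependency tree before relation extraction:
#'
#' * *of/with chunks*: when an entity hangs off a head word through an
#'   `of`/`with` prepositional edge (`"the most common cause of
#'   DIS00sepsis"`), the head word's `amod`/`compound` modifiers are merged
#'   into it, yielding a single relation-bearing node (`common_cause`)
#'   governing the entity.
#' * *compound chunks*: a non-entity word joined to an entity by a
#'   `compound` edge is merged into the entity node; the absorbed word is
#'   remembered (`chunk_word`) and can serve as the relation word when the
#'   entity itself turns out to be the ancestor of the pair.
#'
#' Merges are edge contractions applied innermost (deepest) first, so the
#' result is still a single-headed acyclic tree and every original token
#' belongs to exactly one node.
#'
#' @param dtree An `mdlink_dtree`.
#' @param mentions Mention tibble of the sentence (columns `token`,
#'   `entity_class`, `canonical`); `NULL` for no entities.
#' @param prepositions Which prepositional subtypes trigger the of/with rule.
#' @return An `mdlink_chunked`: list with `nodes` (tibble: `node_id`, `form`
#'   -- merged label in token order --, `head`, `deprel`, `is_entity`,
#'   `entity_class`, `canonical`, `chunk_word`, `tokens`) and the original
#'   `dtree`.
#' @export
chunk <- function(dtree, mentions = NULL, prepositions = c("of", "with")) {
  n <- nrow(dtree)
  head <- dtree$head
  deprel <- dtree$deprel
  forms <- dtree$form
  alive <- rep(TRUE, n)
  tokens <- as.list(seq_len(n))
  is_entity <- rep(FALSE, n)
  eclass <- rep(NA_character_, n)
  canon <- rep(NA_character_, n)
  if (!is.null(mentions) && nrow(mentions) > 0L) {
    is_entity[mentions$token] <- TRUE
    eclass[mentions$token] <- mentions$entity_class
    canon[mentions$token] <- mentions$canonical
  }

  depth <- vapply(seq_len(n), function(i) {
    d <- 0L; j <- i
    while (j != 0L) { d <- d + 1L; j <- head[j] }
    d
  }, 0L)

  children_of <- function(i) which(alive & head == i)

  # absorb node `drop` into node `keep`; when `drop` is keep's head, keep
  # inherits drop's attachment (edge contraction either way)
  absorb <- function(keep, drop) {
    if (head[keep] == drop) {
      head[keep] <<- head[drop]
      deprel[keep] <<- deprel[drop]
    }
    tokens[[keep]] <<- sort(c(tokens[[keep]], tokens[[drop]]))
    kids <- which(alive & head == drop)
    head[kids] <<- keep
    alive[drop] <<- FALSE
  }

  is_prep_edge <- function(e) {
    if (deprel[e] %in% as.vector(outer(c("nmod", "obl"), prepositions, paste, sep = ":")))
      return(TRUE)
    if (deprel[e] %in% c("nmod", "obl")) {
      kids <- children_of(e)
      return(any(deprel[kids] == "case" & tolower(forms[kids]) %in% prepositions))
    }
    FALSE
  }

  for (e in order(-depth)) {
    if (!alive[e] || !is_entity[e]) next
    h <- head[e]
    # of/with rule: merge the governing word's amod/compound modifiers
    if (h != 0L && alive[h] && !is_entity[h] && is_prep_edge(e)) {
      mods <- children_of(h)
      mods <- mods[deprel[mods] %in% c("amod", "compound") & !is_entity[mods]]
      for (m in sort(mods)) absorb(h, m)
    }
    # compound rule: merge compound-linked words into the entity node
    kids <- children_of(e)
    for (m in kids[deprel[kids] == "compound" & !is_entity[kids]]) absorb(e, m)
    if (head[e] != 0L && deprel[e] == "compound" && alive[head[e]] &&
        !is_entity[head[e]]) {
      absorb(e, head[e])
    }
  }

  ids <- which(alive)
  label <- vapply(ids, function(i) paste(forms[tokens[[i]]], collapse = "_"), "")
  chunk_word <- vapply(ids, function(i) {
    if (!is_entity[i] || length(tokens[[i]]) == 1L) return(NA_character_)
    paste(forms[setdiff(tokens[[i]], i)], collapse = "_")
  }, "")
  nodes <- tibble::tibble(
    node_id = ids, form = label, head = head[ids], deprel = deprel[ids],
    is_entity = is_entity[ids], entity_class = eclass[ids],
    canonical = canon[ids], chunk_word = chunk_word, tokens = tokens[ids]
  )
  structure(list(nodes = nodes, dtree = dtree), class = "mdlink_chunked")
}

#' Node holding a given token
#' @param chunked An `mdlink_chunked`.
#' @param token Original token index.
#' @return The `node_id` of the (possibly merged) node containing the token.
#' @export
node_of_token <- function(chunked, token) {
  hit <- which(vapply(chunked$nodes$tokens, function(t) token %in% t, TRUE))
  if (length(hit) != 1L) stop("token ", token, " not in exactly one chunk node")
  chunked$nodes$node_id[hit]
}

.chunk_head <- function(chunked) {
  h <- integer(max(chunked$nodes$node_id))
  h[chunked$nodes$node_id] <- chunked$nodes$head
  h
}
.chunk_field <- function(chunked, field) {
  v <- rep(NA_character_, max(chunked$nodes$node_id))
  v[chunked$nodes$node_id] <- chunked$nodes[[field]]
  v
}

.chunk_path <- function(chunked, a, b) {
  head <- .chunk_head(chunked)
  chain <- function(i) {
    out <- integer(0); j <- i
    while (j != 0L) { out <- c(out, j); j <- head[j] }
    out
  }
  pa <- chain(a); pb <- chain(b)
  lca <- pa[pa %in% pb][1L]
  if (is.na(lca)) stop("nodes ", a, " and ", b, " are disconnected")
  list(lca = lca,
       up = pa[seq_len(match(lca, pa))],
       down = rev(pb[seq_len(match(lca, pb) - 1L)]))
}

#' Dependency-tree distance between two entity nodes
#'
#' Length of the unique undirected path between the nodes in the chunked
#' tree, not counting coordination/compound/appositive edges (`conj`,
#' `conj:and`, `conj:or`, `compound`, `appos`), which join co-mentioned
#' entities rather than separating them syntactically.
#'
#' @param chunked An `mdlink_chunked`.
#' @param a,b Node ids (see [node_of_token()]).
#' @param uncounted Edge labels excluded from the count.
#' @return Non-negative integer distance.
#' @export
tree_distance <- function(chunked, a, b,
                          uncounted = c("conj", "conj:and", "conj:or",
                                        "compound", "appos")) {
  if (a == b) return(0L)
  p <- .chunk_path(chunked, a, b)
  onpath <- setdiff(c(p$up, p$down), p$lca)  # each contributes its head edge
  deprel <- .chunk_field(chunked, "deprel")
  sum(!(deprel[onpath] %in% uncounted))
}

.default_connectors <- c("by", "in", "from", "on", "with", "of", "due_to",
                         "between")

#' Simple preposition-linked relations
#'
#' When the two entities are joined by a direct dependency edge through one
#' of the listed connectors (`by`, `in`, `from`, `on`, `with`, `of`,
#' `due to`, `induced`, `between`), the connector itself is the relation
#' word (rule `PREP_SIMPLE`). An `induced by` construction (the token before
#' the `by` case marker stemming to *induce*) reports `induced`.
#'
#' @param chunked An `mdlink_chunked`.
#' @param a,b Entity node ids.
#' @param connectors Connector inventory (multi-word joined by underscore).
#' @return `NULL`, or a list with `relation` and `rule`.
#' @export
prep_relation <- function(chunked, a, b, connectors = .default_connectors) {
  nodes <- chunked$nodes
  head <- .chunk_head(chunked)
  dep <- if (head[a] == b) a else if (head[b] == a) b else return(NULL)
  deprel <- .chunk_field(chunked, "deprel")[dep]

  conn <- NULL
  if (grepl(":", deprel, fixed = TRUE)) {
    sub <- sub("^[^:]+:", "", deprel)
    if (sub %in% connectors) conn <- sub
  } else if (deprel %in% c("nmod", "obl")) {
    kids <- nodes$node_id[nodes$head == dep]
    case_kids <- kids[.chunk_field(chunked, "deprel")[kids] == "case"]
    case_forms <- tolower(.chunk_field(chunked, "form")[case_kids])
    hit <- case_forms[case_forms %in% connectors]
    if (length(hit)) conn <- hit[[1L]]
    if (is.null(conn) && any(case_forms == "due")) conn <- "due_to"
    if (!is.null(conn) && conn == "by") {
      by_tok <- case_kids[case_forms == "by"][1L]
      prev <- by_tok - 1L
      if (prev >= 1L && stem_word(chunked$dtree$form[prev]) %in% c("induc", "induce"))
        conn <- "induced"
    }
  }
  if (is.null(conn)) return(NULL)
  list(relation = conn, rule = "PREP_SIMPLE")
}

.default_lca_children <- c("acl", "acl:relcl", "amod", "xcomp", "ccomp",
                           "appos", "nmod:as", "conj:and", "conj:or",
                           "advcl", "dep")

#' Relation word from the lowest common ancestor
#'
#' The subtree rooted at the LCA of the two entity nodes carries the
#' relation. If the LCA has a child attached by a descriptive edge (`acl`,
#' `acl:relcl`, `amod`, `xcomp`, `ccomp`, `appos`, `nmod:as`, `conj:and`,
#' `conj:or`, `advcl`, `dep`; leftmost by token order on ties), that child's
#' word is the relation word (rule `LCA_CHILD`); otherwise the LCA's own
#' word is (rule `LCA_NODE`). When one entity *is* the ancestor of the
#' other, the relation comes from the entity itself: the word it was
#' chunk-combined with if any (rule `NO_LCA_CHUNK`), else the label of the
#' edge leading towards the other entity (rule `LCA_SELF_EDGE`).
#'
#' @param chunked An `mdlink_chunked`.
#' @param a,b Entity node ids (must lie in the same tree).
#' @param qualifying Edge labels that make a child the relation word.
#' @return List with `relation` and `rule`.
#' @export
lca_relation <- function(chunked, a, b, qualifying = .default_lca_children) {
  stopifnot(a != b)
  nodes <- chunked$nodes
  p <- .chunk_path(chunked, a, b)
  lca <- p$lca
  form <- .chunk_field(chunked, "form")
  deprel <- .chunk_field(chunked, "deprel")

  if (!lca %in% c(a, b)) {
    kids <- nodes$node_id[nodes$head == lca & !nodes$is_entity]
    kids <- kids[deprel[kids] %in% qualifying]
    if (length(kids) > 0L) {
      # priority follows the qualifying-label order (clausal modifiers
      # before adjectival ones), then sentence order within a label
      child <- kids[order(match(deprel[kids], qualifying), kids)][1L]
      return(list(relation = form[child], rule = "LCA_CHILD"))
    }
    return(list(relation = form[lca], rule = "LCA_NODE"))
  }

  # one entity dominates the other
  cw <- .chunk_field(chunked, "chunk_word")[lca]
  if (!is.na(cw)) return(list(relation = cw, rule = "NO_LCA_CHUNK"))
  # first node on the path below the dominating entity
  step <- if (lca == a) p$down[[1L]] else p$up[[length(p$up) - 1L]]
  list(relation = deprel[step], rule = "LCA_SELF_EDGE")
}

#' Inherit relations along coordination chains
#'
#' Entities of the same class joined by coordination-type edges (`conj`,
#' `conj:and`, `conj:or`, `appos`, `compound`) share their relations: if
#' (M, A, r) was extracted and B is coordination-connected to A, then
#' (M, B, r) holds too (rule `INHERIT`). Connectivity is the transitive
#' closure over the coordination edges.
#'
#' @param chunked An `mdlink_chunked`.
#' @param extracted Tibble of extracted rows with columns `microbe_node`,
#'   `disease_node`, `microbe`, `disease`, `relation`, `rule`.
#' @param coord_edges Edge labels treated as coordination.
#' @return Additional rows in the same shape (possibly zero).
#' @export
inherit_relations <- function(chunked, extracted,
                              coord_edges = c("conj", "conj:and", "conj:or",
                                              "appos", "compound")) {
  nodes <- chunked$nodes
  if (nrow(extracted) == 0L) return(extracted[0, ])
  # connected components over coordination edges
  coord <- nodes[nodes$deprel %in% coord_edges & nodes$head != 0L, ]
  if (nrow(coord) == 0L) return(extracted[0, ])
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(coord$node_id), to = as.character(coord$head)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node_id))
  )
  membership <- igraph::components(g)$membership
  comp_of <- function(id) membership[[as.character(id)]]

  ent <- nodes[nodes$is_entity, ]
  out <- list()
  for (i in seq_len(nrow(extracted))) {
    row <- extracted[i, ]
    for (side in c("disease", "microbe")) {
      anchor <- row[[paste0(side, "_node")]]
      mates <- ent[ent$entity_class == toupper(side) &
                   ent$node_id != anchor, ]
      mates <- mates[vapply(mates$node_id, comp_of, numeric(1)) == comp_of(anchor), ]
      for (j in seq_len(nrow(mates))) {
        new <- row
        new[[side]] <- mates$canonical[j]
        new[[paste0(side, "_node")]] <- mates$node_id[j]
        new$rule <- "INHERIT"
        out[[length(out) + 1L]] <- new
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Dependency-based relation extraction
#'
#' The full pipeline over one parsed sentence: chunk, filter entity pairs by
#' dependency distance, then apply the preposition rule and the LCA rules to
#' every retained microbe-disease pair, and propagate relations along
#' coordination chains. Both a `PREP_SIMPLE` and an LCA-rule triplet may be
#' emitted for the same pair; the ensemble stage arbitrates reliability.
#'
#' @param parsed An `mdlink_parsed` sentence.
#' @param max_distance Maximum (uncounted-edge-adjusted) dependency distance
#'   between the entities; pairs farther apart are skipped. The boundary
#'   value is retained.
#' @param connectors,qualifying,coord_edges Rule inventories, see
#'   [prep_relation()], [lca_relation()], [inherit_relations()].
#' @param apply_inherit Disable to suppress `INHERIT` rows (the other rows
#'   are unaffected).
#' @return Triplet tibble: `sentence_id`, `microbe`, `disease`, `relation`
#'   (stemmed), `relation_surface`, `extractor` (`"DBE"`), `pattern_ids`
#'   (the rule ids, comma-joined on duplicates).
#' @export
extract_dbe <- function(parsed, max_distance = 4L,
                        connectors = .default_connectors,
                        qualifying = .default_lca_children,
                        coord_edges = c("conj", "conj:and", "conj:or",
                                        "appos", "compound"),
                        apply_inherit = TRUE) {
  empty <- tibble::tibble(sentence_id = character(), microbe = character(),
                          disease = character(), relation = character(),
                          relation_surface = character(),
                          extractor = character(), pattern_ids = character())
  s <- parsed$sentence
  mic <- mentions_of(s, "MICROBE"); dis <- mentions_of(s, "DISEASE")
  if (nrow(mic) == 0L || nrow(dis) == 0L) return(empty)
  ck <- chunk(parsed$dtree, s$mentions)

  rows <- list()
  for (i in seq_len(nrow(mic))) {
    for (j in seq_len(nrow(dis))) {
      na <- node_of_token(ck, mic$token[i])
      nb <- node_of_token(ck, dis$token[j])
      if (na == nb) next
      if (tree_distance(ck, na, nb) > max_distance) next
      base <- tibble::tibble(microbe = mic$canonical[i], disease = dis$canonical[j],
                             microbe_node = na, disease_node = nb)
      pr <- prep_relation(ck, na, nb, connectors)
      if (!is.null(pr)) {
        rows[[length(rows) + 1L]] <- dplyr::mutate(base, relation = pr$relation,
                                                   rule = pr$rule)
      }
      lr <- lca_relation(ck, na, nb, qualifying)
      rows[[length(rows) + 1L]] <- dplyr::mutate(base, relation = lr$relation,
                                                 rule = lr$rule)
    }
  }
  extracted <- dplyr::bind_rows(rows)
  if (nrow(extracted) == 0L) return(empty)
  if (apply_inherit) {
    extracted <- dplyr::bind_rows(extracted,
                                  inherit_relations(ck, extracted, coord_edges))
  }
  extracted |>
    dplyr::mutate(sentence_id = s$sentence_id,
                  relation_surface = .data$relation,
                  relation = stem_word(.data$relation),
                  extractor = "DBE") |>
    dplyr::group_by(.data$sentence_id, .data$microbe, .data$disease,
                    .data$relation) |>
    dplyr::summarise(relation_surface = .data$relation_surface[1L],
                     extractor = "DBE",
                     pattern_ids = paste(sort(unique(.data$rule)), collapse = ","),
                     .groups = "drop")
}
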