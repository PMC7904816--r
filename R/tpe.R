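#' Tree pattern expressions
#'
#' A tree pattern expression (TPE) is a query over constituency parse trees:
#'
#' \preformatted{
#'   { LABEL_RE child ... }   internal node whose label matches LABEL_RE and
#'                            whose child sequence matches the child matchers
#'   < POS_RE WORD_RE >       leaf (preterminal + token)
#'   *                        exactly one arbitrary subtree
#'   **                       a gap: zero or more consecutive subtrees
#'   k#WORD_RE                capture marker on a leaf word regex;
#'                            k = 1 microbe, 2 disease, 3 relation word
#' }
#'
#' Regexes are ordinary (PCRE) regexes anchored at both ends. Child matcher
#' sequences are matched left to right with backtracking over gaps; a
#' pattern may anchor at any tree node.
#'
#' @name tpe
NULL

.tpe_lex <- function(string) {
  padded <- gsub("([{}<>])", " \\1 ", string)
  toks <- strsplit(trimws(padded), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.tpe_regex <- function(fragment) {
  re <- paste0("^(?:", fragment, ")$")
  ok <- tryCatch({ grepl(re, "x", perl = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) stop("invalid regex fragment in pattern: '", fragment, "'", call. = FALSE)
  re
}

#' Parse a tree pattern expression
#'
#' @param pattern_string The TPE string (see [tpe] for the grammar).
#' @param pattern_id Identifier carried into match provenance.
#' @return An `mdlink_tpe` object holding the compiled matcher tree, the
#'   source string, and the set of capture ids used.
#' @export
parse_tpe <- function(pattern_string, pattern_id = "p1") {
  toks <- .tpe_lex(pattern_string)
  pos <- 1L
  seen_caps <- integer(0)
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  err <- function(msg) stop(sprintf("TPE parse error at item %d: %s", pos, msg),
                            call. = FALSE)

  parse_word_atom <- function(atom) {
    cap <- NA_integer_
    m <- regmatches(atom, regexec("^([0-9]+)#(.*)$", atom))[[1]]
    if (length(m) == 3L) {
      cap <- as.integer(m[[2L]])
      if (!cap %in% 1:3) err(sprintf("capture id %d outside {1,2,3}", cap))
      if (cap %in% seen_caps) err(sprintf("duplicate capture id %d", cap))
      seen_caps <<- c(seen_caps, cap)
      atom <- m[[3L]]
    }
    list(re = .tpe_regex(atom), capture = cap)
  }

  parse_item <- function() {
    t <- peek()
    if (is.null(t)) err("unexpected end of pattern")
    if (t == "{") {
      take()
      lab <- peek()
      if (is.null(lab) || lab %in% c("{", "}", "<", ">")) err("missing node label after '{'")
      take()
      label_re <- .tpe_regex(lab)
      children <- list()
      repeat {
        t2 <- peek()
        if (is.null(t2)) err("unbalanced '{': missing '}'")
        if (t2 == "}") { take(); break }
        children[[length(children) + 1L]] <- parse_item()
      }
      list(type = "internal", label_re = label_re, children = children)
    } else if (t == "<") {
      take()
      p <- peek(); if (is.null(p) || p %in% c("{", "}", "<", ">")) err("missing POS regex in leaf")
      take()
      w <- peek(); if (is.null(w) || w %in% c("{", "}", "<", ">")) err("missing word regex in leaf")
      take()
      if (!identical(peek(), ">")) err("unbalanced '<': missing '>'")
      take()
      wa <- parse_word_atom(w)
      list(type = "leaf", pos_re = .tpe_regex(p), word_re = wa$re, capture = wa$capture)
    } else if (t == "*") {
      take(); list(type = "star")
    } else if (t == "**") {
      take(); list(type = "gap")
    } else {
      err(sprintf("unexpected item '%s'", t))
    }
  }

  root <- parse_item()
  if (!is.null(peek())) err(sprintf("trailing content '%s'", peek()))
  if (root$type %in% c("star", "gap")) err("pattern root must be a node matcher")
  structure(list(pattern_id = pattern_id, source = pattern_string,
                 root = root, captures = sort(seen_caps)),
            class = "mdlink_tpe")
}

#' @export
print.mdlink_tpe <- function(x, ...) {
  cat(sprintf("<mdlink_tpe %s: captures {%s}>\n  %s\n", x$pattern_id,
              paste(x$captures, collapse = ","), x$source))
  invisible(x)
}

# ---- matching ----------------------------------------------------------

# list of capture maps (possibly empty maps); NULL means no match
.match_node <- function(node, m) {
  if (m$type == "star") return(list(list()))
  if (m$type == "leaf") {
    if (!is_cleaf(node)) return(list())
    if (!grepl(m$pos_re, node$pos, perl = TRUE)) return(list())
    if (!grepl(m$word_re, node$word, perl = TRUE)) return(list())
    b <- list()
    if (!is.na(m$capture)) b[[as.character(m$capture)]] <- node$word
    return(list(b))
  }
  # internal matcher
  if (is_cleaf(node)) return(list())
  if (!grepl(m$label_re, node$label, perl = TRUE)) return(list())
  .match_seq(node$children, m$children)
}

.match_seq <- function(nodes, matchers) {
  if (length(matchers) == 0L) {
    return(if (length(nodes) == 0L) list(list()) else list())
  }
  m1 <- matchers[[1L]]
  rest_m <- matchers[-1L]
  out <- list()
  if (m1$type == "gap") {
    for (k in 0:length(nodes)) {
      out <- c(out, .match_seq(nodes[seq_len(length(nodes)) > k], rest_m))
    }
  } else {
    if (length(nodes) == 0L) return(list())
    heads <- .match_node(nodes[[1L]], m1)
    if (length(heads) > 0L) {
      rests <- .match_seq(nodes[-1L], rest_m)
      for (h in heads) for (r in rests) out[[length(out) + 1L]] <- c(h, r)
    }
  }
  out
}

.tree_nodes_preorder <- function(tree) {
  acc <- list()
  walk <- function(node) {
    acc[[length(acc) + 1L]] <<- node
    if (!is_cleaf(node)) for (ch in node$children) walk(ch)
  }
  walk(tree)
  acc
}

#' Match a TPE pattern against a constituency tree
#'
#' The pattern is anchored at every tree node in turn; every distinct
#' embedding is reported. Alignments at one anchor that bind identical
#' capture values are collapsed to one row.
#'
#' @param tree A constituency tree.
#' @param pattern An `mdlink_tpe`.
#' @return Tibble with columns `pattern_id`, `anchor` (preorder node index),
#'   `microbe`, `disease`, `relation` (captured words, `NA` when the capture
#'   is absent from the pattern).
#' @export
match_tpe <- function(tree, pattern) {
  nodes <- .tree_nodes_preorder(tree)
  rows <- list()
  for (i in seq_along(nodes)) {
    for (b in .match_node(nodes[[i]], pattern$root)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pattern_id = pattern$pattern_id, anchor = i,
        microbe = b[["1"]] %||% NA_character_,
        disease = b[["2"]] %||% NA_character_,
        relation = b[["3"]] %||% NA_character_
      )
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

#' Extract relation triplets by structural pattern matching
#'
#' Runs every pattern over the sentence's constituency tree; complete
#' bindings (captures 1, 2 and 3 all present) become
#' (microbe, disease, relation word) triplets. Entity tag prefixes are
#' stripped, the relation word is stemmed, and duplicate triplets from one
#' sentence are collapsed with merged pattern provenance.
#'
#' @param parsed An `mdlink_parsed` sentence.
#' @param patterns List of `mdlink_tpe` patterns (each must use captures
#'   1, 2 and 3).
#' @return Triplet tibble: `sentence_id`, `microbe`, `disease`, `relation`
#'   (stemmed), `relation_surface`, `extractor` (`"TPE"`), `pattern_ids`.
#' @export
extract_triplets <- function(parsed, patterns) {
  empty <- tibble::tibble(sentence_id = character(), microbe = character(),
                          disease = character(), relation = character(),
                          relation_surface = character(),
                          extractor = character(), pattern_ids = character())
  if (length(patterns) == 0L) return(empty)
  bad <- vapply(patterns, function(p) !all(1:3 %in% p$captures), TRUE)
  if (any(bad)) {
    stop("extraction patterns must contain captures 1, 2 and 3: ",
         paste(vapply(patterns[bad], `[[`, "", "pattern_id"), collapse = ", "))
  }
  hits <- dplyr::bind_rows(lapply(patterns, function(p) match_tpe(parsed$ctree, p)))
  if (nrow(hits) == 0L) return(empty)
  hits |>
    dplyr::filter(!is.na(.data$microbe), !is.na(.data$disease), !is.na(.data$relation)) |>
    dplyr::mutate(
      sentence_id = parsed$sentence$sentence_id,
      microbe = strip_entity_tag(.data$microbe),
      disease = strip_entity_tag(.data$disease),
      relation_surface = .data$relation,
      relation = stem_word(.data$relation),
      extractor = "TPE"
    ) |>
    dplyr::group_by(.data$sentence_id, .data$microbe, .data$disease,
                    .data$relation) |>
    dplyr::summarise(
      relation_surface = .data$relation_surface[1L],
      extractor = "TPE",
      pattern_ids = paste(sort(unique(.data$pattern_id)), collapse = ","),
      .groups = "drop"
    )
}

#' Strip the `BAC00`/`DIS00` tag prefix from a token
#' @param x Character vector.
#' @return `x` without a leading entity tag.
#' @export
strip_entity_tag <- function(x) sub("^(BAC00|DIS00)", "", x)

#' The shipped tree patterns
#'
#' Two canonical extraction patterns: `appositive_commas` targets an
#' appositive phrase set off by commas whose noun head is the relation word
#' and which embeds the disease in a prepositional phrase
#' (\emph{"X, a common cause of Y, ..."}); `passive_participle` targets a
#' copular/passive clause whose past participle is the relation word
#' (\emph{"X is associated with Y"}). Both capture microbe (1), disease (2)
#' and relation word (3). Further patterns can be supplied via
#' [read_patterns()]; the pattern set is configuration, not code.
#'
#' @return List of `mdlink_tpe` objects.
#' @export
mdlink_patterns <- function() {
  list(
    parse_tpe(paste0("{.+ ** {NP ** <N.+ 1#BAC00.+> **} <, ,> ",
                     "{NP ** <N.+ 3#.+> {PP <IN .+> ** {NP ** <N.+ 2#DIS00.+> **}}} ",
                     "<, ,> **}"),
              pattern_id = "appositive_commas"),
    parse_tpe(paste0("{S ** {NP ** <N.+ 1#BAC00.+> **} ** ",
                     "{VP ** <VBN 3#.+> ** {PP <IN .+> ** {NP ** <N.+ 2#DIS00.+> **}}} **}"),
              pattern_id = "passive_participle")
  )
}

#' Read / write TPE pattern files
#'
#' One pattern per line: `pattern_id <TAB> pattern_string`; `#` starts a
#' comment line.
#'
#' @param path Pattern file.
#' @return List of `mdlink_tpe` objects.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  lapply(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("pattern line must be 'id<TAB>pattern': ", line)
    parse_tpe(parts[[2L]], pattern_id = parts[[1L]])
  })
}

#' @rdname read_patterns
#' @param patterns List of `mdlink_tpe` objects.
#' @export
write_patterns <- function(patterns, path) {
  writeLines(vapply(patterns, function(p) paste(p$pattern_id, p$source, sep = "\t"), ""),
             path, useBytes = TRUE)
  invisible(path)
}
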