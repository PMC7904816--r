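#' Constituency and dependency tree containers
#'
#' Constituency trees are nested lists: internal nodes are
#' `list(label, children)`, leaves are `list(pos, word)` (the preterminal and
#' its token collapsed together, so the leaf sequence aligns one-to-one with
#' the sentence token stream). Dependency trees are tibbles with one row per
#' token (`id`, `form`, `upos`, `head`, `deprel`), `head == 0` marking the
#' root; they are validated to be single-rooted spanning arborescences.
#'
#' @name trees
NULL

.ct_node <- function(label, children) {
  structure(list(label = label, children = children), class = "mdlink_cnode")
}
.ct_leaf <- function(pos, word) {
  structure(list(pos = pos, word = word), class = "mdlink_cleaf")
}
is_cleaf <- function(x) inherits(x, "mdlink_cleaf")

#' Parse one bracketed tree from a string
#' @param string A Penn-Treebank style S-expression.
#' @return The root node.
#' @export
parse_bracketed <- function(string) {
  trees <- .parse_bracket_tokens(.bracket_tokens(string))
  if (length(trees) != 1L) stop("expected exactly one tree, found ", length(trees))
  trees[[1L]]
}

.bracket_tokens <- function(text, lines = NULL) {
  if (is.null(lines)) lines <- text
  toks <- list(); lineno <- integer(0)
  for (i in seq_along(lines)) {
    padded <- gsub("(\\(|\\))", " \\1 ", lines[[i]])
    tk <- strsplit(trimws(padded), "\\s+")[[1]]
    tk <- tk[nzchar(tk)]
    toks <- c(toks, as.list(tk))
    lineno <- c(lineno, rep(i, length(tk)))
  }
  list(tokens = unlist(toks), line = lineno)
}

# parses a whole token stream into a list of trees
.parse_bracket_tokens <- function(ts) {
  tokens <- ts$tokens; line <- ts$line
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  take <- function() { t <- tokens[[pos]]; pos <<- pos + 1L; t }
  err <- function(msg) {
    at <- if (pos <= length(line)) line[[pos]] else line[[length(line)]]
    stop(sprintf("%s (near line %d)", msg, at), call. = FALSE)
  }

  parse_node <- function() {
    if (!identical(peek(), "(")) err("expected '('")
    take()
    if (is.null(peek())) err("unbalanced parentheses: unexpected end of input")
    label <- take()
    if (label %in% c("(", ")")) err("empty node label")
    children <- list()
    words <- character(0)
    repeat {
      t <- peek()
      if (is.null(t)) err("unbalanced parentheses: unexpected end of input")
      if (t == ")") { take(); break }
      if (t == "(") children[[length(children) + 1L]] <- parse_node()
      else words <- c(words, take())
    }
    if (length(words) > 0L && length(children) > 0L)
      err("node mixes terminal words and subtrees")
    if (length(children) == 0L) {
      if (length(words) != 1L) err(sprintf("leaf '%s' must hold exactly one word", label))
      .ct_leaf(label, words)
    } else {
      .ct_node(label, children)
    }
  }

  out <- list()
  while (!is.null(peek())) {
    if (!identical(peek(), "(")) err("unbalanced parentheses: unexpected ')'")
    out[[length(out) + 1L]] <- parse_node()
  }
  out
}

#' Read bracketed constituency trees
#'
#' Trees may sit one per line or span several lines; any top-level
#' S-expression starts a new tree. Unbalanced parentheses and empty labels
#' are errors reporting the offending line.
#'
#' @param path File of Penn-Treebank bracketed trees.
#' @return List of constituency trees.
#' @export
read_bracketed <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  .parse_bracket_tokens(.bracket_tokens(NULL, lines))
}

#' Serialize a constituency tree
#' @param tree A constituency tree node.
#' @return Single bracketed string; `parse_bracketed(write_bracketed(x))` is
#'   structurally identical to `x`.
#' @export
write_bracketed <- function(tree) {
  if (is_cleaf(tree)) sprintf("(%s %s)", tree$pos, tree$word)
  else sprintf("(%s %s)", tree$label,
               paste(vapply(tree$children, write_bracketed, ""), collapse = " "))
}

#' Leaves of a constituency tree
#' @param tree A constituency tree.
#' @return Tibble with `pos` and `word` in sentence order.
#' @export
ctree_leaves <- function(tree) {
  acc <- list()
  walk <- function(node) {
    if (is_cleaf(node)) acc[[length(acc) + 1L]] <<- node
    else for (ch in node$children) walk(ch)
  }
  walk(tree)
  tibble::tibble(pos = vapply(acc, `[[`, "", "pos"),
                 word = vapply(acc, `[[`, "", "word"))
}

#' Construct a dependency tree
#'
#' @param form Token strings.
#' @param head Integer head indices, `0` for the root (exactly one).
#' @param deprel Dependency labels, preserved verbatim (subtypes such as
#'   `conj:and` or `nmod:as` included).
#' @param upos Part-of-speech tags (optional).
#' @return An `mdlink_dtree` tibble.
#' @export
dtree <- function(form, head, deprel, upos = rep("X", length(form))) {
  n <- length(form)
  stopifnot(length(head) == n, length(deprel) == n, length(upos) == n)
  head <- as.integer(head)
  if (any(head < 0L | head > n)) stop("HEAD index out of range")
  if (sum(head == 0L) != 1L) stop("dependency tree must have exactly one root")
  # cycle check: every node must reach the root by following heads
  for (i in seq_len(n)) {
    seen <- logical(n); j <- i
    while (j != 0L) {
      if (seen[j]) stop("cycle in dependency tree involving token ", i)
      seen[j] <- TRUE
      j <- head[j]
    }
  }
  out <- tibble::tibble(id = seq_len(n), form = as.character(form),
                        upos = as.character(upos), head = head,
                        deprel = as.character(deprel))
  class(out) <- c("mdlink_dtree", class(out))
  out
}

#' Read CoNLL-U dependency trees
#'
#' Sentences are blank-line separated blocks; comment lines (`#`) and
#' multi-word-token / empty-node rows (ids containing `-` or `.`) are
#' skipped. The XPOS column is used as `upos` when UPOS is `_`. Multiple
#' roots, out-of-range heads and cycles are errors.
#'
#' @param path CoNLL-U file.
#' @return List of `mdlink_dtree` objects.
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  blocks <- lapply(blocks, function(b) {
    b <- b[nzchar(trimws(b)) & !grepl("^#", b)]
    b[!grepl("^\\d+[-.]", b)]
  })
  blocks <- blocks[lengths(blocks) > 0L]
  lapply(blocks, function(b) {
    fields <- strsplit(b, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 8L)
    if (length(bad)) stop("malformed CoNLL-U row: ", b[bad[1L]])
    upos <- vapply(fields, `[[`, "", 4L)
    xpos <- vapply(fields, `[[`, "", 5L)
    dtree(form = vapply(fields, `[[`, "", 2L),
          head = as.integer(vapply(fields, `[[`, "", 7L)),
          deprel = vapply(fields, `[[`, "", 8L),
          upos = ifelse(upos == "_", xpos, upos))
  })
}

#' Write dependency trees as CoNLL-U
#' @param dtrees List of `mdlink_dtree` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conllu <- function(dtrees, path) {
  if (inherits(dtrees, "mdlink_dtree")) dtrees <- list(dtrees)
  blocks <- vapply(dtrees, function(d) {
    paste(sprintf("%d\t%s\t_\t%s\t_\t_\t%d\t%s\t_\t_",
                  d$id, d$form, d$upos, d$head, d$deprel),
          collapse = "\n")
  }, "")
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}
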