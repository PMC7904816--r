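#' Parse providers
#'
#' A parse provider supplies, per annotated sentence, one constituency tree
#' and one dependency tree. The fixture backend serves pre-built gold trees
#' keyed by sentence id; the adapter backend shells out to a user-supplied
#' external parser through a command template. Entity mentions must already
#' be collapsed into single tagged tokens in the trees (the tagger runs
#' before parsing), so leaf/token alignment is checked exactly.
#'
#' @param ctrees List of constituency trees.
#' @param dtrees List of `mdlink_dtree` objects.
#' @param sentence_ids Character vector naming both lists, in order.
#' @return An `mdlink_provider`.
#' @export
fixture_provider <- function(ctrees, dtrees, sentence_ids) {
  stopifnot(length(ctrees) == length(sentence_ids),
            length(dtrees) == length(sentence_ids))
  structure(list(ctrees = stats::setNames(ctrees, sentence_ids),
                 dtrees = stats::setNames(dtrees, sentence_ids)),
            class = "mdlink_provider", backend = "fixture")
}

#' @rdname fixture_provider
#' @param mrg_path Bracketed-tree file (trees in corpus order).
#' @param conllu_path CoNLL-U file (blocks in corpus order).
#' @export
load_fixture_provider <- function(mrg_path, conllu_path, sentence_ids) {
  fixture_provider(read_bracketed(mrg_path), read_conllu(conllu_path),
                   sentence_ids)
}

#' Attach parse trees to an annotated sentence
#'
#' Verifies that the constituency leaves and the dependency-tree forms both
#' equal the sentence token stream; a mismatch reports the first divergent
#' token index rather than failing silently downstream.
#'
#' @param sentence An `mdlink_sentence`.
#' @param provider An `mdlink_provider`.
#' @return An `mdlink_parsed` list with fields `sentence`, `ctree`, `dtree`.
#' @export
provide <- function(sentence, provider) {
  id <- sentence$sentence_id
  ctree <- provider$ctrees[[id]]
  dtree <- provider$dtrees[[id]]
  if (is.null(ctree) || is.null(dtree)) {
    stop("no parse fixtures for sentence_id '", id, "'")
  }
  parsed_sentence(sentence, ctree, dtree)
}

#' @rdname provide
#' @param ctree Constituency tree for the sentence.
#' @param dtree Dependency tree for the sentence.
#' @export
parsed_sentence <- function(sentence, ctree, dtree) {
  leaves <- ctree_leaves(ctree)
  .check_alignment(sentence$tokens, leaves$word, "constituency leaves",
                   sentence$sentence_id)
  .check_alignment(sentence$tokens, dtree$form, "dependency tree forms",
                   sentence$sentence_id)
  structure(list(sentence = sentence, ctree = ctree, dtree = dtree),
            class = "mdlink_parsed")
}

.check_alignment <- function(tokens, other, what, id) {
  if (length(tokens) != length(other)) {
    stop(sprintf("sentence '%s': %s have %d tokens, sentence has %d",
                 id, what, length(other), length(tokens)))
  }
  diff <- which(tokens != other)
  if (length(diff)) {
    stop(sprintf("sentence '%s': %s diverge from tokens at index %d ('%s' vs '%s')",
                 id, what, diff[1L], other[diff[1L]], tokens[diff[1L]]))
  }
  invisible(TRUE)
}

#' @export
print.mdlink_parsed <- function(x, ...) {
  cat(sprintf("<mdlink_parsed %s: %d tokens>\n",
              x$sentence$sentence_id, length(x$sentence$tokens)))
  invisible(x)
}

#' External-parser adapter
#'
#' Interface slot for plugging in a real parser: `command` is a shell
#' template containing `{in}` and `{out_mrg}` / `{out_conllu}` placeholders.
#' The adapter writes the sentence tokens (one sentence per line, tagged
#' tokens included) to `{in}`, runs the command, and reads the two outputs.
#' No parser is bundled with the package.
#'
#' @param command Shell command template.
#' @return A function `(sentences) -> mdlink_provider`.
#' @export
adapter_provider <- function(command) {
  force(command)
  function(sentences) {
    tin <- tempfile("mdlink_in_"); tmrg <- tempfile("mdlink_", fileext = ".mrg")
    tco <- tempfile("mdlink_", fileext = ".conllu")
    writeLines(vapply(sentences, function(s) paste(s$tokens, collapse = " "), ""),
               tin, useBytes = TRUE)
    cmd <- gsub("{in}", tin, command, fixed = TRUE)
    cmd <- gsub("{out_mrg}", tmrg, cmd, fixed = TRUE)
    cmd <- gsub("{out_conllu}", tco, cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0L) stop("external parser command failed with status ", status)
    load_fixture_provider(tmrg, tco,
                          vapply(sentences, `[[`, "", "sentence_id"))
  }
}
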