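#' Tokenize a sentence
#'
#' Splits on whitespace and peels separable punctuation off into tokens of
#' their own. Hyphens and underscores are word-internal (so collapsed entity
#' tokens such as `BAC00Pseudomonas_aeruginosa` survive re-tokenization
#' unchanged), everything in `.,;:!?()[]{}"'` becomes a separate token.
#'
#' The same tokenizer is applied to lexicon surface forms and to input
#' sentences, so multi-word dictionary entries align with the sentence token
#' stream by construction.
#'
#' @param text A length-one character vector.
#' @return Character vector of tokens (possibly empty).
#' @export
md_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  padded <- gsub("([.,;:!?()\\[\\]{}\"'])", " \\1 ", text, perl = TRUE)
  toks <- strsplit(trimws(padded), "\\s+", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}

# characters the tokenizer always separates; canonical names must avoid them
.md_split_chars_re <- "[.,;:!?()\\[\\]{}\"']"

# canonical names are single tokens: whitespace -> underscore, separable
# punctuation removed so that a tagged token re-tokenizes to itself
md_canonicalize <- function(surface) {
  x <- gsub("\\s+", "_", trimws(surface))
  gsub(.md_split_chars_re, "", x, perl = TRUE)
}
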