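#' Entity lexicons
#'
#' A lexicon maps surface forms (possibly multi-word) to canonical entity
#' names. Matching is case-insensitive except for single-token all-uppercase
#' entries (acronyms such as `MRSA`), which are matched case-sensitively to
#' avoid false hits on common words.
#'
#' @param x A data frame (or tibble) with a `surface` column and an optional
#'   `canonical` column, or a character vector of surface forms.
#' @param entity_class `"MICROBE"` or `"DISEASE"`.
#' @return An object of class `mdlink_lexicon`: a tibble with columns
#'   `surface`, `canonical`, `tokens` (list of lowercased token vectors),
#'   `n_tokens`, and `case_sensitive`, with the entity class and its tag
#'   prefix (`BAC00` / `DIS00`) stored as attributes.
#' @export
lexicon <- function(x, entity_class = c("MICROBE", "DISEASE")) {
  entity_class <- match.arg(entity_class)
  if (is.character(x)) x <- tibble::tibble(surface = x)
  stopifnot(is.data.frame(x), "surface" %in% names(x))
  surface <- trimws(as.character(x$surface))
  if (any(!nzchar(surface))) stop("lexicon contains empty surface forms")
  canonical <- if ("canonical" %in% names(x) && !all(is.na(x$canonical))) {
    ifelse(is.na(x$canonical) | !nzchar(trimws(x$canonical)),
           md_canonicalize(surface), md_canonicalize(x$canonical))
  } else {
    md_canonicalize(surface)
  }
  if (any(grepl("\\s", canonical))) stop("canonical names must not contain whitespace")

  key <- tolower(surface)
  dup <- duplicated(key)
  if (any(dup)) {
    first <- match(key[dup], key)
    conflict <- canonical[dup] != canonical[first]
    if (any(conflict)) {
      stop("duplicate surface form with conflicting canonical names: ",
           paste(unique(surface[dup][conflict]), collapse = ", "))
    }
  }
  keep <- !dup
  surface <- surface[keep]; canonical <- canonical[keep]

  toks <- lapply(surface, function(s) tolower(md_tokenize(s)))
  if (any(lengths(toks) == 0L)) stop("lexicon contains surface forms with no tokens")
  case_sensitive <- lengths(toks) == 1L &
    surface == toupper(surface) & grepl("[A-Z]", surface)

  out <- tibble::tibble(
    surface = surface, canonical = canonical, tokens = toks,
    n_tokens = lengths(toks), case_sensitive = case_sensitive
  )
  structure(out,
            class = c("mdlink_lexicon", class(out)),
            entity_class = entity_class,
            tag_prefix = if (entity_class == "MICROBE") "BAC00" else "DIS00")
}

#' Read a lexicon from a TSV file
#'
#' The file holds one entry per line: a surface form, optionally followed by
#' a tab and a canonical name. Lines starting with `#` are comments. When the
#' canonical column is absent the canonical name is the surface form with
#' whitespace replaced by underscores. Several surfaces may share one
#' canonical name; the same surface mapping to two different canonicals is an
#' error.
#'
#' @param path Path to a UTF-8 TSV file.
#' @inheritParams lexicon
#' @return An `mdlink_lexicon`.
#' @export
load_lexicon <- function(path, entity_class = c("MICROBE", "DISEASE")) {
  entity_class <- match.arg(entity_class)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty lexicon file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lexicon(
    tibble::tibble(
      surface = vapply(parts, `[[`, "", 1L),
      canonical = vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_, "")
    ),
    entity_class = entity_class
  )
}

#' @export
print.mdlink_lexicon <- function(x, ...) {
  cat(sprintf("<mdlink_lexicon: %s, %d entries, %d canonical names>\n",
              attr(x, "entity_class"), nrow(x), length(unique(x$canonical))))
  NextMethod()
}

#' Write a lexicon to TSV
#' @param lex An `mdlink_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  writeLines(paste(lex$surface, lex$canonical, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}
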