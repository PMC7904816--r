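#' Tag microbe and disease entities in a sentence
#'
#' Scans the token stream left to right with longest-match dictionary lookup,
#' one lexicon at a time. Matched word sequences are collapsed into a single
#' tagged token, `BAC00<canonical>` for microbes and `DIS00<canonical>` for
#' diseases, so that downstream parse trees see one token per entity mention.
#' When a microbe and a disease match overlap, the lexicon applied first wins
#' (microbes by default: strain names are the more specific vocabulary).
#'
#' @param text Sentence string.
#' @param microbe_lex,disease_lex `mdlink_lexicon` objects (see [lexicon()]).
#' @param sentence_id Identifier carried through the pipeline.
#' @param priority Which entity class is matched first on overlap.
#' @return An `mdlink_sentence`: a list with `sentence_id`, `tokens` (after
#'   mention collapsing), `mentions` (tibble with `entity_class`, `token` --
#'   the index of the tagged token in `tokens` --, `canonical`,
#'   `tagged_token`, `surface`, `orig_start`, `orig_end`), and `text`.
#' @export
tag_entities <- function(text, microbe_lex, disease_lex, sentence_id = "s1",
                         priority = c("microbe", "disease")) {
  stopifnot(nzchar(text))
  priority <- match.arg(priority)
  tokens <- md_tokenize(text)
  n <- length(tokens)
  claimed <- logical(n)

  lexes <- if (priority == "microbe") list(microbe_lex, disease_lex)
           else list(disease_lex, microbe_lex)
  hits <- list()
  for (lex in lexes) {
    found <- .match_lexicon(tokens, lex, claimed)
    for (h in found) claimed[h$start:h$end] <- TRUE
    hits <- c(hits, found)
  }

  if (length(hits) == 0L) {
    mentions <- tibble::tibble(
      entity_class = character(), token = integer(), canonical = character(),
      tagged_token = character(), surface = character(),
      orig_start = integer(), orig_end = integer()
    )
    return(structure(list(sentence_id = sentence_id, tokens = tokens,
                          mentions = mentions, text = text),
                     class = "mdlink_sentence"))
  }

  ord <- order(vapply(hits, `[[`, 1L, "start"))
  hits <- hits[ord]

  # collapse spans into single tagged tokens
  new_tokens <- character(0)
  mention_rows <- list()
  i <- 1L; k <- 1L
  while (i <= n) {
    h <- if (k <= length(hits)) hits[[k]] else NULL
    if (!is.null(h) && h$start == i) {
      new_tokens <- c(new_tokens, h$tagged_token)
      mention_rows[[k]] <- tibble::tibble(
        entity_class = h$entity_class, token = length(new_tokens),
        canonical = h$canonical, tagged_token = h$tagged_token,
        surface = paste(tokens[h$start:h$end], collapse = " "),
        orig_start = h$start, orig_end = h$end
      )
      i <- h$end + 1L; k <- k + 1L
    } else {
      new_tokens <- c(new_tokens, tokens[i])
      i <- i + 1L
    }
  }

  structure(list(sentence_id = sentence_id, tokens = new_tokens,
                 mentions = dplyr::bind_rows(mention_rows), text = text),
            class = "mdlink_sentence")
}

# longest-match, leftmost-first scan; positions already claimed are blocked
.match_lexicon <- function(tokens, lex, claimed) {
  n <- length(tokens)
  if (n == 0L || nrow(lex) == 0L) return(list())
  lower <- tolower(tokens)
  prefix <- attr(lex, "tag_prefix")
  eclass <- attr(lex, "entity_class")

  ci <- lex[!lex$case_sensitive, ]
  cs <- lex[lex$case_sensitive, ]
  ci_map <- stats::setNames(ci$canonical,
                            vapply(ci$tokens, paste, "", collapse = " "))
  cs_map <- stats::setNames(cs$canonical, cs$surface)
  max_len <- max(lex$n_tokens)

  out <- list()
  i <- 1L
  while (i <= n) {
    if (claimed[i]) { i <- i + 1L; next }
    matched <- FALSE
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      j <- i + len - 1L
      if (any(claimed[i:j])) next
      canonical <- NA_character_
      key <- paste(lower[i:j], collapse = " ")
      if (!is.na(ci_map[key])) canonical <- ci_map[[key]]
      if (is.na(canonical) && len == 1L && !is.na(cs_map[tokens[i]])) {
        canonical <- cs_map[[tokens[i]]]
      }
      if (!is.na(canonical)) {
        out[[length(out) + 1L]] <- list(
          start = i, end = j, canonical = canonical,
          tagged_token = paste0(prefix, canonical), entity_class = eclass
        )
        i <- j + 1L; matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  out
}

#' @export
print.mdlink_sentence <- function(x, ...) {
  cat(sprintf("<mdlink_sentence %s: %d tokens, %d mentions>\n",
              x$sentence_id, length(x$tokens), nrow(x$mentions)))
  cat(" ", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

#' Mentions of one entity class
#' @param sentence An `mdlink_sentence`.
#' @param entity_class `"MICROBE"` or `"DISEASE"`.
#' @return The mention tibble restricted to that class.
#' @export
mentions_of <- function(sentence, entity_class) {
  dplyr::filter(sentence$mentions, .data$entity_class == !!entity_class)
}

#' Tag every sentence of a text file
#'
#' @param path Plain text (one sentence per line) or a two-column TSV
#'   (`sentence_id <TAB> text`); the format is auto-detected per line.
#' @inheritParams tag_entities
#' @return List of `mdlink_sentence` objects.
#' @export
tag_file <- function(path, microbe_lex, disease_lex,
                     priority = c("microbe", "disease")) {
  priority <- match.arg(priority)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  purrr::imap(lines, function(line, i) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) {
      tag_entities(parts[[2L]], microbe_lex, disease_lex,
                   sentence_id = parts[[1L]], priority = priority)
    } else {
      tag_entities(line, microbe_lex, disease_lex,
                   sentence_id = paste0("s", i), priority = priority)
    }
  })
}

#' Write annotated sentences as JSON lines
#'
#' One JSON object per line with fields `sentence_id`, `tokens`, `mentions`
#' and `text`.
#'
#' @param sentences List of `mdlink_sentence` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated <- function(sentences, path) {
  lines <- vapply(sentences, function(s) {
    jsonlite::toJSON(list(sentence_id = s$sentence_id, tokens = s$tokens,
                          mentions = s$mentions, text = s$text),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read annotated sentences from JSON lines
#' @param path Path written by [write_annotated()].
#' @return List of `mdlink_sentence` objects.
#' @export
read_annotated <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(lines[nzchar(lines)], function(line) {
    obj <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    mentions <- tibble::as_tibble(obj$mentions)
    if (nrow(mentions) == 0L) {
      mentions <- tibble::tibble(
        entity_class = character(), token = integer(), canonical = character(),
        tagged_token = character(), surface = character(),
        orig_start = integer(), orig_end = integer()
      )
    }
    structure(list(sentence_id = obj$sentence_id, tokens = obj$tokens,
                   mentions = mentions, text = obj$text),
              class = "mdlink_sentence")
  })
}
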