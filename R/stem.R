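#' Stem a relation word
#'
#' A light inflectional stemmer (the first step of Porter's algorithm:
#' plural \code{-s/-es/-ies} and the \code{-ed}/\code{-ing} endings with
#' e-restoration). Relation words are open-class verbs and nouns whose
#' inflected variants must collapse to one key without merging distinct
#' lemmas, so only inflection is stripped: \code{causes -> cause},
#' \code{associated -> associate}, \code{implicated -> implicate}. The full
#' Porter cascade would over-stem this vocabulary (\code{cause -> caus},
#' \code{associated -> associ}) and break the correspondence between the
#' extractors' relation words and their surface forms.
#'
#' Deterministic and idempotent: `stem_word(stem_word(w)) == stem_word(w)`.
#'
#' @param word Character vector of words.
#' @return Character vector of stems (lowercased).
#' @export
stem_word <- function(word) {
  vapply(tolower(word), .stem1, "", USE.NAMES = FALSE)
}

.has_vowel <- function(s) grepl("[aeiou]", s) || grepl("[^aeiou]y", s)

# Porter measure: number of VC blocks in the consonant/vowel pattern
.measure <- function(s) {
  if (!nzchar(s)) return(0L)
  ch <- strsplit(s, "")[[1]]
  isv <- logical(length(ch))
  for (i in seq_along(ch)) {
    isv[i] <- ch[i] %in% c("a", "e", "i", "o", "u") ||
      (ch[i] == "y" && i > 1L && !isv[i - 1L])
  }
  pat <- rle(isv)$values
  sum(head(pat, -1) & !tail(pat, -1)) + 0L  # count V followed by C
}

# stem ends consonant-vowel-consonant, last consonant not w/x/y
.ends_cvc <- function(s) {
  if (nchar(s) < 3L) return(FALSE)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  vow <- c("a", "e", "i", "o", "u")
  c3 <- !(ch[n] %in% vow); v2 <- ch[n - 1L] %in% vow
  c1 <- !(ch[n - 2L] %in% vow)
  c3 && v2 && c1 && !(ch[n] %in% c("w", "x", "y"))
}

.stem1 <- function(w) {
  # step 1a: plurals
  if (grepl("sses$", w)) w <- sub("sses$", "ss", w)
  else if (grepl("ies$", w)) w <- sub("ies$", "i", w)
  else if (grepl("(ss|us|is)$", w)) w <- w  # keep Latin singulars / copula
  else if (grepl("s$", w) && nchar(w) > 2L) w <- sub("s$", "", w)

  # step 1b: -eed / -ed / -ing
  if (grepl("eed$", w)) {
    stem <- sub("eed$", "", w)
    if (.measure(stem) > 0L) w <- sub("eed$", "ee", w)
  } else {
    hit <- FALSE
    if (grepl("ed$", w)) {
      stem <- sub("ed$", "", w)
      if (.has_vowel(stem)) { w <- stem; hit <- TRUE }
    } else if (grepl("ing$", w)) {
      stem <- sub("ing$", "", w)
      if (.has_vowel(stem)) { w <- stem; hit <- TRUE }
    }
    if (hit) {
      if (grepl("(at|bl|iz)$", w)) w <- paste0(w, "e")
      else if (grepl("([^aeiouslz])\\1$", w)) w <- sub(".$", "", w)
      else if (.measure(w) == 1L && .ends_cvc(w)) w <- paste0(w, "e")
    }
  }
  w
}
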