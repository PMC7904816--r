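#' Candidate microbe-disease pairs
#'
#' A candidate pair is one microbe mention and one disease mention in a
#' sentence. The entity occurring first in token order is `e1`; the sentence
#' splits into the phrase before `e1` (`seq1`), the phrase between the
#' entities (`seq2`) and the phrase after `e2` (`seq3`), and the shortest
#' dependency path (SDP) between the two entity tokens (endpoints excluded)
#' carries the syntactic core of the relation.
#'
#' @param parsed An `mdlink_parsed` sentence.
#' @return List of `mdlink_pair` objects, the Cartesian product of microbe
#'   and disease mentions (empty when either class is absent). Each pair has
#'   fields `sentence_id`, `microbe`, `disease` (canonical names),
#'   `microbe_token`, `disease_token`, `e1_token`, `e2_token`, `seq1`,
#'   `seq2`, `seq3` (token-index vectors), `sdp` (token-index vector), and
#'   `parsed`.
#' @export
enumerate_pairs <- function(parsed) {
  s <- parsed$sentence
  mic <- mentions_of(s, "MICROBE")
  dis <- mentions_of(s, "DISEASE")
  if (nrow(mic) == 0L || nrow(dis) == 0L) return(list())
  out <- list()
  for (i in seq_len(nrow(mic))) {
    for (j in seq_len(nrow(dis))) {
      out[[length(out) + 1L]] <- .make_pair(parsed, mic[i, ], dis[j, ])
    }
  }
  out
}

.make_pair <- function(parsed, mic, dis) {
  n <- length(parsed$sentence$tokens)
  segs <- segment_spans(mic$token, dis$token, n)
  sdp <- shortest_dep_path(mic$token, dis$token, parsed$dtree)
  structure(list(
    sentence_id = parsed$sentence$sentence_id,
    microbe = mic$canonical, disease = dis$canonical,
    microbe_token = mic$token, disease_token = dis$token,
    e1_token = segs$e1, e2_token = segs$e2,
    seq1 = segs$seq1, seq2 = segs$seq2, seq3 = segs$seq3,
    sdp = sdp, parsed = parsed
  ), class = "mdlink_pair")
}

#' Segment a sentence around two entity tokens
#'
#' @param a,b Token indices of the two entities (any order).
#' @param n Sentence length in tokens.
#' @return List with `e1`, `e2` (ordered entity indices) and the three
#'   token-index spans `seq1`, `seq2`, `seq3`; spans may be empty when an
#'   entity sits at a sentence edge or the entities are adjacent.
#' @export
segment_spans <- function(a, b, n) {
  e1 <- min(a, b); e2 <- max(a, b)
  stopifnot(e1 >= 1L, e2 <= n, e1 != e2)
  list(e1 = e1, e2 = e2,
       seq1 = if (e1 > 1L) seq.int(1L, e1 - 1L) else integer(0),
       seq2 = if (e2 - e1 > 1L) seq.int(e1 + 1L, e2 - 1L) else integer(0),
       seq3 = if (e2 < n) seq.int(e2 + 1L, n) else integer(0))
}

#' Shortest dependency path between two tokens
#'
#' The unique undirected tree path between the entity tokens; the entity
#' endpoints are excluded and the interior tokens are returned in sentence
#' order.
#'
#' @param a,b Token indices.
#' @param dtree An `mdlink_dtree`.
#' @return Integer vector of interior token indices (possibly empty).
#' @export
shortest_dep_path <- function(a, b, dtree) {
  path <- dep_path_nodes(dtree, a, b)
  interior <- setdiff(path, c(a, b))
  sort(interior)
}

# full node path a..b inclusive, via the lowest common ancestor
dep_path_nodes <- function(dtree, a, b) {
  n <- nrow(dtree)
  stopifnot(a >= 1L, a <= n, b >= 1L, b <= n)
  chain <- function(i) {
    out <- integer(0); j <- i
    while (j != 0L) { out <- c(out, j); j <- dtree$head[j] }
    out
  }
  pa <- chain(a); pb <- chain(b)
  lca <- pa[pa %in% pb][1L]
  if (is.na(lca)) stop("tokens ", a, " and ", b, " are disconnected in the dependency tree")
  up <- pa[seq_len(match(lca, pa))]
  down <- rev(pb[seq_len(match(lca, pb) - 1L)])
  c(up, down)
}

#' Tabulate candidate pairs
#' @param pairs List of `mdlink_pair` objects.
#' @return Tibble with one row per pair (sentence id, entities, token
#'   positions, segment and SDP lengths).
#' @export
pairs_tibble <- function(pairs) {
  purrr::map_dfr(pairs, function(p) {
    tibble::tibble(
      sentence_id = p$sentence_id, microbe = p$microbe, disease = p$disease,
      microbe_token = p$microbe_token, disease_token = p$disease_token,
      len_seq1 = length(p$seq1), len_seq2 = length(p$seq2),
      len_seq3 = length(p$seq3), len_sdp = length(p$sdp)
    )
  })
}

#' @export
print.mdlink_pair <- function(x, ...) {
  cat(sprintf("<mdlink_pair %s: %s ~ %s>\n", x$sentence_id, x$microbe, x$disease))
  invisible(x)
}

#' Tokens of a segment
#' @param pair An `mdlink_pair`.
#' @param which One of `"seq1"`, `"seq2"`, `"seq3"`, `"sdp"`.
#' @return Character vector of tokens.
#' @export
segment_tokens <- function(pair, which = c("seq1", "seq2", "seq3", "sdp")) {
  which <- match.arg(which)
  pair$parsed$sentence$tokens[pair[[which]]]
}
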