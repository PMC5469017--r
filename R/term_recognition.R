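# Locating candidate measurement terms in text: dictionary phrase matches,
# abbreviation regex matches, anatomy/measure word detection, and the
# concept builder that merges consecutive categorized words into new
# candidate terms.

#' Find dictionary phrase and abbreviation term mentions
#'
#' Scans `text` for boundary-respecting occurrences of dictionary surfaces
#' (matched case-insensitively with flexible internal whitespace) and of
#' the abbreviation patterns. No match may start or end inside a longer
#' alphanumeric run, so "ef" never matches inside "relief". A mention found
#' at the same span by both recognizers is kept once with origin
#' `ABBREVIATION`.
#'
#' @param text a single document string.
#' @param entries dictionary data.frame from [load_dictionary()].
#' @param abbreviations character vector of abbreviation regex patterns.
#' @return data.frame of term mentions: `start`, `end` (1-based inclusive
#'   character offsets), `text`, `surface` (normalized), `origin`.
#' @export
#' @examples
#' res <- load_resources()
#' find_phrase_terms("The LVEF = 40%", res$dictionary, res$abbreviations)
find_phrase_terms <- function(text, entries, abbreviations = character(0)) {
  out <- empty_mentions()
  pat <- surfaces_alternation(entries$surface)
  if (!is.null(pat)) {
    hits <- locate_all(text, pat)
    if (nrow(hits) > 0) {
      hits$surface <- normalize_term(hits$text)
      hits$origin <- "PHRASE"
      out <- rbind(out, hits)
    }
  }
  for (ab in abbreviations) {
    hits <- locate_all(text, with_boundaries(ab))
    if (nrow(hits) > 0) {
      hits$surface <- normalize_term(hits$text)
      hits$origin <- "ABBREVIATION"
      out <- rbind(out, hits)
    }
  }
  if (nrow(out) == 0) return(out)
  # Same-span duplicates: abbreviation matches take precedence as the more
  # specific recognizer.
  ord <- order(out$start, out$end,
               ifelse(out$origin == "ABBREVIATION", 0L, 1L),
               method = "radix")
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(paste(out$start, out$end)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_mentions <- function() {
  empty_df(start = "integer", end = "integer", text = "character",
           surface = "character", origin = "character")
}

#' Find anatomy and measure word mentions
#'
#' One mention per boundary-respecting occurrence of a word-lexicon surface;
#' overlapping surfaces are resolved longest first.
#'
#' @param text a single document string.
#' @param lexicon word lexicon from [load_word_lexicon()].
#' @return data.frame with `start`, `end`, `text`, `surface`, `category`,
#'   `group_id`.
#' @export
find_category_words <- function(text, lexicon) {
  out <- empty_df(start = "integer", end = "integer", text = "character",
                  surface = "character", category = "character",
                  group_id = "character")
  pat <- surfaces_alternation(lexicon$surface)
  if (is.null(pat)) return(out)
  hits <- locate_all(text, pat)
  if (nrow(hits) == 0) return(out)
  hits$surface <- normalize_term(hits$text)
  idx <- match(hits$surface, lexicon$surface)
  hits$category <- lexicon$category[idx]
  hits$group_id <- lexicon$group_id[idx]
  hits <- hits[!is.na(idx), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Is the text between two merged words an allowed connector gap?
builder_gap_ok <- function(gap) {
  if (grepl("\n", gap, fixed = TRUE)) return(FALSE)
  toks <- strsplit(gsub("[-/]", " ", gap), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  length(toks) == 0 || all(tolower(toks) %in% BUILDER_CONNECTORS)
}

#' Build candidate terms from consecutive anatomy/measure words
#'
#' The concept builder merges maximal runs of word mentions whose members
#' are separated only by whitespace, hyphen, slash, or connector words
#' ("of", "the", "at", ...) into a single `BUILT` term mention. A run must
#' contain at least one ANATOMY and one MEASURE word, at least two words in
#' total, and at most eight lexicon words; runs never cross a line break.
#'
#' @param words word mentions from [find_category_words()], sorted by start.
#' @param text the document string the offsets refer to.
#' @return data.frame of `BUILT` term mentions (same columns as
#'   [find_phrase_terms()]).
#' @export
build_candidate_terms <- function(words, text) {
  out <- empty_mentions()
  if (nrow(words) == 0) return(out)
  words <- words[order(words$start), , drop = FALSE]
  runs <- list()
  cur <- 1L
  if (nrow(words) >= 2) {
    for (i in seq_len(nrow(words) - 1L)) {
      gap <- substring(text, words$end[i] + 1L, words$start[i + 1L] - 1L)
      if (builder_gap_ok(gap) && words$start[i + 1L] > words$end[i]) {
        next
      }
      runs[[length(runs) + 1L]] <- cur:i
      cur <- i + 1L
    }
  }
  runs[[length(runs) + 1L]] <- cur:nrow(words)
  for (r in runs) {
    if (length(r) < 2L || length(r) > BUILDER_MAX_WORDS) next
    cats <- words$category[r]
    if (!("ANATOMY" %in% cats && "MEASURE" %in% cats)) next
    s <- words$start[r[1]]
    e <- words$end[r[length(r)]]
    covered <- substring(text, s, e)
    out <- rbind(out, data.frame(
      start = s, end = e, text = covered,
      surface = normalize_term(covered), origin = "BUILT",
      stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Resolve overlapping term mentions
#'
#' Among overlapping mentions the longest span wins; ties are broken by
#' origin priority (PHRASE > ABBREVIATION > BUILT), then by leftmost start.
#' The result is independent of the input order.
#'
#' @param mentions data.frame of term mentions.
#' @return data.frame of non-overlapping mentions sorted by start.
#' @export
resolve_overlaps <- function(mentions) {
  if (nrow(mentions) == 0) return(mentions)
  len <- mentions$end - mentions$start + 1L
  prio <- ORIGIN_PRIORITY[mentions$origin]
  ord <- order(-len, -prio, mentions$start, mentions$end, method = "radix")
  kept <- integer(0)
  for (i in ord) {
    clash <- any(mentions$start[i] <= mentions$end[kept] &
                 mentions$end[i] >= mentions$start[kept])
    if (!clash) kept <- c(kept, i)
  }
  out <- mentions[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find all candidate term mentions in a document
#'
#' Runs the phrase/abbreviation recognizer, the anatomy/measure word
#' recognizer and the concept builder, then resolves overlaps.
#'
#' @param text a single document string.
#' @param resources an `echo_resources` object.
#' @return list with `terms` (non-overlapping term mentions) and `words`
#'   (all anatomy/measure word mentions, kept for within-term linking).
#' @export
find_terms <- function(text, resources) {
  phrases <- find_phrase_terms(text, resources$dictionary,
                               resources$abbreviations)
  words <- find_category_words(text, resources$words)
  built <- build_candidate_terms(words, text)
  list(terms = resolve_overlaps(rbind(phrases, built)), words = words)
}
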