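# Two-step mapping of a term surface to a measurement concept: exact
# dictionary match, else token-overlap scoring, with semantic-constraint
# disambiguation in both paths.

#' Exact dictionary match
#'
#' @param surface normalized term surface.
#' @param entries dictionary data.frame.
#' @return the matching `concept_id`, or `NA_character_` when the surface
#'   is not a dictionary surface.
#' @export
exact_match <- function(surface, entries) {
  i <- match(surface, entries$surface)
  if (is.na(i)) NA_character_ else entries$concept_id[i]
}

#' Token-overlap scores against the dictionary
#'
#' Splits the query surface into whitespace-delimited tokens (distinct
#' tokens only; connective stop words "of", "the", "at", "a", "an", "to",
#' "and" are ignored) and scores each concept by the number of query tokens
#' that occur as tokens of at least one of that concept's dictionary
#' surfaces. For the query "left ventricular diastolic dimension" against
#' entries "left ventricular dimension at end diastole" and "left atrium
#' diameter" the scores are 3 and 1.
#'
#' @param surface normalized term surface.
#' @param entries dictionary data.frame.
#' @param stop_tokens tokens excluded from scoring.
#' @return data.frame with columns `concept_id`, `score`, sorted by
#'   descending score (ties by concept_id); concepts scoring 0 are omitted.
#' @export
token_overlap_scores <- function(surface, entries,
                                 stop_tokens = STOP_TOKENS) {
  qtok <- setdiff(unique(term_tokens(surface)), stop_tokens)
  out <- empty_df(concept_id = "character", score = "integer")
  if (length(qtok) == 0 || nrow(entries) == 0) return(out)
  concept_tokens <- lapply(split(entries$surface, entries$concept_id),
                           function(surfs) {
                             unique(unlist(lapply(surfs, term_tokens)))
                           })
  score <- vapply(concept_tokens,
                  function(toks) length(intersect(qtok, toks)), 0L)
  keep <- score > 0L
  if (!any(keep)) return(out)
  out <- data.frame(concept_id = names(concept_tokens)[keep],
                    score = unname(score[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$concept_id), , drop = FALSE]
}

# Semantic groups named by lexicon words occurring (as tokens) in a surface.
surface_groups <- function(surface, lexicon) {
  toks <- term_tokens(surface)
  hit <- lexicon$surface %in% toks
  unique(lexicon$group_id[hit])
}

# Groups mutually exclusive with any group in `groups`.
excluded_groups <- function(groups, constraints) {
  if (length(groups) == 0 || nrow(constraints) == 0) return(character(0))
  unique(c(constraints$group_b[constraints$group_a %in% groups],
           constraints$group_a[constraints$group_b %in% groups]))
}

#' Apply semantic mutual-exclusion constraints to scored candidates
#'
#' Let G be the semantic groups of word-lexicon words occurring in the
#' query surface. Every candidate concept whose anatomy or measure tags
#' contain a group mutually exclusive with some g in G is removed; scores
#' are never altered. E.g. a phrase containing "atrial" discards candidates
#' tagged ventricle, mitral or tricuspid; a phrase containing "volume"
#' discards candidates tagged dimension, velocity or pressure.
#'
#' @param surface normalized query surface.
#' @param scored data.frame of `(concept_id, score)` candidates.
#' @param lexicon word lexicon.
#' @param constraints mutual-exclusion pairs.
#' @param concepts concept inventory (provides the anatomy/measure tags).
#' @return the filtered `scored` data.frame (a subset; scores unchanged).
#' @export
apply_semantic_constraints <- function(surface, scored, lexicon, constraints,
                                       concepts) {
  if (nrow(scored) == 0) return(scored)
  g <- surface_groups(surface, lexicon)
  excl <- excluded_groups(g, constraints)
  if (length(excl) == 0) return(scored)
  idx <- match(scored$concept_id, concepts$concept_id)
  drop <- vapply(seq_len(nrow(scored)), function(i) {
    if (is.na(idx[i])) return(FALSE)
    tags <- c(concepts$anatomy_tags[[idx[i]]], concepts$measure_tags[[idx[i]]])
    length(intersect(tags, excl)) > 0
  }, TRUE)
  out <- scored[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a term surface to a measurement concept
#'
#' Two-step lookup: an exact dictionary match is used directly (after a
#' semantic-constraint check); otherwise candidates are scored by token
#' overlap and filtered by the constraints. A strict maximum maps the term;
#' a tie at the maximum is `AMBIGUOUS`; an empty candidate list is
#' `UNMAPPED`. Ambiguous and unmapped terms produce no output pairs.
#'
#' @param surface normalized term surface.
#' @param resources an `echo_resources` object.
#' @return list with `status` (MAPPED/AMBIGUOUS/UNMAPPED), `concept_id`
#'   (NA unless MAPPED) and `scored` (constraint-filtered candidates).
#' @export
map_surface <- function(surface, resources) {
  entries <- resources$dictionary
  ex <- exact_match(surface, entries)
  if (!is.na(ex)) {
    single <- data.frame(concept_id = ex,
                         score = length(setdiff(term_tokens(surface),
                                                STOP_TOKENS)),
                         stringsAsFactors = FALSE)
    single$score <- max(single$score, 1L)
    kept <- apply_semantic_constraints(surface, single, resources$words,
                                       resources$constraints,
                                       resources$concepts)
    if (nrow(kept) == 1) {
      return(list(status = "MAPPED", concept_id = ex, scored = kept))
    }
    # exact match vetoed by constraints: fall through to partial matching
  }
  scored <- token_overlap_scores(surface, entries)
  scored <- apply_semantic_constraints(surface, scored, resources$words,
                                       resources$constraints,
                                       resources$concepts)
  if (nrow(scored) == 0) {
    return(list(status = "UNMAPPED", concept_id = NA_character_,
                scored = scored))
  }
  top <- scored$score == max(scored$score)
  if (sum(top) > 1) {
    return(list(status = "AMBIGUOUS", concept_id = NA_character_,
                scored = scored))
  }
  list(status = "MAPPED", concept_id = scored$concept_id[which(top)],
       scored = scored)
}

#' Map all term mentions of a document
#'
#' @param mentions term-mention data.frame from [find_terms()].
#' @param resources an `echo_resources` object.
#' @return `mentions` with added columns `status`, `concept_id`, `score`.
#' @export
map_terms <- function(mentions, resources) {
  if (nrow(mentions) == 0) {
    mentions$status <- character(0)
    mentions$concept_id <- character(0)
    mentions$score <- integer(0)
    return(mentions)
  }
  res <- lapply(mentions$surface, map_surface, resources = resources)
  mentions$status <- vapply(res, `[[`, "", "status")
  mentions$concept_id <- vapply(res, `[[`, "", "concept_id")
  mentions$score <- vapply(res, function(r) {
    if (nrow(r$scored) == 0) 0L else as.integer(max(r$scored$score))
  }, 0L)
  mentions
}
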