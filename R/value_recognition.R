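# Recognition of quantitative values, qualitative grades, units, and
# merging of adjacent point values into ranges.

RANGE_CONNECTOR <- "^\\s*(?:-|–|—|to|through)\\s*$"

# How far (in characters) a unit may trail a number and still attach.
UNIT_ATTACH_GAP <- 2L

empty_values <- function() {
  empty_df(start = "integer", end = "integer", text = "character",
           kind = "character", low = "numeric", high = "numeric",
           low_text = "character", high_text = "character",
           unit_id = "character", is_range = "logical")
}

# Alternation regex over all unit surfaces, longest first; no boundary on
# the left ("16mm"), token boundary on the right.
unit_alternation <- function(units) {
  surfs <- unlist(units$surfaces)
  if (length(surfs) == 0) return(NULL)
  surfs <- surfs[order(-nchar(surfs), surfs)]
  paste0("(?:", paste(vapply(surfs, surface_fragment, ""), collapse = "|"),
         ")(?![[:alnum:]])")
}

unit_id_for_surface <- function(surface, units) {
  surface <- normalize_term(surface)
  for (i in seq_len(nrow(units))) {
    if (surface %in% units$surfaces[[i]]) return(units$unit_id[i])
  }
  NA_character_
}

#' Find quantitative value mentions
#'
#' Recognizes integers and decimals with an optionally attached unit (the
#' unit may trail by at most two characters, as in "2 cm"). Adjacent
#' numbers joined by a range connector ("-", "to", an en dash) are merged
#' into a single range mention. Context guards exclude numbers that are
#' part of date/ratio constructs (`120/80`, `03/14/2019`) or clock times
#' (`12:30`).
#'
#' @param text a single document string.
#' @param units unit table from [load_units()].
#' @return data.frame of value mentions: `start`, `end`, `text`, `kind`
#'   ("QUANT"), `low`, `high`, `low_text`, `high_text`, `unit_id`,
#'   `is_range`.
#' @export
#' @examples
#' res <- load_resources()
#' find_quantitative_values("LVEF was 50-55%", res$units)
find_quantitative_values <- function(text, units) {
  out <- empty_values()
  hits <- locate_all(text, "(?<![[:alnum:].])\\d+(?:\\.\\d+)?(?!\\.?\\d)",
                     ignore_case = FALSE)
  if (nrow(hits) == 0) return(out)
  upat <- unit_alternation(units)
  keep <- logical(nrow(hits))
  unit_id <- rep(NA_character_, nrow(hits))
  end <- hits$end
  for (i in seq_len(nrow(hits))) {
    before <- substring(text, max(1L, hits$start[i] - 3L), hits$start[i] - 1L)
    after <- substring(text, hits$end[i] + 1L,
                       min(nchar(text), hits$end[i] + 3L))
    # date / blood-pressure / clock-time guards
    if (grepl("\\d\\s?/\\s?$", before) || grepl("^\\s?/\\s?\\d", after) ||
        grepl("\\d:$", before) || grepl("^:\\d", after)) {
      next
    }
    keep[i] <- TRUE
    if (!is.null(upat)) {
      tail_txt <- substring(text, hits$end[i] + 1L,
                            min(nchar(text), hits$end[i] + 24L))
      um <- regexpr(paste0("(?i)^ {0,", UNIT_ATTACH_GAP, "}(?:", upat, ")"),
                    tail_txt, perl = TRUE)
      if (um[1] == 1) {
        ulen <- attr(um, "match.length")
        usurf <- trimws(substring(tail_txt, 1L, ulen))
        unit_id[i] <- unit_id_for_surface(usurf, units)
        end[i] <- hits$end[i] + ulen
      }
    }
  }
  if (!any(keep)) return(out)
  idx <- which(keep)
  out <- data.frame(
    start = hits$start[idx], end = end[idx],
    text = substring(text, hits$start[idx], end[idx]),
    kind = "QUANT",
    low = as.numeric(hits$text[idx]), high = as.numeric(hits$text[idx]),
    low_text = hits$text[idx], high_text = hits$text[idx],
    unit_id = unit_id[idx], is_range = FALSE,
    stringsAsFactors = FALSE
  )
  merge_ranges(out, text)
}

#' Find qualitative value mentions
#'
#' Boundary-respecting matches of qualitative-lexicon surfaces (longest
#' first, so "moderately severe" beats "severe"). Two grades joined by a
#' range connector ("low to moderate") are merged into one range mention
#' whose endpoints are the grade ranks.
#'
#' @param text a single document string.
#' @param qual qualitative lexicon from [load_qualitative()].
#' @return data.frame of value mentions with `kind = "QUAL"`; `low`/`high`
#'   hold grade ranks, `low_text`/`high_text` the grade surfaces.
#' @export
find_qualitative_values <- function(text, qual) {
  out <- empty_values()
  pat <- surfaces_alternation(qual$surface)
  if (is.null(pat)) return(out)
  hits <- locate_all(text, pat)
  if (nrow(hits) == 0) return(out)
  surf <- normalize_term(hits$text)
  rank <- qual$grade_rank[match(surf, qual$surface)]
  out <- data.frame(
    start = hits$start, end = hits$end, text = hits$text,
    kind = "QUAL", low = as.numeric(rank), high = as.numeric(rank),
    low_text = surf, high_text = surf,
    unit_id = NA_character_, is_range = FALSE,
    stringsAsFactors = FALSE
  )
  merge_ranges(out, text)
}

#' Merge adjacent point values into ranges
#'
#' Scans value mentions left to right; two same-kind point mentions
#' separated only by a range connector merge into one range (the merge is
#' left-greedy and a merged range does not merge again, so a chain
#' "40 - 45 - 50" deterministically yields the range 40-45 plus the point
#' 50). The merged unit is the right endpoint's unit when present, else the
#' left's; endpoints are ordered so that `low <= high`.
#'
#' @param values value mentions sorted by offset.
#' @param text the document string the offsets refer to.
#' @return data.frame of value mentions with ranges merged.
#' @export
merge_ranges <- function(values, text) {
  if (nrow(values) <= 1) return(values)
  values <- values[order(values$start), , drop = FALSE]
  out <- list()
  cur <- values[1, , drop = FALSE]
  for (i in 2:nrow(values)) {
    nxt <- values[i, , drop = FALSE]
    gap <- substring(text, cur$end + 1L, nxt$start - 1L)
    if (!cur$is_range && !nxt$is_range && cur$kind == nxt$kind &&
        !grepl("\n", gap, fixed = TRUE) &&
        grepl(RANGE_CONNECTOR, gap, ignore.case = TRUE, perl = TRUE)) {
      lo_first <- cur$low <= nxt$low
      merged <- cur
      merged$low <- min(cur$low, nxt$low)
      merged$high <- max(cur$high, nxt$high)
      merged$low_text <- if (lo_first) cur$low_text else nxt$low_text
      merged$high_text <- if (lo_first) nxt$high_text else cur$high_text
      merged$unit_id <- if (!is.na(nxt$unit_id)) nxt$unit_id else cur$unit_id
      merged$end <- nxt$end
      merged$text <- substring(text, merged$start, merged$end)
      merged$is_range <- TRUE
      cur <- merged
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- nxt
    }
  }
  out[[length(out) + 1L]] <- cur
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Find unit mentions not already consumed by a value
#'
#' @param text a single document string.
#' @param units unit table.
#' @param exclude data.frame with `start`/`end` spans (typically value
#'   mentions) inside which unit occurrences are skipped.
#' @return data.frame with `start`, `end`, `text`, `unit_id`.
#' @export
find_units <- function(text, units, exclude = NULL) {
  out <- empty_df(start = "integer", end = "integer", text = "character",
                  unit_id = "character")
  pat <- unit_alternation(units)
  if (is.null(pat)) return(out)
  hits <- locate_all(text, paste0("(?<![[:alnum:]])", pat))
  if (nrow(hits) == 0) return(out)
  hits$unit_id <- vapply(hits$text, unit_id_for_surface, "", units = units)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    inside <- vapply(seq_len(nrow(hits)), function(i) {
      any(hits$start[i] >= exclude$start & hits$end[i] <= exclude$end)
    }, TRUE)
    hits <- hits[!inside, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Find all value mentions (quantitative and qualitative) in a document
#'
#' @param text a single document string.
#' @param resources an `echo_resources` object.
#' @return list with `values` (both kinds, sorted by start) and `units`
#'   (detached unit mentions).
#' @export
find_values <- function(text, resources) {
  quant <- find_quantitative_values(text, resources$units)
  qual <- find_qualitative_values(text, resources$qualitative)
  values <- rbind(quant, qual)
  values <- values[order(values$start), , drop = FALSE]
  rownames(values) <- NULL
  units <- find_units(text, resources$units, exclude = values)
  list(values = values, units = units)
}
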