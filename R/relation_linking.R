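# Linking mapped term mentions to value mentions through the configured
# co-occurrence pattern rules, producing measurement-value pairs.

# Verb-ish connectors tolerated between the head words and the value in the
# within-term qualitative rule ("aortic valve has mild stenosis").
WITHIN_CONNECTORS <- c("of", "the", "at", "a", "an", "and",
                       "has", "have", "with", "shows", "is", "was",
                       "appears")

#' Load the co-occurrence pattern configuration
#'
#' Reads `patterns.cfg`: one rule per record with columns rule_id,
#' priority, slots, sep_class, sep_regex, value_kind, is_range, unit_mode,
#' max_gap, scope. The shipped configuration realizes 38 rules crossing the
#' semi-structured separators ("=", ":"), narrative verb phrases,
#' parenthesized and bare-column layouts with unit attached/detached/absent
#' and point/range values, plus the three qualitative positions (value
#' before, after, or inside the term).
#'
#' @param path path to a pattern config file.
#' @return data.frame of pattern rules ordered by priority.
#' @export
load_patterns <- function(path) {
  res <- read_resource_lines(path)
  n <- length(res$fields)
  if (n == 0) {
    warning("pattern config is empty: ", path)
    return(empty_df(rule_id = "character", priority = "integer",
                    slots = "character", sep_class = "character",
                    sep_regex = "character", value_kind = "character",
                    is_range = "logical", unit_mode = "character",
                    max_gap = "integer", scope = "character"))
  }
  for (i in seq_len(n)) {
    if (length(res$fields[[i]]) != 10) {
      stop("patterns: line ", res$line[i], ": expected 10 fields, got ",
           length(res$fields[[i]]), call. = FALSE)
    }
  }
  f <- function(k) vapply(res$fields, `[[`, "", k)
  out <- data.frame(
    rule_id = f(1), priority = as.integer(f(2)), slots = f(3),
    sep_class = f(4), sep_regex = f(5), value_kind = f(6),
    is_range = toupper(f(7)) == "TRUE", unit_mode = f(8),
    max_gap = as.integer(f(9)), scope = f(10),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$rule_id)) {
    stop("patterns: duplicate rule_id '",
         out$rule_id[duplicated(out$rule_id)][1], "'", call. = FALSE)
  }
  for (i in seq_len(nrow(out))) {
    slots <- strsplit(out$slots[i], " ", fixed = TRUE)[[1]]
    n_term <- sum(slots %in% c("TERM")) +
      (("TERM_HEAD" %in% slots) && ("TERM_TAIL" %in% slots))
    if (n_term != 1 || sum(slots == "VALUE") != 1) {
      stop("patterns: rule '", out$rule_id[i],
           "': slot sequence must contain exactly one TERM and one VALUE",
           call. = FALSE)
    }
    if (out$max_gap[i] < 0) {
      stop("patterns: rule '", out$rule_id[i], "': max_gap must be >= 0",
           call. = FALSE)
    }
    if (!out$scope[i] %in% c("LINE", "SENTENCE")) {
      stop("patterns: rule '", out$rule_id[i], "': scope must be LINE or ",
           "SENTENCE", call. = FALSE)
    }
  }
  out[order(out$priority), , drop = FALSE]
}

# Line windows of a document: data.frame(line, start, end) with 1-based
# inclusive offsets; the newline itself belongs to no window.
segment_lines <- function(text) {
  if (!nzchar(text)) return(empty_df(line = "integer", start = "integer",
                                     end = "integer"))
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0) lines <- ""
  start <- cumsum(c(1L, nchar(lines) + 1L))[seq_along(lines)]
  data.frame(line = seq_along(lines), start = start,
             end = start + nchar(lines) - 1L)
}

# Sentence windows: lines split further at ". ", ";" boundaries.
segment_sentences <- function(text) {
  ln <- segment_lines(text)
  out <- list()
  for (i in seq_len(nrow(ln))) {
    seg_text <- substring(text, ln$start[i], ln$end[i])
    cuts <- locate_all(seg_text, "\\.\\s+|;\\s*", ignore_case = FALSE)
    bounds <- c(0L, cuts$end, nchar(seg_text))
    starts <- head(bounds, -1) + 1L
    ends <- c(cuts$start - 1L, nchar(seg_text))
    keep <- starts <= ends
    out[[i]] <- data.frame(line = ln$line[i],
                           start = ln$start[i] + starts[keep] - 1L,
                           end = ln$start[i] + ends[keep] - 1L)
  }
  out <- do.call(rbind, out) %||%
    empty_df(line = "integer", start = "integer", end = "integer")
  out
}

in_window <- function(df, w) df$start >= w$start & df$end <= w$end

# Does `gap` fully match the rule's separator regex?
sep_matches <- function(gap, sep_regex) {
  grepl(paste0("^(?:", sep_regex, ")$"), gap, perl = TRUE, ignore.case = TRUE)
}

# Value filter for a rule: kind, rangeness, unit mode.
value_admissible <- function(values, rule) {
  ok <- values$kind == rule$value_kind & values$is_range == rule$is_range
  if (rule$unit_mode == "attached") ok <- ok & !is.na(values$unit_id)
  if (rule$unit_mode %in% c("detached", "absent")) {
    ok <- ok & is.na(values$unit_id)
  }
  ok
}

# Compatibility of a value kind with a concept's declared value kind.
kind_compatible <- function(kind, value_kind) {
  (value_kind == "BOTH") ||
    (value_kind == "QUANTITATIVE" && kind == "QUANT") ||
    (value_kind == "QUALITATIVE" && kind == "QUAL")
}

empty_pairs <- function() {
  empty_df(doc_id = "character", line = "integer", concept_id = "character",
           value_kind = "character", value_low = "numeric",
           value_high = "numeric", value_low_text = "character",
           value_high_text = "character", is_range = "logical",
           unit_id = "character", unit_ok = "logical", rule_id = "character",
           term_text = "character", term_start = "integer",
           term_end = "integer", value_start = "integer",
           value_end = "integer")
}

make_pair <- function(doc_id, line, concept, value, unit_id, rule_id,
                      term_text, term_start, term_end, resources) {
  cunits <- resources$concepts$units[[
    match(concept, resources$concepts$concept_id)]]
  unit_ok <- is.na(unit_id) || length(cunits) == 0 || unit_id %in% cunits
  data.frame(
    doc_id = doc_id, line = line, concept_id = concept,
    value_kind = value$kind, value_low = value$low, value_high = value$high,
    value_low_text = value$low_text, value_high_text = value$high_text,
    is_range = value$is_range, unit_id = unit_id, unit_ok = unit_ok,
    rule_id = rule_id, term_text = term_text,
    term_start = term_start, term_end = term_end,
    value_start = value$start, value_end = value$end,
    stringsAsFactors = FALSE
  )
}

#' Link mapped term mentions to value mentions
#'
#' Applies the pattern rules in priority order. A rule matches when its
#' slot sequence is realized inside one scope window (line or sentence)
#' with the text between slots fully matching the rule's separator class,
#' gaps no longer than `max_gap`, and no other term mention between the
#' TERM and VALUE slots. Each mention participates in at most one pair.
#' Pairs whose value kind is incompatible with the concept are never
#' emitted; pairs whose unit is incompatible with the concept are flagged
#' (`unit_ok = FALSE`) or dropped according to `resources$unit_mismatch`.
#'
#' @param doc_id document identifier carried into the output.
#' @param text the document string.
#' @param terms mapped term mentions (from [map_terms()]).
#' @param values value mentions (from [find_values()]).
#' @param units detached unit mentions.
#' @param words anatomy/measure word mentions (for the within-term rule).
#' @param resources an `echo_resources` object.
#' @return data.frame of measurement-value pairs.
#' @export
link_measurement_values <- function(doc_id, text, terms, values, units,
                                    words, resources) {
  rules <- resources$patterns
  out <- empty_pairs()
  lines <- segment_lines(text)
  sentences <- segment_sentences(text)
  mapped <- terms[terms$status == "MAPPED", , drop = FALSE]
  all_term_spans <- terms
  term_used <- rep(FALSE, nrow(mapped))
  value_used <- rep(FALSE, nrow(values))

  line_of <- function(pos) {
    i <- which(lines$start <= pos & pos <= lines$end)
    if (length(i) == 0) NA_integer_ else lines$line[i[1]]
  }

  intervening_term <- function(lo, hi) {
    any(all_term_spans$start > lo & all_term_spans$end < hi)
  }

  for (r in seq_len(nrow(rules))) {
    rule <- rules[r, , drop = FALSE]
    windows <- if (rule$scope == "LINE") lines else sentences
    slots <- strsplit(rule$slots, " ", fixed = TRUE)[[1]]
    for (w in seq_len(nrow(windows))) {
      win <- windows[w, , drop = FALSE]
      t_idx <- which(!term_used & in_window(mapped, win))
      v_idx <- which(!value_used & in_window(values, win) &
                       value_admissible(values, rule))
      if (identical(slots, c("TERM_HEAD", "VALUE", "TERM_TAIL"))) {
        for (vi in v_idx) {
          if (value_used[vi]) next
          pair <- match_within_term(doc_id, text, values[vi, , drop = FALSE],
                                    words, win, rule, resources, line_of)
          if (!is.null(pair)) {
            out <- rbind(out, pair)
            value_used[vi] <- TRUE
          }
        }
        next
      }
      if (length(t_idx) == 0 || length(v_idx) == 0) next
      value_first <- slots[1] == "VALUE"
      for (ti in t_idx[order(mapped$start[t_idx])]) {
        if (term_used[ti]) next
        term <- mapped[ti, , drop = FALSE]
        if (!kind_compatible(rule$value_kind, resources$concepts$value_kind[
          match(term$concept_id, resources$concepts$concept_id)])) next
        cand <- v_idx[!value_used[v_idx]]
        if (value_first) {
          cand <- cand[values$end[cand] < term$start]
          cand <- rev(cand[order(values$start[cand])])  # nearest first
        } else {
          cand <- cand[values$start[cand] > term$end]
          cand <- cand[order(values$start[cand])]       # nearest first
        }
        for (vi in cand) {
          val <- values[vi, , drop = FALSE]
          if (value_first) {
            gap <- substring(text, val$end + 1L, term$start - 1L)
            lo <- val$end; hi <- term$start
          } else {
            gap <- substring(text, term$end + 1L, val$start - 1L)
            lo <- term$end; hi <- val$start
          }
          if (nchar(gap) > rule$max_gap) break
          if (!sep_matches(gap, rule$sep_regex)) next
          if (intervening_term(lo, hi)) next
          unit_id <- val$unit_id
          val_out <- val
          if (rule$unit_mode == "detached") {
            u <- which(units$start > val$end &
                         units$start - val$end - 1L <= 3L &
                         in_window(units, win))
            if (length(u) == 0) next
            u <- u[order(units$start[u])][1]
            ugap <- substring(text, val$end + 1L, units$start[u] - 1L)
            if (!grepl("^\\s*$", ugap)) next
            unit_id <- units$unit_id[u]
            val_out$end <- units$end[u]
          }
          out <- rbind(out, make_pair(doc_id, line_of(term$start),
                                      term$concept_id, val_out, unit_id,
                                      rule$rule_id, term$text, term$start,
                                      term$end, resources))
          term_used[ti] <- TRUE
          value_used[vi] <- TRUE
          break
        }
      }
    }
  }
  if (identical(resources$unit_mismatch, "drop")) {
    out <- out[out$unit_ok, , drop = FALSE]
  }
  out <- out[order(out$term_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Within-term qualitative rule: TERM_HEAD VALUE TERM_TAIL, e.g.
# "aortic valve has mild stenosis". Word mentions adjacent to the value
# (connector/verb gaps only) are concatenated head + tail and mapped as one
# surface; a MAPPED result emits a pair.
match_within_term <- function(doc_id, text, value, words, win, rule,
                              resources, line_of) {
  w_idx <- which(in_window(words, win))
  if (length(w_idx) == 0) return(NULL)
  ws <- words[w_idx, , drop = FALSE]
  ws <- ws[order(ws$start), , drop = FALSE]
  gap_ok <- function(lo, hi) {
    gap <- substring(text, lo, hi)
    if (nchar(gap) > rule$max_gap) return(FALSE)
    toks <- strsplit(gsub("[-/]", " ", gap), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    length(toks) == 0 || all(tolower(toks) %in% WITHIN_CONNECTORS)
  }
  before <- which(ws$end < value$start)
  after <- which(ws$start > value$end)
  # contiguous run of words ending just before the value
  head_run <- integer(0)
  if (length(before) > 0) {
    i <- before[length(before)]
    if (gap_ok(ws$end[i] + 1L, value$start - 1L)) {
      head_run <- i
      while (i > 1 && (i - 1) %in% before &&
             gap_ok(ws$end[i - 1L] + 1L, ws$start[i] - 1L)) {
        i <- i - 1L
        head_run <- c(i, head_run)
      }
    }
  }
  tail_run <- integer(0)
  if (length(after) > 0) {
    i <- after[1]
    if (gap_ok(value$end + 1L, ws$start[i] - 1L)) {
      tail_run <- i
      while ((i + 1) <= nrow(ws) && (i + 1) %in% after &&
             gap_ok(ws$end[i] + 1L, ws$start[i + 1L] - 1L)) {
        i <- i + 1L
        tail_run <- c(tail_run, i)
      }
    }
  }
  if (length(head_run) == 0 || length(tail_run) == 0) return(NULL)
  surface <- normalize_term(paste(
    paste(ws$surface[head_run], collapse = " "),
    paste(ws$surface[tail_run], collapse = " ")
  ))
  m <- map_surface(surface, resources)
  if (!identical(m$status, "MAPPED")) return(NULL)
  vk <- resources$concepts$value_kind[
    match(m$concept_id, resources$concepts$concept_id)]
  if (!kind_compatible(value$kind, vk)) return(NULL)
  term_start <- ws$start[head_run[1]]
  term_end <- ws$end[tail_run[length(tail_run)]]
  make_pair(doc_id, line_of(term_start), m$concept_id, value,
            value$unit_id, rule$rule_id,
            substring(text, term_start, term_end), term_start, term_end,
            resources)
}

#' Extract measurement-value pairs from one document
#'
#' Full pipeline composition: term recognition (dictionary phrases,
#' abbreviations, concept builder), concept mapping, value recognition,
#' and pattern-based relationship linking. Deterministic for fixed input
#' and resources.
#'
#' @param text the document text.
#' @param resources an `echo_resources` object (default: shipped resources).
#' @param doc_id document identifier carried into the output.
#' @return data.frame of measurement-value pairs (one row per pair) with
#'   concept, value endpoints, unit, provenance spans and the rule that
#'   licensed the link.
#' @export
#' @examples
#' extract_document("LVEF = 40%")
extract_document <- function(text, resources = load_resources(),
                             doc_id = "doc1") {
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  tm <- find_terms(text, resources)
  terms <- map_terms(tm$terms, resources)
  vals <- find_values(text, resources)
  link_measurement_values(doc_id, text, terms, vals$values, vals$units,
                          tm$words, resources)
}

#' Extract measurement-value pairs from a corpus
#'
#' Applies [extract_document()] to every document; a failing document is
#' recorded as an error and the run continues.
#'
#' @param corpus data.frame with columns `doc_id`, `text` (and optionally
#'   `source_type`, `title`), as returned by [read_corpus()].
#' @param resources an `echo_resources` object.
#' @return list with `pairs` (row-bound pair data.frame) and `errors`
#'   (data.frame of doc_id/message for failed documents).
#' @export
extract_corpus <- function(corpus, resources = load_resources()) {
  pairs <- list()
  errors <- empty_df(doc_id = "character", message = "character")
  for (i in seq_len(nrow(corpus))) {
    res <- tryCatch(
      extract_document(corpus$text[i], resources, doc_id = corpus$doc_id[i]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors <- rbind(errors, data.frame(doc_id = corpus$doc_id[i],
                                         message = conditionMessage(res),
                                         stringsAsFactors = FALSE))
    } else {
      pairs[[length(pairs) + 1L]] <- res
    }
  }
  pairs <- do.call(rbind, pairs) %||% empty_pairs()
  rownames(pairs) <- NULL
  list(pairs = pairs, errors = errors)
}
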