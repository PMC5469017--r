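# Corpus I/O, corpus filtering, semantic-bootstrapping candidate
# harvesting for dictionary curation, and the precision/recall evaluation
# harness.

CORPUS_SOURCE_TYPES <- c("TIU", "Echo", "Radiology", "plain")

#' Read a document corpus
#'
#' Supports JSONL (one JSON object per line with fields `doc_id`,
#' `source_type`, `title`, `text`) and CSV with the same columns. Missing
#' `source_type` defaults to "plain"; missing `title` to "".
#'
#' @param path path to a `.jsonl`/`.json` or `.csv` corpus file.
#' @return data.frame with columns `doc_id`, `source_type`, `title`, `text`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(ln) jsonlite::fromJSON(ln))
    out <- data.frame(
      doc_id = vapply(rows, function(r) as.character(r$doc_id), ""),
      source_type = vapply(rows, function(r)
        as.character(r$source_type %||% "plain"), ""),
      title = vapply(rows, function(r) as.character(r$title %||% ""), ""),
      text = vapply(rows, function(r) as.character(r$text %||% ""), ""),
      stringsAsFactors = FALSE
    )
  } else {
    out <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!"doc_id" %in% names(out) || !"text" %in% names(out)) {
      stop("corpus CSV must have doc_id and text columns", call. = FALSE)
    }
    if (is.null(out$source_type)) out$source_type <- "plain"
    if (is.null(out$title)) out$title <- ""
    out <- out[, c("doc_id", "source_type", "title", "text")]
  }
  if (anyDuplicated(out$doc_id)) {
    stop("corpus: duplicate doc_id '", out$doc_id[duplicated(out$doc_id)][1],
         "'", call. = FALSE)
  }
  out
}

#' Write a document corpus as JSONL
#'
#' @param corpus data.frame with `doc_id`, `source_type`, `title`, `text`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(doc_id = corpus$doc_id[i],
                          source_type = corpus$source_type[i],
                          title = corpus$title[i],
                          text = corpus$text[i]), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Filter a corpus by title substrings
#'
#' Retains documents whose lower-cased title contains at least one of the
#' given substrings. The defaults reproduce the targeted-corpus filter used
#' for echocardiography-related notes ("echo", "card").
#'
#' @param corpus corpus data.frame.
#' @param substrings character vector of lower-case substrings.
#' @return the retained subset of `corpus`.
#' @export
filter_corpus_by_title <- function(corpus, substrings = c("echo", "card")) {
  title <- tolower(corpus$title %||% character(nrow(corpus)))
  keep <- vapply(title, function(tt) {
    nzchar(tt) && any(vapply(substrings, grepl, TRUE, x = tt, fixed = TRUE))
  }, TRUE)
  out <- corpus[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter documents by mapped concept-mention count
#'
#' Retains documents containing at least `min_count` term mentions that map
#' to a target concept, a surrogate that distinguishes actual echocardiogram
#' reports from general-purpose notes that mention a measure in passing.
#'
#' @param corpus corpus data.frame.
#' @param resources an `echo_resources` object.
#' @param min_count minimum number of MAPPED term mentions (default 10).
#' @return the retained subset of `corpus`.
#' @export
filter_docs_by_concept_count <- function(corpus, resources, min_count = 10) {
  if (min_count <= 0) return(corpus)
  keep <- vapply(seq_len(nrow(corpus)), function(i) {
    tm <- find_terms(corpus$text[i], resources)
    terms <- map_terms(tm$terms, resources)
    sum(terms$status == "MAPPED") >= min_count
  }, TRUE)
  out <- corpus[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harvest term candidates by semantic bootstrapping
#'
#' Scans every line of every document for the semi-structured slot pattern
#' `<candidate string> <= or :> <number> <optional unit>`; the string in
#' the concept slot, when not already a dictionary surface, is recorded as
#' a term candidate for human curation. Candidates are aggregated by
#' frequency (descending) with up to `max_contexts` example lines each.
#'
#' @param corpus corpus data.frame.
#' @param resources an `echo_resources` object (provides the dictionary of
#'   already-known surfaces).
#' @param max_contexts number of sample context lines to keep per candidate.
#' @return data.frame with columns `candidate`, `frequency`, `contexts`,
#'   `decision` (blank, to be filled during curation), sorted by descending
#'   frequency.
#' @export
harvest_term_candidates <- function(corpus, resources, max_contexts = 3) {
  slot_re <- paste0(
    "^\\s*([A-Za-z][A-Za-z /.'-]*?)\\s*[:=]\\s*",                # concept slot
    "\\d+(?:\\.\\d+)?",                                          # number
    "(?:\\s*(?:-|–|—|to)\\s*\\d+(?:\\.\\d+)?)?",       # optional range
    "\\s*[A-Za-z%^/2]{0,8}\\s*\\.?\\s*$"                         # optional unit
  )
  tally <- new.env(parent = emptyenv())
  contexts <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(corpus))) {
    for (line in strsplit(corpus$text[i], "\n", fixed = TRUE)[[1]]) {
      m <- regmatches(line, regexec(slot_re, line, perl = TRUE))[[1]]
      if (length(m) == 0) next
      cand <- normalize_term(m[2])
      if (!nzchar(cand) || cand %in% resources$dictionary$surface) next
      tally[[cand]] <- get0(cand, envir = tally, ifnotfound = 0L) + 1L
      ctx <- get0(cand, envir = contexts, ifnotfound = character(0))
      if (length(ctx) < max_contexts) contexts[[cand]] <- c(ctx, trimws(line))
    }
  }
  cands <- ls(tally)
  if (length(cands) == 0) {
    return(empty_df(candidate = "character", frequency = "integer",
                    contexts = "character", decision = "character"))
  }
  out <- data.frame(
    candidate = cands,
    frequency = vapply(cands, function(k) tally[[k]], 0L),
    contexts = vapply(cands, function(k)
      paste(contexts[[k]], collapse = " | "), ""),
    decision = "",
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$frequency, out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge curated candidates into a dictionary
#'
#' Appends candidates whose `decision` column names a concept_id to the
#' dictionary, closing the iterative curation loop (harvest, curate, merge,
#' re-process).
#'
#' @param candidates data.frame from [harvest_term_candidates()], with the
#'   `decision` column filled with a concept_id for accepted candidates
#'   (blank or "reject" otherwise).
#' @param dictionary dictionary data.frame to extend.
#' @param concepts concept inventory for validating decisions.
#' @return the extended dictionary data.frame.
#' @export
merge_candidates <- function(candidates, dictionary, concepts) {
  acc <- candidates[nzchar(candidates$decision) &
                      candidates$decision != "reject", , drop = FALSE]
  if (nrow(acc) == 0) return(dictionary)
  unknown <- !acc$decision %in% concepts$concept_id
  if (any(unknown)) {
    stop("merge_candidates: unknown concept_id '",
         acc$decision[which(unknown)[1]], "'", call. = FALSE)
  }
  add <- data.frame(surface = normalize_term(acc$candidate),
                    concept_id = acc$decision,
                    line = NA_integer_, stringsAsFactors = FALSE)
  out <- rbind(dictionary, add[!add$surface %in% dictionary$surface, ,
                               drop = FALSE])
  rownames(out) <- NULL
  out
}

# match key for predicted-vs-gold comparison
pair_key <- function(df, use_unit) {
  unit <- if (use_unit) ifelse(is.na(df$unit_id), "", df$unit_id) else ""
  paste(df$doc_id, df$concept_id, df$value_kind,
        as.character(df$value_low), as.character(df$value_high),
        unit, sep = "\r")
}

#' Evaluate predicted pairs against gold annotations
#'
#' A predicted pair is a true positive when a gold annotation in the same
#' document has the same concept, value kind and value endpoints, and --
#' when the gold annotation specifies one -- the same unit. Matching is
#' one-to-one; unmatched predictions are false positives and unmatched gold
#' annotations false negatives. With `collapse_repeated = TRUE`, a missed
#' gold annotation whose (concept, value) was correctly extracted elsewhere
#' in the same document is not counted as a miss; repeated statements of
#' the same measurement add no information, so the collapsed recall is
#' reported alongside the strict one.
#'
#' @param predicted data.frame of pairs (as from [extract_document()]).
#' @param gold data.frame of gold annotations with columns `doc_id`,
#'   `concept_id`, `value_kind`, `value_low`, `value_high`, `unit_id`.
#' @param collapse_repeated if TRUE, `recall` itself is reported collapsed;
#'   `recall_collapsed` is always present.
#' @return object of class `echo_eval`: list with `overall` (one-row
#'   data.frame: tp, fp, fn, precision, recall, f1, recall_collapsed) and
#'   `per_concept` (same columns per concept).
#' @export
evaluate_extractions <- function(predicted, gold, collapse_repeated = FALSE) {
  extra <- setdiff(unique(predicted$doc_id), unique(gold$doc_id))
  if (length(extra) > 0 && nrow(gold) > 0) {
    stop("evaluation: predicted doc_id not present in gold: ", extra[1],
         call. = FALSE)
  }
  gkey <- pair_key(gold, use_unit = TRUE)
  gkey_nounit <- pair_key(gold, use_unit = FALSE)
  pkey <- pair_key(predicted, use_unit = TRUE)
  gold_unit_known <- !is.na(gold$unit_id) & nzchar(ifelse(is.na(gold$unit_id),
                                                          "", gold$unit_id))
  matched_gold <- rep(FALSE, nrow(gold))
  matched_pred <- rep(FALSE, nrow(predicted))
  for (i in seq_len(nrow(predicted))) {
    # gold with a stated unit must match on unit; gold without one matches
    # regardless of the predicted unit
    j <- which(!matched_gold &
                 ifelse(gold_unit_known, gkey == pkey[i],
                        gkey_nounit == pair_key(predicted[i, , drop = FALSE],
                                                use_unit = FALSE)))
    if (length(j) > 0) {
      matched_gold[j[1]] <- TRUE
      matched_pred[i] <- TRUE
    }
  }
  # a missed gold row is "repeated" if some matched gold row in the same doc
  # shares its (concept, value)
  repeated_miss <- rep(FALSE, nrow(gold))
  if (nrow(gold) > 0) {
    hit_keys <- unique(gkey_nounit[matched_gold])
    repeated_miss <- !matched_gold & gkey_nounit %in% hit_keys
  }
  concepts <- sort(unique(c(predicted$concept_id, gold$concept_id)))
  metrics <- function(tp, fp, fn, fn_coll) {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    rec_c <- if (tp + fn_coll > 0) tp / (tp + fn_coll) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(tp = tp, fp = fp, fn = fn, precision = prec,
               recall = if (collapse_repeated) rec_c else rec,
               f1 = f1, recall_collapsed = rec_c)
  }
  per <- do.call(rbind, lapply(concepts, function(cc) {
    p <- predicted$concept_id == cc
    g <- gold$concept_id == cc
    tp <- sum(matched_pred & p)
    fp <- sum(!matched_pred & p)
    fn <- sum(!matched_gold & g)
    fn_coll <- sum(!matched_gold & !repeated_miss & g)
    cbind(data.frame(concept_id = cc), metrics(tp, fp, fn, fn_coll))
  })) %||% cbind(empty_df(concept_id = "character"),
                 metrics(0, 0, 0, 0)[0, ])
  overall <- metrics(sum(matched_pred), sum(!matched_pred),
                     sum(!matched_gold), sum(!matched_gold & !repeated_miss))
  out <- list(overall = overall, per_concept = per,
              collapse_repeated = collapse_repeated)
  class(out) <- "echo_eval"
  out
}

#' @export
print.echo_eval <- function(x, ...) {
  cat("<echo_eval>  tp =", x$overall$tp, " fp =", x$overall$fp,
      " fn =", x$overall$fn, "\n")
  cat(sprintf("  precision = %.3f  recall = %.3f  f1 = %.3f  (collapsed recall = %.3f)\n",
              x$overall$precision, x$overall$recall, x$overall$f1,
              x$overall$recall_collapsed))
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' Per-concept rows (concept, mentions, precision, recall, collapsed
#' recall) followed by an overall row.
#'
#' @param eval an `echo_eval` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  per <- eval$per_concept
  per$mentions <- per$tp + per$fp
  all_row <- cbind(data.frame(concept_id = "OVERALL"), eval$overall)
  all_row$mentions <- all_row$tp + all_row$fp
  out <- rbind(per, all_row)
  out <- out[, c("concept_id", "mentions", "tp", "fp", "fn", "precision",
                 "recall", "f1", "recall_collapsed")]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
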