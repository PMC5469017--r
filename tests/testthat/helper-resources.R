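# Shared fixtures: shipped resources are loaded once per test run; small
# dictionaries and corpora are built in code.

shipped <- local({
  res <- NULL
  function() {
    if (is.null(res)) res <<- load_resources()
    res
  }
})

# Minimal two-entry dictionary used by the mapping worked example.
two_entry_dictionary <- function() {
  data.frame(
    surface = c("left ventricular dimension at end diastole",
                "left atrium diameter"),
    concept_id = c("left_ventricular_dimension_end_diastole",
                   "left_atrium_size_end_systole"),
    stringsAsFactors = FALSE
  )
}

# Write a temporary resource file with the given lines; returns its path.
tmp_resource <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Independent brute-force oracle for token-overlap scoring: explicit loops
# over (concept, surface, token) with no set operations beyond membership.
oracle_token_scores <- function(surface, entries, stop_tokens = STOP_TOKENS) {
  qtok <- unique(strsplit(surface, " ", fixed = TRUE)[[1]])
  qtok <- qtok[nzchar(qtok) & !(qtok %in% stop_tokens)]
  out <- data.frame(concept_id = character(0), score = integer(0),
                    stringsAsFactors = FALSE)
  for (cid in unique(entries$concept_id)) {
    surfs <- entries$surface[entries$concept_id == cid]
    matched <- character(0)
    for (tok in qtok) {
      for (s in surfs) {
        stoks <- strsplit(s, " ", fixed = TRUE)[[1]]
        if (tok %in% stoks && !(tok %in% matched)) {
          matched <- c(matched, tok)
        }
      }
    }
    if (length(matched) > 0) {
      out <- rbind(out, data.frame(concept_id = cid,
                                   score = length(matched),
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(-out$score, out$concept_id), , drop = FALSE]
}

# Random small dictionary over a closed vocabulary, for property tests.
random_dictionary <- function(vocab, n_concepts, n_entries) {
  cids <- paste0("concept_", seq_len(n_concepts))
  data.frame(
    surface = vapply(seq_len(n_entries), function(i) {
      paste(sample(vocab, sample(1:4, 1), replace = TRUE), collapse = " ")
    }, ""),
    concept_id = sample(cids, n_entries, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
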