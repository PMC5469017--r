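test_that("corpus round-trips through JSONL and rejects duplicate ids", {
  corpus <- data.frame(doc_id = c("d1", "d2"), source_type = c("Echo", "TIU"),
                       title = c("ECHO REPORT", ""),
                       text = c("LVEF = 40%", "line one\nline two"),
                       stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_identical(back, corpus)

  dup <- corpus; dup$doc_id <- c("d1", "d1")
  path2 <- tempfile(fileext = ".jsonl")
  write_corpus(dup, path2)
  expect_error(read_corpus(path2), "duplicate doc_id")
})

test_that("title filter keeps echo/card titles and drops empty titles", {
  corpus <- data.frame(
    doc_id = c("a", "b", "c", "d"),
    source_type = "TIU",
    title = c("ECHOCARDIOGRAM REPORT", "PODIATRY NOTE",
              "CARDIOLOGY CONSULT", ""),
    text = "x", stringsAsFactors = FALSE)
  kept <- filter_corpus_by_title(corpus)
  expect_equal(kept$doc_id, c("a", "c"))
  expect_equal(nrow(filter_corpus_by_title(corpus, "podiatry")), 1)
})

test_that("concept-count filter uses mapped mentions with a threshold", {
  res <- shipped()
  many <- paste(rep(c("LVEF = 55%", "LVEDD: 48mm", "PASP = 30 mmHg"), 4),
                collapse = "\n")
  corpus <- data.frame(doc_id = c("rich", "poor"), source_type = "TIU",
                       title = "", text = c(many, "no measurements here"),
                       stringsAsFactors = FALSE)
  kept <- filter_docs_by_concept_count(corpus, res, min_count = 10)
  expect_equal(kept$doc_id, "rich")
  expect_equal(filter_docs_by_concept_count(corpus, res, min_count = 0),
               corpus)
})

test_that("semantic bootstrapping harvests unknown concept-slot strings", {
  res <- shipped()
  text1 <- paste(rep("LV EJ FRACTION: 55%", 5), collapse = "\n")
  corpus <- data.frame(doc_id = "d1", source_type = "Echo", title = "",
                       text = text1, stringsAsFactors = FALSE)
  cands <- harvest_term_candidates(corpus, res)
  expect_equal(cands$candidate, "lv ej fraction")
  expect_equal(cands$frequency, 5L)

  prose <- data.frame(doc_id = "d2", source_type = "TIU", title = "",
                      text = "The patient walked in without assistance.",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(harvest_term_candidates(prose, res)), 0)

  known <- data.frame(doc_id = "d3", source_type = "Echo", title = "",
                      text = "LVEF: 55%", stringsAsFactors = FALSE)
  expect_equal(nrow(harvest_term_candidates(known, res)), 0)

  # frequencies sum to the number of matching lines
  mixed <- data.frame(doc_id = "d4", source_type = "Echo", title = "",
                      text = paste("AO ROOT = 32mm", "AO ROOT = 31mm",
                                   "RVSP: 28 mmHg", "LVEF: 60%",
                                   "narrative sentence without numbers",
                                   sep = "\n"),
                      stringsAsFactors = FALSE)
  cands4 <- harvest_term_candidates(mixed, res)
  expect_equal(sum(cands4$frequency), 3L)
  expect_equal(cands4$candidate[1], "ao root")
})

test_that("curated candidates merge back into the dictionary", {
  res <- shipped()
  cands <- data.frame(candidate = c("ao root", "junk line"),
                      frequency = c(5L, 2L), contexts = "",
                      decision = c("left_ventricular_ejection_fraction", ""),
                      stringsAsFactors = FALSE)
  merged <- merge_candidates(cands, res$dictionary, res$concepts)
  expect_equal(nrow(merged), nrow(res$dictionary) + 1)
  expect_true("ao root" %in% merged$surface)
  cands$decision[2] <- "not_a_concept"
  expect_error(merge_candidates(cands, res$dictionary, res$concepts),
               "unknown concept_id")
})

test_that("evaluation counts tp/fp/fn with the degenerate-zero convention", {
  pairs <- data.frame(
    doc_id = "d1",
    concept_id = c("left_ventricular_ejection_fraction",
                   "right_atrial_pressure"),
    value_kind = "QUANT", value_low = c(55, 10), value_high = c(55, 10),
    unit_id = c("percent", "mmhg"), stringsAsFactors = FALSE)
  ev <- evaluate_extractions(pairs, pairs)
  expect_equal(ev$overall$precision, 1)
  expect_equal(ev$overall$recall, 1)
  expect_equal(ev$overall$f1, 1)

  empty <- pairs[0, ]
  ev0 <- evaluate_extractions(empty, empty)
  expect_equal(unlist(ev0$overall[c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))

  # a wrong value is both a false positive and a false negative
  wrong <- pairs; wrong$value_low[2] <- 11; wrong$value_high[2] <- 11
  ev1 <- evaluate_extractions(wrong, pairs)
  expect_equal(ev1$overall$tp, 1)
  expect_equal(ev1$overall$fp, 1)
  expect_equal(ev1$overall$fn, 1)

  # gold without a unit matches any predicted unit; gold with a unit must agree
  gold_nounit <- pairs; gold_nounit$unit_id <- NA_character_
  expect_equal(evaluate_extractions(pairs, gold_nounit)$overall$recall, 1)
  pred_wrongunit <- pairs; pred_wrongunit$unit_id[1] <- "mm"
  expect_equal(evaluate_extractions(pred_wrongunit, pairs)$overall$tp, 1)
})

test_that("repeated-mention collapse lifts recall without touching precision", {
  gold <- data.frame(
    doc_id = "d1", concept_id = "left_ventricular_ejection_fraction",
    value_kind = "QUANT", value_low = 55, value_high = 55,
    unit_id = "percent", stringsAsFactors = FALSE)
  gold <- rbind(gold, gold)
  pred <- gold[1, ]
  ev <- evaluate_extractions(pred, gold)
  expect_equal(ev$overall$recall, 0.5)
  expect_equal(ev$overall$recall_collapsed, 1)
  expect_equal(ev$overall$precision, 1)
  ev_c <- evaluate_extractions(pred, gold, collapse_repeated = TRUE)
  expect_equal(ev_c$overall$recall, 1)

  # the same miss in a different document does not collapse
  gold2 <- gold; gold2$doc_id <- c("d1", "d2")
  expect_error(evaluate_extractions(pred, gold2), NA)
  ev2 <- evaluate_extractions(pred, gold2)
  expect_equal(ev2$overall$recall_collapsed, 0.5)
})

test_that("evaluation is invariant to document order and sums per concept", {
  res <- shipped()
  out <- generate_corpus(generator_profile(seed = 21, n_docs = 12), res)
  ex <- extract_corpus(out$corpus, res)
  ev <- evaluate_extractions(ex$pairs, out$gold)

  perm <- sample(nrow(out$gold))
  ev_perm <- evaluate_extractions(ex$pairs[sample(nrow(ex$pairs)), ],
                                  out$gold[perm, ])
  expect_equal(ev_perm$overall, ev$overall)

  expect_equal(sum(ev$per_concept$tp), ev$overall$tp)
  expect_equal(sum(ev$per_concept$fp), ev$overall$fp)
  expect_equal(sum(ev$per_concept$fn), ev$overall$fn)

  # doc_id mismatch is an evaluation error
  bad <- ex$pairs[1, , drop = FALSE]
  bad$doc_id <- "not-in-gold"
  expect_error(evaluate_extractions(bad, out$gold), "doc_id")
})
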