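test_that("pattern config loads 38 validated rules", {
  res <- shipped()
  expect_equal(nrow(res$patterns), 38)
  expect_false(anyDuplicated(res$patterns$rule_id) > 0)
  expect_equal(res$patterns$priority, sort(res$patterns$priority))

  expect_warning(p0 <- load_patterns(tmp_resource(character(0),
                                                  ext = ".cfg")), "empty")
  expect_equal(nrow(p0), 0)

  expect_error(load_patterns(tmp_resource(c(
    "r1,1,TERM SEP VALUE,equals,\\s*=\\s*,QUANT,FALSE,attached,40,LINE",
    "r1,2,TERM SEP VALUE,colon,\\s*:\\s*,QUANT,FALSE,attached,40,LINE"),
    ext = ".cfg")), "duplicate rule_id")

  expect_error(load_patterns(tmp_resource(
    "r2,1,TERM SEP TERM VALUE,equals,\\s*=\\s*,QUANT,FALSE,attached,40,LINE",
    ext = ".cfg")), "exactly one TERM")
})

test_that("semi-structured and narrative worked examples extract correctly", {
  res <- shipped()
  cases <- list(
    list(text = "LVEF = 40%",
         concept = "left_ventricular_ejection_fraction",
         low = 40, high = 40, unit = "percent"),
    list(text = "LVEDD: 16mm",
         concept = "left_ventricular_dimension_end_diastole",
         low = 16, high = 16, unit = "mm"),
    list(text = "Ejection fraction was 40%",
         concept = "left_ventricular_ejection_fraction",
         low = 40, high = 40, unit = "percent"),
    list(text = paste("The ejection fraction was visually estimated in a",
                      "range of 50 to 55%"),
         concept = "left_ventricular_ejection_fraction",
         low = 50, high = 55, unit = "percent")
  )
  for (cs in cases) {
    p <- extract_document(cs$text, res)
    expect_equal(nrow(p), 1, info = cs$text)
    expect_equal(p$concept_id, cs$concept, info = cs$text)
    expect_equal(c(p$value_low, p$value_high), c(cs$low, cs$high),
                 info = cs$text)
    expect_equal(p$unit_id, cs$unit, info = cs$text)
    expect_equal(p$value_kind, "QUANT")
  }
})

test_that("qualitative values link in all three positions", {
  res <- shipped()
  mild_rank <- res$qualitative$grade_rank[res$qualitative$surface == "mild"]
  for (text in c("mild aortic stenosis",
                 "aortic stenosis was mild",
                 "aortic valve has mild stenosis")) {
    p <- extract_document(text, res)
    expect_equal(nrow(p), 1, info = text)
    expect_equal(p$concept_id, "aortic_valve_stenosis", info = text)
    expect_equal(p$value_kind, "QUAL")
    expect_equal(p$value_low, mild_rank)
  }
})

test_that("mentions pair at most once, with no cross-term links", {
  res <- shipped()
  p <- extract_document("LVEF = 40% LVEDD: 16mm", res)
  expect_equal(nrow(p), 2)
  expect_setequal(p$concept_id,
                  c("left_ventricular_ejection_fraction",
                    "left_ventricular_dimension_end_diastole"))
  expect_equal(p$value_low[p$concept_id ==
                             "left_ventricular_ejection_fraction"], 40)
  expect_equal(p$value_low[p$concept_id ==
                             "left_ventricular_dimension_end_diastole"], 16)

  # one value cannot serve two terms
  p2 <- extract_document("LVEF ejection fraction = 40%", res)
  expect_lte(nrow(p2), 1)
})

test_that("linking does not cross line or sentence boundaries", {
  res <- shipped()
  # value on the next line never links to the previous line's term
  p <- extract_document("LVEF =\n40%", res)
  expect_equal(nrow(p), 0)
  # narrative separator across a sentence boundary does not link
  p2 <- extract_document("Ejection fraction was normal. Weight was 80", res)
  expect_false(any(p2$value_low == 80 &
                     p2$concept_id == "left_ventricular_ejection_fraction"))
})

test_that("value kind must be compatible with the concept", {
  res <- shipped()
  # aortic stenosis is qualitative-only: a number must not pair with it
  p <- extract_document("aortic stenosis = 40", res)
  expect_equal(nrow(p), 0)
})

test_that("unit-concept mismatch is flagged by default and droppable", {
  res <- shipped()
  p <- extract_document("AV area = 2 cm", res)
  expect_equal(nrow(p), 1)
  expect_equal(p$concept_id, "aortic_valve_orifice_area")
  expect_false(p$unit_ok)

  res_drop <- load_resources(unit_mismatch = "drop")
  p2 <- extract_document("AV area = 2 cm", res_drop)
  expect_equal(nrow(p2), 0)
  # a compatible unit is not dropped
  p3 <- extract_document("AV area = 2 cm2", res_drop)
  expect_equal(nrow(p3), 1)
  expect_true(p3$unit_ok)
})

test_that("extraction is deterministic and invariant to rule file row order", {
  res <- shipped()
  text <- paste("MEASUREMENTS:", "LVEF = 55-60%", "LVEDD: 48 mm",
                "The mitral regurgitation was moderate.",
                "There is mild tricuspid regurgitation.", sep = "\n")
  p1 <- extract_document(text, res)
  p2 <- extract_document(text, res)
  expect_identical(p1, p2)

  # shuffle the pattern rows; priority ordering restores determinism
  res_shuf <- res
  set.seed(4)
  res_shuf$patterns <- res$patterns[sample(nrow(res$patterns)), ]
  res_shuf$patterns <- res_shuf$patterns[order(res_shuf$patterns$priority), ]
  p3 <- extract_document(text, res_shuf)
  expect_identical(p1, p3)
  expect_equal(nrow(p1), 4)
})

test_that("empty documents and documents without pairs yield empty output", {
  res <- shipped()
  expect_equal(nrow(extract_document("", res)), 0)
  expect_equal(nrow(extract_document("Patient resting comfortably.", res)), 0)
})

test_that("a generated measurement block extracts exactly its gold pairs", {
  res <- shipped()
  rep <- generate_report(generator_profile(seed = 3, n_docs = 1,
                                           format_mix = c(
                                             semi_structured = 1,
                                             narrative = 0, mixed = 0),
                                           concepts_per_doc = c(3, 3)),
                         1, res)
  p <- extract_document(rep$doc$text, res, doc_id = rep$doc$doc_id)
  expect_equal(nrow(p), 3)
  ev <- evaluate_extractions(p, rep$gold)
  expect_equal(ev$overall$precision, 1)
  expect_equal(ev$overall$recall, 1)
})

test_that("corpus extraction records per-document errors and continues", {
  res <- shipped()
  corpus <- data.frame(doc_id = c("a", "b"), source_type = "plain",
                       title = "", text = c("LVEF = 40%", NA),
                       stringsAsFactors = FALSE)
  out <- extract_corpus(corpus, res)
  expect_equal(nrow(out$pairs), 1)
  expect_equal(out$errors$doc_id, "b")
})
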