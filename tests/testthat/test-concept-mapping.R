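test_that("exact match is a plain dictionary lookup", {
  d <- two_entry_dictionary()
  expect_equal(exact_match("left atrium diameter", d),
               "left_atrium_size_end_systole")
  expect_true(is.na(exact_match("left ventricular diastolic dimension", d)))
  expect_true(is.na(exact_match("", d)))
})

test_that("token overlap reproduces the 3-vs-1 worked example", {
  s <- token_overlap_scores("left ventricular diastolic dimension",
                            two_entry_dictionary())
  expect_equal(s$concept_id, c("left_ventricular_dimension_end_diastole",
                               "left_atrium_size_end_systole"))
  expect_equal(s$score, c(3L, 1L))
  # a query equal to a surface scores that surface's content-token count
  self <- token_overlap_scores("left atrium diameter",
                               two_entry_dictionary())
  expect_equal(self$score[self$concept_id == "left_atrium_size_end_systole"],
               3L)
})

test_that("token overlap scorer agrees with the brute-force oracle", {
  vocab <- c("left", "right", "ventricular", "atrium", "dimension",
             "pressure", "velocity", "area", "end", "diastole", "of", "the")
  set.seed(202)
  for (i in seq_len(1000)) {
    entries <- random_dictionary(vocab, n_concepts = sample(2:5, 1),
                                 n_entries = sample(2:8, 1))
    query <- paste(sample(vocab, sample(1:5, 1), replace = TRUE),
                   collapse = " ")
    got <- token_overlap_scores(query, entries)
    want <- oracle_token_scores(query, entries)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("semantic constraints discard mutually exclusive candidates", {
  res <- shipped()
  scored <- data.frame(
    concept_id = c("left_ventricular_dimension_end_diastole",
                   "mitral_valve_regurgitation",
                   "tricuspid_valve_regurgitation",
                   "left_atrium_size_end_systole"),
    score = c(3L, 2L, 2L, 1L), stringsAsFactors = FALSE)
  out <- apply_semantic_constraints("left atrial dimension", scored,
                                    res$words, res$constraints,
                                    res$concepts)
  expect_equal(out$concept_id, "left_atrium_size_end_systole")
  expect_equal(out$score, 1L)

  # "volume" excludes dimension/velocity/pressure-tagged concepts
  scored2 <- data.frame(
    concept_id = c("left_ventricular_dimension_end_diastole",
                   "tricuspid_valve_regurgitation_peak_velocity",
                   "right_atrial_pressure"),
    score = c(2L, 2L, 2L), stringsAsFactors = FALSE)
  out2 <- apply_semantic_constraints("left ventricular volume", scored2,
                                     res$words, res$constraints,
                                     res$concepts)
  expect_equal(nrow(out2), 0)

  # no lexicon words in the surface: candidates unchanged
  out3 <- apply_semantic_constraints("zzz qqq", scored, res$words,
                                     res$constraints, res$concepts)
  expect_identical(out3, scored)
})

test_that("constraint filtering is a monotone filter", {
  res <- shipped()
  set.seed(77)
  surfaces <- c(res$dictionary$surface,
                "atrial volume index", "ventricular pressure volume")
  for (i in seq_len(200)) {
    n <- sample(1:6, 1)
    scored <- data.frame(
      concept_id = sample(res$concepts$concept_id, n),
      score = sample(1:5, n, replace = TRUE), stringsAsFactors = FALSE)
    surface <- sample(surfaces, 1)
    out <- apply_semantic_constraints(surface, scored, res$words,
                                      res$constraints, res$concepts)
    expect_lte(nrow(out), nrow(scored))
    if (nrow(out) > 0) {
      m <- match(out$concept_id, scored$concept_id)
      expect_false(anyNA(m))
      expect_equal(out$score, scored$score[m])
    }
  }
})

test_that("map_surface implements the two-step lookup with tie discard", {
  res <- shipped()
  res$dictionary <- two_entry_dictionary()
  m <- map_surface("left ventricular diastolic dimension", res)
  expect_equal(m$status, "MAPPED")
  expect_equal(m$concept_id, "left_ventricular_dimension_end_diastole")

  expect_equal(map_surface("no such words here", res)$status, "UNMAPPED")

  # two concepts tied at the same score are AMBIGUOUS
  res$dictionary <- data.frame(
    surface = c("aortic valve mean gradient", "mitral valve mean gradient"),
    concept_id = c("aortic_valve_mean_pressure_gradient",
                   "mitral_valve_mean_pressure_gradient"),
    stringsAsFactors = FALSE)
  tie <- map_surface("valve mean gradient", res)
  expect_equal(tie$status, "AMBIGUOUS")
  expect_true(is.na(tie$concept_id))
})

test_that("an exact match vetoed by constraints falls through to scoring", {
  res <- shipped()
  # fabricate a dictionary where the exact surface maps to a concept whose
  # tags contradict a word in the surface
  res$dictionary <- data.frame(
    surface = c("atrial dimension", "left atrial dimension"),
    concept_id = c("left_ventricular_dimension_end_diastole",
                   "left_atrium_size_end_systole"),
    stringsAsFactors = FALSE)
  m <- map_surface("atrial dimension", res)
  # exact target (a ventricle-tagged concept) is excluded by "atrial";
  # partial matching then resolves to the atrium concept
  expect_equal(m$status, "MAPPED")
  expect_equal(m$concept_id, "left_atrium_size_end_systole")
})

test_that("mapping agrees with exact lookup across the shipped dictionary", {
  res <- shipped()
  for (i in seq_len(nrow(res$dictionary))) {
    m <- map_surface(res$dictionary$surface[i], res)
    expect_equal(m$status, "MAPPED")
    expect_equal(m$concept_id, res$dictionary$concept_id[i])
  }
})
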