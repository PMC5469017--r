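# Synthetic echocardiogram-style documents with exact gold annotations.
# The generator emulates the three report formats the extractor targets:
# semi-structured measurement blocks (one "TERM = value unit" statement per
# line), narrative sentences (verb-phrase and qualitative positions), and
# mixed documents that restate a measurement in both sections (repeated
# mentions).

# Relative sampling weight per concept; left ventricular ejection fraction
# dominates, mirroring the skew of real report corpora.
CONCEPT_WEIGHTS <- c(
  left_ventricular_ejection_fraction = 30,
  left_atrium_size_end_systole = 11,
  mitral_valve_regurgitation = 9,
  tricuspid_valve_regurgitation = 8,
  left_ventricular_posterior_wall_thickness_end_diastole = 6,
  interventricular_septum_dimension_end_diastole = 6,
  aortic_valve_regurgitation = 5,
  left_ventricular_hypertrophy = 5,
  left_ventricular_size = 5,
  left_ventricular_dimension_end_diastole = 5,
  left_ventricular_dimension_end_systole = 3,
  pulmonary_artery_pressure = 3,
  right_atrial_pressure = 2,
  aortic_valve_stenosis = 2,
  aortic_valve_orifice_area = 1.5,
  tricuspid_valve_regurgitation_peak_velocity = 1.5,
  aortic_valve_max_pressure_gradient = 1,
  aortic_valve_mean_pressure_gradient = 1,
  mitral_valve_stenosis = 1,
  e_e_prime_ratio = 1,
  mitral_valve_mean_pressure_gradient = 0.8,
  mitral_valve_orifice_area = 0.8,
  mitral_valve_regurgitation_peak_velocity = 0.6,
  tricuspid_valve_mean_pressure_gradient = 0.6,
  left_ventricular_contractility = 0.6,
  aortic_valve_regurgitation_peak_velocity = 0.2,
  tricuspid_valve_orifice_area = 0.2
)

# Printed surface for each unit id.
UNIT_PRINT <- c(percent = "%", mm = "mm", cm = "cm", cm2 = "cm2",
                m_s = "m/s", cm_s = "cm/s", mmhg = "mmHg")

#' Create a synthetic-corpus generator profile
#'
#' The profile fixes every stochastic aspect of generation so that a
#' (seed, doc_index) pair always yields a byte-identical document.
#'
#' @param seed integer seed for the generator.
#' @param n_docs number of documents to generate.
#' @param format_mix named proportions over `semi_structured`, `narrative`,
#'   `mixed` document formats (must sum to 1).
#' @param concepts_per_doc integer range (min, max) of distinct measurement
#'   concepts stated per document.
#' @param variant_noise probability that a non-canonical dictionary variant
#'   is used instead of the concept's canonical surface.
#' @param misspelling_noise probability of a single-character perturbation
#'   (substitution or deletion) inside a term; numbers are never perturbed.
#' @param distractor_rate expected number of non-target lines (demographics,
#'   impressions, vitals) per target statement.
#' @param range_rate probability that a quantitative value is a range.
#' @param repeat_rate probability that a mixed-format document restates one
#'   of its measurements in both sections (the second statement is marked
#'   `is_repeated` in the gold annotations).
#' @return object of class `generator_profile`.
#' @export
generator_profile <- function(seed = 1L, n_docs = 100L,
                              format_mix = c(semi_structured = 0.4,
                                             narrative = 0.3, mixed = 0.3),
                              concepts_per_doc = c(3L, 8L),
                              variant_noise = 0.3,
                              misspelling_noise = 0,
                              distractor_rate = 0.3,
                              range_rate = 0.2,
                              repeat_rate = 0.6) {
  stopifnot(length(format_mix) == 3,
            all(c("semi_structured", "narrative", "mixed") %in%
                  names(format_mix)))
  if (abs(sum(format_mix) - 1) > 1e-8) {
    stop("format_mix proportions must sum to 1", call. = FALSE)
  }
  probs <- c(variant_noise, misspelling_noise, distractor_rate / 10,
             range_rate, repeat_rate)
  if (any(probs < 0) || any(c(variant_noise, misspelling_noise, range_rate,
                              repeat_rate) > 1)) {
    stop("noise parameters must be probabilities in [0, 1]", call. = FALSE)
  }
  stopifnot(length(concepts_per_doc) == 2,
            concepts_per_doc[1] >= 1,
            concepts_per_doc[1] <= concepts_per_doc[2])
  out <- list(seed = as.integer(seed), n_docs = as.integer(n_docs),
              format_mix = format_mix[c("semi_structured", "narrative",
                                        "mixed")],
              concepts_per_doc = as.integer(concepts_per_doc),
              variant_noise = variant_noise,
              misspelling_noise = misspelling_noise,
              distractor_rate = distractor_rate,
              range_rate = range_rate,
              repeat_rate = repeat_rate)
  class(out) <- "generator_profile"
  out
}

# Run `expr` under a derived deterministic seed, restoring the caller's RNG
# state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-document seed below 2^31.
doc_seed <- function(seed, doc_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(doc_index) * 16807) %%
               2147483647)
}

# Per-concept generator metadata derived from the resources.
concept_meta <- function(resources) {
  conc <- resources$concepts
  meta <- lapply(seq_len(nrow(conc)), function(i) {
    surfs <- resources$dictionary$surface[
      resources$dictionary$concept_id == conc$concept_id[i]]
    list(concept_id = conc$concept_id[i],
         value_kind = conc$value_kind[i],
         units = conc$units[[i]],
         canonical = surfs[which.max(nchar(surfs))],
         variants = surfs)
  })
  names(meta) <- conc$concept_id
  meta
}

# Plausible quantitative value by unit dimension (generator metadata only;
# extraction never constrains values).
sample_quant <- function(unit_id) {
  if (is.na(unit_id)) return(sample(4:20, 1))
  switch(unit_id,
         percent = 5 * sample(2:16, 1),
         mm = sample(25:70, 1),
         cm = round(stats::runif(1, 2, 6.9), 1),
         cm2 = round(stats::runif(1, 0.6, 4), 1),
         m_s = round(stats::runif(1, 0.5, 4.5), 1),
         cm_s = round(stats::runif(1, 50, 450)),
         mmhg = sample(5:70, 1),
         sample(4:20, 1))
}

format_quant <- function(x, unit_id) {
  if (!is.na(unit_id) && unit_id %in% c("cm", "cm2", "m_s")) {
    format(round(x, 1), nsmall = 1, trim = TRUE)
  } else {
    format(x, trim = TRUE, scientific = FALSE)
  }
}

# Single-character perturbation of a term: substitution or deletion of one
# alphabetic character. All random draws happen unconditionally so that the
# RNG stream is identical across misspelling_noise levels (higher noise
# perturbs a superset of the terms perturbed at lower noise).
maybe_misspell <- function(term, p) {
  u <- stats::runif(1)
  alpha <- which(grepl("[a-z]", strsplit(term, "")[[1]], ignore.case = TRUE))
  pos_draw <- stats::runif(1)
  sub_draw <- stats::runif(1)
  letter_draw <- stats::runif(1)
  if (u >= p || length(alpha) == 0) return(term)
  pos <- alpha[ceiling(pos_draw * length(alpha))]
  chars <- strsplit(term, "")[[1]]
  if (sub_draw < 0.5) {
    chars[pos] <- letters[ceiling(letter_draw * 26)]
  } else {
    chars <- chars[-pos]
  }
  paste(chars, collapse = "")
}

DISTRACTOR_LINES <- c(
  "Patient Name: REDACTED",
  "Study date: 03/14/2019",
  "BP: 120/80",
  "Heart rate: 72 bpm",
  "Normal sinus rhythm.",
  "The patient tolerated the procedure well.",
  "IMPRESSION:",
  "Referring provider notified of the findings.",
  "Technically limited study due to body habitus."
)

# One measurement statement. Returns list(line = text, gold = one-row df).
# `fmt` is "semi" or one of the narrative templates chosen internally.
render_statement <- function(meta_c, profile, resources, semi) {
  qual <- resources$qualitative
  use_variant <- stats::runif(1) < profile$variant_noise
  term <- if (use_variant && length(meta_c$variants) > 1) {
    sample(meta_c$variants, 1)
  } else {
    meta_c$canonical
  }
  term <- maybe_misspell(term, profile$misspelling_noise)
  kind <- meta_c$value_kind
  if (kind == "BOTH") kind <- if (stats::runif(1) < 0.85) "QUANTITATIVE"
    else "QUALITATIVE"

  if (kind == "QUANTITATIVE") {
    unit_id <- if (length(meta_c$units) > 0) sample(meta_c$units, 1)
      else NA_character_
    is_range <- stats::runif(1) < profile$range_rate
    v1 <- sample_quant(unit_id)
    v2 <- sample_quant(unit_id)
    lo <- min(v1, v2); hi <- max(v1, v2)
    if (is_range && lo == hi) is_range <- FALSE
    if (!is_range) { lo <- v1; hi <- v1 }
    usurf <- if (is.na(unit_id)) "" else UNIT_PRINT[[unit_id]]
    ugap <- if (nzchar(usurf) && stats::runif(1) < 0.4) " " else ""
    vtxt <- if (is_range) {
      conn <- if (semi) "-" else sample(c("-", " to "), 1)
      paste0(format_quant(lo, unit_id), conn, format_quant(hi, unit_id))
    } else {
      format_quant(lo, unit_id)
    }
    vtxt_unit <- paste0(vtxt, ugap, usurf)
    if (semi) {
      sep <- sample(c(" = ", ": ", " : ", "="), 1)
      shown <- if (stats::runif(1) < 0.5) toupper(term) else term
      line <- paste0(shown, sep, vtxt_unit)
      term_start <- 1L
    } else {
      tmpl <- sample(c("The %s was %s.", "%s is %s.",
                       "The %s was measured at %s.",
                       "The %s was visually estimated in a range of %s."), 1)
      if (grepl("range of", tmpl) && !is_range) {
        tmpl <- "The %s was %s."
      }
      if (grepl("range of", tmpl)) {
        vtxt_unit <- paste0(format_quant(lo, unit_id), " to ",
                            format_quant(hi, unit_id), ugap, usurf)
      }
      line <- sprintf(tmpl, term, vtxt_unit)
      term_start <- as.integer(regexpr(term, line, fixed = TRUE))
    }
    gold <- data.frame(
      concept_id = meta_c$concept_id, value_kind = "QUANT",
      value_low = lo, value_high = hi,
      unit_id = if (nzchar(usurf)) unit_id else NA_character_,
      is_range = is_range,
      term_start = term_start, term_end = term_start + nchar(term) - 1L,
      stringsAsFactors = FALSE
    )
  } else {
    is_range <- stats::runif(1) < profile$range_rate
    # sample grade surfaces usable in ranges (single-word ordering clarity)
    g1 <- sample(qual$surface, 1)
    g2 <- sample(qual$surface, 1)
    r1 <- qual$grade_rank[match(g1, qual$surface)]
    r2 <- qual$grade_rank[match(g2, qual$surface)]
    if (is_range && r1 == r2) is_range <- FALSE
    if (is_range && r1 > r2) { tmp <- g1; g1 <- g2; g2 <- tmp
                               tmp <- r1; r1 <- r2; r2 <- tmp }
    gtxt <- if (is_range) paste0(g1, " to ", g2) else g1
    lo <- r1; hi <- if (is_range) r2 else r1
    if (semi) {
      sep <- sample(c(" = ", ": "), 1)
      shown <- if (stats::runif(1) < 0.5) toupper(term) else term
      line <- paste0(shown, sep, gtxt)
      term_start <- 1L
    } else {
      tmpl <- sample(c("The %s was %s.", "There is %2$s %1$s."), 1)
      line <- sprintf(tmpl, term, gtxt)
      term_start <- as.integer(regexpr(term, line, fixed = TRUE))
    }
    gold <- data.frame(
      concept_id = meta_c$concept_id, value_kind = "QUAL",
      value_low = lo, value_high = hi, unit_id = NA_character_,
      is_range = is_range,
      term_start = term_start, term_end = term_start + nchar(term) - 1L,
      stringsAsFactors = FALSE
    )
  }
  list(line = line, gold = gold)
}

#' Generate one synthetic report with gold annotations
#'
#' Deterministic for a fixed (profile seed, `doc_index`). Semi-structured
#' sections state one measurement per line ("LVEF = 55%"); narrative
#' sections use verb-phrase and qualitative-position sentence templates.
#' Every emitted statement has a gold record; with zero misspelling noise
#' every term is a dictionary surface.
#'
#' @param profile a [generator_profile()].
#' @param doc_index 1-based document index.
#' @param resources an `echo_resources` object.
#' @return list with `doc` (one-row corpus data.frame) and `gold`
#'   (data.frame of gold annotations with document-level spans).
#' @export
generate_report <- function(profile, doc_index,
                            resources = load_resources()) {
  with_local_seed(doc_seed(profile$seed, doc_index), {
    meta <- concept_meta(resources)
    fmt <- sample(names(profile$format_mix), 1, prob = profile$format_mix)
    rng <- profile$concepts_per_doc
    n_concepts <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    w <- CONCEPT_WEIGHTS[names(meta)]
    w[is.na(w)] <- 1
    chosen <- sample(names(meta), min(n_concepts, length(meta)), prob = w)

    semi_flag <- switch(fmt,
                        semi_structured = rep(TRUE, length(chosen)),
                        narrative = rep(FALSE, length(chosen)),
                        mixed = stats::runif(length(chosen)) < 0.5)
    statements <- lapply(seq_along(chosen), function(i) {
      st <- render_statement(meta[[chosen[i]]], profile, resources,
                             semi = semi_flag[i])
      st$gold$is_repeated <- FALSE
      st
    })
    # repeated mention: restate one statement in the other format
    if (fmt == "mixed" && stats::runif(1) < profile$repeat_rate &&
        length(statements) > 0) {
      k <- sample(seq_along(statements), 1)
      g <- statements[[k]]$gold
      meta_k <- meta[[g$concept_id]]
      vtxt <- if (g$value_kind == "QUANT") {
        u <- g$unit_id
        base <- if (g$is_range) paste0(format_quant(g$value_low, u), " to ",
                                       format_quant(g$value_high, u))
          else format_quant(g$value_low, u)
        paste0(base, if (!is.na(u)) UNIT_PRINT[[u]] else "")
      } else {
        qual <- resources$qualitative
        lo_s <- qual$surface[match(g$value_low, qual$grade_rank)]
        hi_s <- qual$surface[match(g$value_high, qual$grade_rank)]
        if (g$is_range) paste0(lo_s, " to ", hi_s) else lo_s
      }
      if (semi_flag[k]) {
        line <- sprintf("The %s was %s.", meta_k$canonical, vtxt)
        term_start <- as.integer(regexpr(meta_k$canonical, line,
                                         fixed = TRUE))
        term_len <- nchar(meta_k$canonical)
      } else {
        line <- paste0(toupper(meta_k$canonical), " = ", vtxt)
        term_start <- 1L
        term_len <- nchar(meta_k$canonical)
      }
      g2 <- g
      g2$term_start <- term_start
      g2$term_end <- term_start + term_len - 1L
      g2$is_repeated <- TRUE
      statements[[length(statements) + 1L]] <-
        list(line = line, gold = g2)
      semi_flag <- c(semi_flag, !semi_flag[k])
    }

    # assemble: header, semi block, narrative block, with distractors
    semi_lines <- statements[semi_flag]
    narr_lines <- statements[!semi_flag]
    lines <- character(0)
    gold <- list()
    add_line <- function(txt, st = NULL) {
      lines <<- c(lines, txt)
      if (!is.null(st)) {
        offset <- sum(nchar(lines[-length(lines)]) + 1L)
        g <- st$gold
        g$term_start <- g$term_start + offset
        g$term_end <- g$term_end + offset
        g$line <- length(lines)
        gold[[length(gold) + 1L]] <<- g
      }
    }
    n_distract <- stats::rpois(1, profile$distractor_rate *
                                 max(1, length(statements)))
    distract <- sample(DISTRACTOR_LINES, min(n_distract,
                                             length(DISTRACTOR_LINES)))
    add_line("ECHOCARDIOGRAM REPORT")
    if (length(distract) > 0) add_line(distract[1])
    if (length(semi_lines) > 0) {
      add_line("MEASUREMENTS:")
      for (st in semi_lines) add_line(st$line, st)
    }
    if (length(narr_lines) > 0) {
      add_line("INTERPRETATION:")
      for (st in narr_lines) add_line(st$line, st)
    }
    for (d in distract[-1]) add_line(d)

    text <- paste(lines, collapse = "\n")
    doc_id <- sprintf("synth-%05d", doc_index)
    gold <- do.call(rbind, gold) %||% empty_gold()
    if (nrow(gold) > 0) {
      gold <- cbind(data.frame(doc_id = doc_id, stringsAsFactors = FALSE),
                    gold)
    } else {
      gold <- empty_gold()
    }
    source_type <- switch(fmt, semi_structured = "Echo",
                          narrative = "Radiology", mixed = "TIU")
    list(doc = data.frame(doc_id = doc_id, source_type = source_type,
                          title = "ECHOCARDIOGRAM REPORT", text = text,
                          stringsAsFactors = FALSE),
         gold = gold)
  })
}

empty_gold <- function() {
  empty_df(doc_id = "character", concept_id = "character",
           value_kind = "character", value_low = "numeric",
           value_high = "numeric", unit_id = "character",
           is_range = "logical", term_start = "integer",
           term_end = "integer", is_repeated = "logical", line = "integer")
}

#' Generate a synthetic corpus with gold annotations
#'
#' @param profile a [generator_profile()].
#' @param resources an `echo_resources` object.
#' @return list with `corpus` (data.frame of documents) and `gold`
#'   (data.frame of all gold annotations).
#' @export
#' @examples
#' out <- generate_corpus(generator_profile(seed = 7, n_docs = 3))
#' nrow(out$corpus)
generate_corpus <- function(profile, resources = load_resources()) {
  docs <- list()
  golds <- list()
  for (i in seq_len(profile$n_docs)) {
    rep <- generate_report(profile, i, resources)
    docs[[i]] <- rep$doc
    golds[[i]] <- rep$gold
  }
  corpus <- do.call(rbind, docs) %||%
    empty_df(doc_id = "character", source_type = "character",
             title = "character", text = "character")
  gold <- do.call(rbind, golds) %||% empty_gold()
  rownames(corpus) <- NULL
  rownames(gold) <- NULL
  list(corpus = corpus, gold = gold)
}
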