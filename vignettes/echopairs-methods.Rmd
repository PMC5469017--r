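---
title: "Extracting measurement-value pairs from echocardiogram text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting measurement-value pairs from echocardiogram text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echopairs)
```

## The problem and the model

Echocardiogram findings reach the medical record as text: semi-structured
measurement blocks with one statement per line ("LVEF = 55%",
"LVEDD: 48 mm"), and narrative prose ("The ejection fraction was visually
estimated in a range of 50 to 55%", "mild aortic stenosis"). The language
is a *sublanguage*: a restricted clinical register in which a small
number of word-class co-occurrence patterns carry almost all of the
measurement content. `echopairs` exploits that regularity with a fully
rule-based pipeline — a curated dictionary, a word-category lexicon,
mutual-exclusion constraints, and an explicit pattern inventory — rather
than a learned model. The design trades recall for precision: a rule
either fires identically on every document or not at all, which is the
behavior wanted when extracted values feed downstream phenotyping.

A *concept* is one of 27 standardized measurement targets (ejection
fraction, chamber dimensions at end systole/diastole, septal and
posterior wall thickness, valve gradients, areas, regurgitation and
stenosis grades, pulmonary artery and right atrial pressures, the E/e′
ratio). A *term* is a surface string that can denote a concept; the
shipped dictionary maps 132 normalized surfaces to concepts, one concept
per surface. A *value* is quantitative (number, optional unit, possibly a
range) or qualitative (a severity grade from an ordered lexicon). The
output unit of the pipeline is the *measurement-value pair*: (document,
concept, value, unit, spans, rule).

## Stage 1: term recognition

Dictionary surfaces are matched case-insensitively with flexible internal
whitespace and token-boundary guards, so "ef" matches the token "EF" but
never the tail of "relief". Abbreviations with internal structure
("LVD ed", "e/e′", "e to e prime") are a separate regex list; a mention
found at the same span by both recognizers is kept once, labeled as an
abbreviation.

Because no dictionary is ever complete, a *concept builder* runs on every
document: anatomy-category and measure-category words (from a 55-word
lexicon that also carries each word's semantic group) are merged into a
candidate term whenever consecutive words are separated only by
whitespace, hyphen, slash, or connector words (*of, the, at, a, an,
and*). A built term must contain at least one anatomy and one measure
word, at most eight lexicon words (a guard against runaway merging across
clauses), and may not cross a line break — lines are the semi-structured
unit, and letting built terms wrap would trade precision for a recall
gain no template format suggests. Overlapping mentions resolve
longest-first, with ties broken by origin (dictionary phrase >
abbreviation > built) and then leftmost; the result is independent of
input order.

## Stage 2: concept mapping

Mapping is a two-step lookup. An exact dictionary match wins immediately.
Otherwise every concept is scored by *token overlap*: the number of
distinct query tokens that occur in at least one of the concept's
dictionary surfaces, with the connective stop tokens *of, the, at, a, an,
to, and* excluded (repeated tokens count once, so repetition cannot
inflate a score):

```{r}
entries <- data.frame(
  surface = c("left ventricular dimension at end diastole",
              "left atrium diameter"),
  concept_id = c("left_ventricular_dimension_end_diastole",
                 "left_atrium_size_end_systole"))
token_overlap_scores("left ventricular diastolic dimension", entries)
```

Scores alone over-map in the presence of shared words ("left",
"ventricular" appear in many concepts), so a disambiguation step applies
*semantic constraints*: unordered pairs of mutually exclusive semantic
groups. If the query surface contains a word of group *g*, every
candidate concept tagged with a group that excludes *g* is discarded —
a phrase containing "atrial" cannot map to ventricular, mitral or
tricuspid concepts; one containing "volume" cannot map to dimension,
velocity or pressure concepts. Filtering is monotone: it only removes
candidates and never alters a score. A strict maximum then maps the
term. Two design points were genuinely open and are decided as follows:

* **Ties are ambiguous.** The scoring rule says only that the higher
  score wins; when two candidates tie at the maximum the mention is
  discarded rather than guessed, consistent with the precision-first
  goal.
* **Constraints also veto exact matches.** Applying the constraints
  uniformly to both lookup steps keeps the semantics of the dictionary
  and of the builder identical; a vetoed exact match falls through to
  partial scoring, which can recover a consistent concept.

## Stage 3: value recognition

Quantitative values are integers or decimals (period decimal separator
only; the source register is US clinical text). A unit attaches when it
trails the number by at most two characters — this covers both "16mm"
and "2 cm", and decides the open case "45-50 %" in favor of attachment.
Context guards drop numbers inside date, blood-pressure-style `120/80`
and clock-time constructs. Qualitative values come from an ordered
severity lexicon (normal = 0 through severe = 5, with synonyms sharing a
rank); ordering makes qualitative ranges well-formed.

Adjacent same-kind point values separated by a range connector ("-",
"to", an en dash) merge into a single range. Merging is left-greedy and
a merged range never re-merges, so a chain like "40 - 45 - 50" has one
canonical, deterministic reading: range(40, 45) plus point(50). Endpoint
totals are conserved, and reversed endpoints are reordered so low ≤ high.
Mixed quantitative-qualitative ranges are not merged (no report format
licenses them).

## Stage 4: relationship linking

The pattern inventory is configuration data (`patterns.cfg`), not code:
38 rules, each a slot sequence with a separator class, a value-kind and
rangeness constraint, a unit mode, a maximum gap, and a scope. The
inventory crosses the dominant template `<Term> <sep> <Value> <Unit>`
with separators {"=", ":", copula verb, measurement verb phrase} × unit
{attached, detached, absent} × value {point, range} (24 rules), adds
bare-column layouts (3), parenthesized values (2), qualitative statements
with "=", ":" or a copula (6), the grade-before-term position
("mild aortic stenosis", 2), and the within-term position
("aortic valve has mild stenosis", 1). Semi-structured rules scan line
windows; narrative rules scan sentence windows delimited by ". ", ";"
or a newline — linking never crosses a line.

The engine applies rules in priority order (semi-structured before
narrative before bare-column, qualitative last). A match requires the
gap text to fully match the separator class, gap length ≤ `max_gap`
(default 40 characters; bare columns 20), and no intervening term
mention between term and value. Matched mentions are consumed, so each
mention joins at most one pair; consumption plus nearest-first candidate
ordering implements nearest-term-wins for values flanked by two terms.
The within-term rule is special-cased: the anatomy/measure words
immediately before and after a qualitative grade are concatenated and
mapped as a single surface; a small verb set (*has, with, shows*) is
tolerated between head and grade, without which the canonical example
sentence could not match. Pairs whose value kind contradicts the
concept's declared kind are never emitted; pairs whose unit is
incompatible with the concept (e.g. "AV area is 2 cm", where area wants
cm²) are emitted with `unit_ok = FALSE` by default (`warn`) because such
statements confuse human annotators too — set `unit_mismatch = "drop"`
to discard them.

## Knowledge resources and curation loop

All resources are plain UTF-8 CSV/text under
`system.file("extdata", "resources", package = "echopairs")` and can be
replaced wholesale via `load_resources(dir)`. `validate_resources()`
cross-checks them; notably, every dictionary surface must survive its own
semantic constraints and map back to its declared concept. The concept
inventory was reconstructed from the 25 concepts with observed mentions
plus the two rarely-mentioned ones (aortic valve regurgitation peak
velocity, tricuspid valve orifice area); its labels are normative for
this package only. The word-lexicon groups are deliberately coarse
(atrium, ventricle, mitral, ... plus a laterality group for left/right)
because each surface carries exactly one group and the constraints are
stated over coarse groups.

`harvest_term_candidates()` implements the bootstrapping loop that built
the dictionary in the first place: any line of the form
`<string> = <number><unit>` whose concept-slot string is not yet a
dictionary surface yields a candidate, aggregated by frequency into a
curation file; `merge_candidates()` folds accepted rows back into the
dictionary.

## The synthetic generator and what passing tests mean

Real echocardiogram corpora cannot ship with a package, so
`generate_corpus()` emulates the three report shapes the extractor
targets: semi-structured blocks (one `TERM = value unit` statement per
line), narrative sentences (verb-phrase and qualitative-position
templates), and mixed documents that restate one measurement in both
sections — the restatement is marked `is_repeated` in the gold table,
mirroring how repeated mentions inflate strict false-negative counts.
Concept frequencies are skewed so left ventricular ejection fraction
dominates (~27% of mentions). Value ranges per concept (EF 10–80%,
dimensions 25–70 mm, velocities 0.5–4.5 m/s, ...) are generator metadata
only; extraction never constrains values. Two noise knobs exist:
`variant_noise` (sample a non-canonical dictionary variant) and
`misspelling_noise` (single-character substitution/deletion inside a
term, never in numbers). Misspelling draws are made unconditionally so
the random stream is identical across noise levels: the terms perturbed
at a lower level are a subset of those perturbed at a higher one, which
is what makes recall provably non-increasing in noise at matched seeds.

The default test problem sizes — 100-document corpora for the end-to-end
checks, 1000 random dictionaries for the scorer-vs-oracle property, 3
noise levels × 40 documents for monotonicity — run the whole suite in
under a minute while leaving the properties nothing to hide behind.
Passing them shows the pipeline is *internally* exact: on text composed
of the formats the generator emits, extraction is lossless and
precision-perfect, determinism is byte-level, and the evaluator's
arithmetic is consistent. It does not show field performance: real
corpora contain split terms (multi-word terms interleaved with other
mentions), negation, hedging, templated tables with column alignment,
OCR noise and local idiosyncrasies the generator does not model, and
recall on such text will be lower.

## Numerical and degenerate-input choices

Evaluation matches pairs exactly (concept, value kind, endpoints, and
unit when the gold annotation states one) — values are transcribed, not
computed, so no tolerance is appropriate. Zero-denominator metrics are
defined as 0. Empty documents, empty dictionaries, and empty pattern
configurations yield empty outputs rather than errors; a malformed
resource line fails loudly with its line number. Per-document extraction
failures in a corpus run are recorded and skipped, never fatal.

## Known limitations

* Split terms are out of scope by design; relations involving them are
  simply not built.
* The 38-rule inventory realizes a published count and taxonomy, not a
  published rule list; the exact original rules are unavailable, so the
  shipped configuration is this package's own reconstruction and is
  curator-editable.
* Qualitative grades are compared by rank, so distinct synonyms of one
  rank ("low", "reduced") are interchangeable in evaluation.
* No negation, temporality, or unit conversion; cross-line linking is
  intentionally impossible.
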