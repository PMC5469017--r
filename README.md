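# echopairs

Rule-based extraction of cardiac structure and function measurements from
free-text echocardiogram reports and clinic notes.

Echocardiography results — ejection fraction, chamber dimensions, valve
gradients and areas, regurgitation and stenosis grades — are usually
locked inside semi-structured or narrative text ("LVEF = 55%",
"mild aortic stenosis", "The ejection fraction was visually estimated in a
range of 50 to 55%"). `echopairs` turns such text into analyzable
**measurement–value pairs**: rows of (document, concept, value, unit,
provenance spans). It is written for clinical-informatics researchers who
need heart-function phenotypes from report corpora without manual chart
review, and for anyone who wants a fully testable, dependency-light
reference implementation of dictionary + pattern measurement extraction.

## The method

For each document the pipeline runs four stages:

1. **Term recognition.** Boundary-respecting regex matching of a custom
   term dictionary (132 surfaces for 27 standardized measurement
   concepts) and an abbreviation pattern list ("LVEF", "LVD ed",
   "e to e prime"); plus a *concept builder* that merges consecutive
   anatomy words (left, ventricular, aortic, ...) and measure words
   (dimension, pressure, fraction, ...) into candidate terms never seen in
   the dictionary ("dimension of the left ventricle at the end of
   diastole"). Overlaps resolve longest-first.
2. **Concept mapping.** Two-step lookup: exact dictionary match, else
   token-overlap scoring — each concept scores the number of distinct
   query tokens appearing in any of its dictionary surfaces (query
   "left ventricular diastolic dimension" scores 3 against "left
   ventricular dimension at end diastole" and 1 against "left atrium
   diameter"). Semantic mutual-exclusion constraints then discard
   contradictory candidates: a phrase containing "atrial" cannot map to a
   ventricular, mitral or tricuspid concept; a phrase containing "volume"
   cannot map to a dimension, velocity or pressure concept. A strict
   maximum maps the term; ties are discarded as ambiguous
   (precision-first).
3. **Value recognition.** Quantitative values with attached units
   ("16mm", "2 cm"), qualitative severity grades (normal … severe), and
   range merging ("50 to 55%", "low to moderate") with guards against
   dates, blood pressures and clock times.
4. **Relationship linking.** 38 configurable co-occurrence pattern rules
   instantiate the dominant template `<Term> <separator> <Value> <Unit>`:
   semi-structured separators ("=", ":") per line, narrative verb phrases
   ("was", "was measured at", "was visually estimated in a range of") per
   sentence, and the three qualitative positions ("mild aortic stenosis",
   "aortic stenosis was mild", "aortic valve has mild stenosis"). Each
   mention participates in at most one pair.

The package also ships the surrounding workflow: a *semantic
bootstrapping* harvester that proposes new dictionary terms from strings
occupying the concept slot of `<term> = <number><unit>` lines, a synthetic
report generator with exact gold annotations, and a
precision/recall/F1 evaluation harness with repeated-mention-adjusted
recall.

## Worked example

```r
library(echopairs)
res <- load_resources()
text <- "MEASUREMENTS:
LVEF = 55-60%
LVEDD: 48 mm
The mitral regurgitation was moderate."
extract_document(text, res)[, c("line", "concept_id", "value_low",
                                "value_high", "unit_id", "rule_id")]
```

```
  line                              concept_id value_low value_high unit_id   rule_id
1    2      left_ventricular_ejection_fraction        55         60 percent eq_att_rg
2    3 left_ventricular_dimension_end_diastole        48         48      mm col_att_pt
3    4              mitral_valve_regurgitation         3          3    <NA>  q_cop_pt
```

Row 1: the equals-sign rule linked the LVEF abbreviation to the range
55–60 percent. Row 2: the colon rule linked the end-diastolic dimension
to 48 mm. Row 3: a narrative qualitative rule linked "moderate" (grade
rank 3 in the shipped severity lexicon) to mitral regurgitation.

The same workflow from a shell, via the installed `exec/echopairs`
script:

```sh
echopairs generate --seed 7 --n 100 --out scratch/demo
echopairs extract  --in scratch/demo/corpus.jsonl --out scratch/demo/pairs.csv
echopairs evaluate --pred scratch/demo/pairs.csv --gold scratch/demo/gold.csv
```

On a noise-free synthetic corpus the last command prints
`precision = 1.000  recall = 1.000  f1 = 1.000`.

## Scope

The extractor deliberately does not handle split terms (multi-word terms
interleaved with other mentions), negation/hedging, cross-line linking,
or unit conversion; values are reported as written. See the methods
vignette (`vignettes/echopairs-methods.Rmd`) for the model, its
assumptions, parameter defaults, and known limitations.
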