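# mmstage

Rule-based extraction of multiple myeloma (MM) stage from free-text clinical
notes, with patient-level roll-up, evaluation, and a synthetic corpus
generator.

## The problem

Stage is an essential measure of disease risk in multiple myeloma, but it is
frequently absent from structured data: the laboratory and cytogenetic
components of the International Staging System (ISS) and its revision
(R-ISS) are often measured outside the health system that holds the record,
and registries rarely capture MM stage at all. What *is* routinely available
is the treating oncologist's own documentation of stage in hematology/
oncology notes and pathology reports — "R-ISS stage II", "ISS 3", "Durie-
Salmon IIIA", or just "stage II myeloma". `mmstage` implements a rule-based
NLP pipeline that turns that documentation into analyzable per-patient
stage variables.

The package recognises three staging systems plus a fallback category:

| Code | Meaning |
|---|---|
| `RISS` | Revised International Staging System, stages I–III |
| `ISS` | International Staging System, stages I–III |
| `DS` | Durie-Salmon, stages I–III (A/B subclasses collapsed) |
| `UNCLEAR` | a stage value documented without a named system |

## The algorithm

**Snippet construction.** Notes are scanned with a deliberately broad,
ordered set of case-insensitive trigger patterns ("stage"/"staging", ISS,
R-ISS, Durie(-Salmon), bare DS); overlapping hits resolve leftmost-longest,
and a fixed character window (100 before, 200 after each trigger) is cut as
a *snippet*.

**Snippet-level extraction** is a pipeline of four rule stages over snippet
text, all configured in an editable YAML rule set
(`system.file("extdata", "rules.yaml", package = "mmstage")`):

1. *Span labeling* — ordered regex rules mark stage values (`3`, `III`,
   `IIIA`, ranges like `II-III`), staging systems (with all common spelling
   variants), non-MM diseases for which stage is also reported (chronic
   kidney disease, other cancers, NYHA class...), antibiotic names (the
   "Bactrim DS" double-strength trap), and MM mentions.
2. *Overlap resolution* — same-category spans that overlap keep only the
   earliest rule's span ("R-ISS" beats the "ISS" inside it).
3. *Context suppression* — stage values within 50 characters of a non-MM
   disease mention are discarded, as are DS system tokens near antibiotic
   names, and bare DS tokens with no myeloma mention or stage value nearby.
4. *Association* — each surviving value links to the best system span within
   40 characters (preferring connective-linked and preceding systems, never
   across another value/system span); values with no system become
   `UNCLEAR` when anchored to the word "stage"; a clear label suppresses
   co-occurring unclear labels. Normalization maps `III → 3`,
   `"International Staging System" → ISS`, and strips DS subclass letters.

**Patient-level roll-up.** For stage at treatment initiation, only
hematology/oncology notes and pathology reports within one year of the
index date are eligible. Independently per system, the note closest in days
to the index date that carries a label for that system contributes its
value; equidistant ties prefer the note on or before the index date. A
patient with no eligible labels has missing stage.

**Evaluation.** Per-system contingency tables over units (snippets or
patients) with exact set matching: TP when predicted and gold value sets
match and are non-empty, TN when both empty, FP for any spurious value
(counted once per unit), FN for a pure miss — so cells always sum to the
unit count — plus exact precision/recall/F1 with half-up reporting, and a
seeded 80/20 development/validation split.

**Synthetic corpus.** Because real oncology notes are restricted, the
package ships a seeded generator that renders staging sentences from
templates (every system, value, numeral form, multi-label and range shape),
interleaves distractors and neutral filler prose, and emits internally
consistent gold at the mention and patient level — gold is computed from
the generation slots, never by running the extractor.

## Worked example

```r
library(mmstage)
rules <- stage_ruleset()

note <- tibble::tibble(
  note_id = "note42", patient_id = "p007",
  note_date = as.Date("2013-02-10"), note_type = "HEM_ONC",
  text = paste("Assessment and plan reviewed with the patient.",
               "Known multiple myeloma, R-ISS stage II, ISS 3 at diagnosis.",
               "Continues on Bactrim DS for prophylaxis.",
               "CKD stage 3 followed by nephrology."))
class(note) <- c("mm_notes", class(note))

sn <- snippets_from_corpus(note)
pred <- extract_snippets(sn, rules)
pred$labels[[1]]
#> # A tibble: 2 × 6
#>   system value value_start value_end system_start system_end
#>   <chr>  <int>       <int>     <int>        <int>      <int>
#> 1 RISS       2          83        85           71         76
#> 2 ISS        3          91        92           87         90
```

Both documented systems are captured with provenance offsets, while the
"Bactrim DS" token and the chronic-kidney-disease "stage 3" are correctly
suppressed. Rolling up to the patient's stage at a treatment-initiation
date of 2013-03-01:

```r
rec <- rollup_patients(pred, note,
                       tibble::tibble(patient_id = "p007",
                                      index_date = as.Date("2013-03-01")))
rec$assignments[[1]]
#> # A tibble: 2 × 5
#>   system value source_note_id source_note_date day_distance
#>   <chr>  <int> <chr>          <date>                  <int>
#> 1 RISS       2 note42         2013-02-10                 19
#> 2 ISS        3 note42         2013-02-10                 19
```

A command-line wrapper covering the whole pipeline (simulate, snippets,
extract, rollup, evaluate, split) lives at
`system.file("cli", "mmstage.R", package = "mmstage")`.

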