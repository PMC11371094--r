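---
title: "Extracting multiple myeloma stage from clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting multiple myeloma stage from clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmstage)
```

## The measurement problem

Multiple myeloma stage — under the Revised International Staging System
(R-ISS), the International Staging System (ISS), or the older Durie-Salmon
(DS) classification — is a core risk variable, yet it is rarely complete in
structured data: beta-2 microglobulin, albumin, LDH and cytogenetics are
often measured elsewhere, and registries generally do not record MM stage.
Oncologists, however, routinely write the stage they assigned into their
notes. `mmstage` treats the note text as the measurement instrument: it
finds candidate stage mentions, normalizes them into (system, value) pairs
per text snippet, and aggregates those pairs into one per-system stage per
patient at a clinically meaningful index date (treatment initiation).

A rule-based design was chosen deliberately. MM staging language is a
small, circumscribed vocabulary; regular-expression rules over it are
transparent, and an error found in review ("DS" captured from the
double-strength antibiotic "Bactrim DS") is fixed by editing one rule
rather than re-annotating and re-training a model. Every lexicon,
proximity window and connective list lives in a YAML configuration
(`inst/extdata/rules.yaml`), not in code, so the iterate-on-rules workflow
stays open to users with their own note dialects.

## Pipeline and parameters

### Snippet windows

Candidate triggers (the word stage/staging, ISS, R-ISS/RISS, Durie(-Salmon),
bare DS/D-S) are matched case-insensitively; overlapping hits resolve
leftmost-longest so "R-ISS" yields one candidate, not an extra "ISS". A
window of **100 characters before and 200 after** the trigger is cut as the
snippet — enough left context to catch a system named before the trigger and
enough right context for the value and qualifiers. Offsets are 0-based,
half-open, counted in characters. One snippet is emitted per candidate even
when windows overlap; deduplication is not attempted, because evaluation
and aggregation operate on snippets, not windows.

### Span rules and normalization

Span-labeling rules are *ordered*; the order is the overlap priority, so the
range rule ("II-III", expanded to both values) outranks the keyword rule
("stage III"), which outranks bare numerals. Value normalization maps roman
and arabic forms to integers 1–3 and strips a trailing Durie-Salmon
subclass letter (IIIA → 3; arabic "3A" is treated the same way); anything
else — "IV", "4" — is rejected as a value, not an error. System
normalization maps all supported spellings onto the four-code enumeration
{RISS, ISS, DS, UNCLEAR}.

Two precision guards are worth calling out because they are stricter than a
literal reading of the staging vocabulary:

* The bare roman numeral **I** is only a stage value immediately after a
  system token or the word "stage". A lone "I" is overwhelmingly the
  pronoun; recognising it anywhere near "ISS" would fabricate stage-1
  labels in ordinary prose.
* A bare **DS** token is only a staging system if an MM mention or a stage
  value lies within the association window, *and* never when an antibiotic
  name is nearby. The long form "Durie-Salmon" is exempt from the
  antibiotic guard — it is unambiguous regardless of what drugs appear in
  the sentence.

Bare arabic numerals additionally refuse decimal/thousands contexts and
number-with-unit readings ("3 mg", "2 tabs"), which otherwise contaminate
snippets drawn from medication lists.

### Suppression and association windows

Stage values within **50 characters** (nearest span edges) of a non-MM
disease mention are discarded; the shipped disease lexicon covers chronic
kidney disease/CKD/ESRD, NYHA/heart failure, and common non-MM cancers
(the "<site> cancer/carcinoma", lymphoma, melanoma, sarcoma families).
Association links each surviving value to a system within **40
characters**, ranking candidates by (i) whether the text between them is
only connectives/punctuation, (ii) distance, (iii) a preference for systems
that precede their value. Two refinements came out of adversarial template
cases:

* association never reaches across another value or system span, so in
  "ISS stage III, previously stage 1" the trailing "1" cannot steal ISS;
* a system *following* its value links strongly only through an explicit
  connective ("stage III **by** Durie-Salmon") — a bare comma is not
  evidence, so in "R-ISS stage 3, ISS stage 1" each value keeps its own
  preceding system.

A value with no system in range becomes `(UNCLEAR, value)` only when
anchored to the word "stage" within 15 characters before it (or matched by
a keyword-anchored rule); unanchored numerals are dropped as noise. This
reads the unclear category as "a *stage* was documented without naming the
system", which also keeps precision on windows whose stray digits have
nothing to do with staging. Finally, if a snippet yields any named-system
label, its UNCLEAR labels are removed — mirroring the annotation convention
that a clearly documented system always wins.

All window sizes are package defaults exposed in the rule file; the
original deployment's exact thresholds are not public, and these values
were fixed from the template suite before being treated as constants.

### Patient-level roll-up

Only hematology/oncology notes and pathology reports dated within
**365 days** (inclusive) of the index date are eligible — "within 1 year"
is read as a plain day difference, with no calendar-aware leap handling.
Independently per system, the eligible note closest in days to the index
date that carries a label for that system supplies the value. Equidistant
ties prefer the note **on or before** the index date (initial staging
precedes treatment more often than restaging follows it within days), then
the lexicographically earlier note id; conflicting values inside the chosen
note resolve by snippet id and then earliest provenance span. One
documented edge: a patient whose only labels are UNCLEAR receives an
UNCLEAR assignment, while a patient with no labels at all is recorded as
missing — the two situations are semantically different (stage documented
without a system vs. no stage documented) and the package keeps them apart.
No cross-system hierarchy is applied at this stage;
`apply_stage_preference()` offers an optional R-ISS > ISS > DS collapse for
downstream analyses that want a single number.

### Evaluation semantics

Scoring is unit-level with exact set matching per system. A unit predicted
`{(ISS, 2)}` against gold `{(ISS, 3)}` counts once, as a false positive:
the FP-dominant rule keeps the four cells summing exactly to the number of
units, which is what makes contingency tables across systems comparable.
Precision, recall and F1 are kept as exact ratios internally and reported
at two decimals with half-up rounding; a zero denominator yields an
explicit undefined (`NA`), never 0. "Not stage" is scored implicitly as the
all-systems-empty case. The reference validation contingency cells shipped
in `inst/extdata/` reproduce their published companion metrics under this
arithmetic in every cell except the patient-level DS F1, whose published
value (0.92) is inconsistent with the harmonic mean of its own cells
(0.9268 → 0.93 half-up); that single cell is therefore excluded from
automated checks.

`split_dev_val()` draws the validation set as `floor(f · N)` ids from a
seeded permutation: 5,207 ids at 20% give the 4,166/1,041 development/
validation partition used at the snippet level.

## The synthetic corpus: what it does and does not show

Real oncology notes are restricted, so the test bed is generated. The
generator's defaults are the study conditions the package is tested under:
**200 patients** (the scale of the annotated patient-level set), 3–10 notes
each dated within ±550 days of the index date (wider than the roll-up
window, so the window filter is exercised), a 60/15/25 mix of
HEM_ONC/PATHOLOGY/OTHER note types, staging sentences in 35% of notes with
a 25/35/20/20 system mix over RISS/ISS/DS/UNCLEAR, stage values mixed
30/40/30, distractor sentences in 25% of notes, and a 10% multi-system
rate. Sentences are rendered from the same template families the fixture
suite enumerates; gold labels are computed from the template slots, never
by running the extractor, and patient-level gold is derived from mention
gold by an independent brute-force day-distance search. Distractor
sentences are kept at least two filler sentences away from staging
sentences so mention gold stays unambiguous; deliberate cross-sentence
collisions are covered instead by hand-labeled "hard" templates whose
separations are written out explicitly.

What passing these tests shows: the rule pipeline implements its own
specification exactly on every surface form the templates enumerate, the
roll-up is equivalent to exhaustive search, and the whole stack is
deterministic under a seed. What it does not show: recall on the long tail
of real clinical language — misspellings, tables flattened to text,
copy-forward artifacts, section headers — none of which the generator
models. The published performance figures quoted with the reference cells
come from clinician-annotated VA notes and cannot be regenerated here; the
package reproduces their *arithmetic*, not their corpus.

## Numerical and degenerate-input choices

Determinism is a design requirement throughout: candidate matching and
overlap resolution have total tie-break orders (priority, leftmost,
longest), association ranks have a final positional tie-break, the
generator is fully seeded (`withr::with_seed`), and every writer emits
records in a canonical order, so repeated runs are byte-identical. Empty
inputs are defined everywhere: empty text yields no candidates, an empty
label set is the "not stage" value (not an error), an empty corpus
round-trips through every reader/writer, and evaluating an empty unit set
is the one contract error (there is nothing to score). Metric rounding uses
half-up, implemented with a small epsilon guard against binary
representation of values like 0.985.

## Known limitations

* No negation or hedging handling ("not stage III", "stage II vs III
  unclear") — value sets simply include what is written.
* No sentence segmentation or section awareness; proximity is measured in
  characters, which is simple and tokenizer-free but blind to sentence
  boundaries beyond the suppression/association windows.
* Laboratory values are never interpreted: a note listing beta-2
  microglobulin without a stage sentence yields no label, by design.
* R2-ISS is not recognised; adding it would mean one system rule, one
  normalization entry and template coverage.
* The trigger list and lexicons are tuned to English-language oncology
  notes; other specialties' "stage" vocabularies (wound staging, pressure
  ulcers) are handled only insofar as the disease lexicon covers them.
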