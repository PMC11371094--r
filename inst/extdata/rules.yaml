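# Rule set for snippet-level MM stage extraction.
# All patterns are case-insensitive PCRE, applied to snippet text.
# Rule order defines priority: when two spans of the SAME category overlap,
# the span from the earlier rule survives.
#
# Edit this file (or a copy passed to stage_ruleset()) to tune lexicons and
# proximity windows without touching code.

windows:
  # STAGE_VALUE spans within this many characters (nearest edges) of an
  # OTHER_DISEASE span are discarded.
  disease_suppression_chars: 50
  # Max nearest-edge distance between a stage value and the staging-system
  # span it may associate with.
  association_chars: 40
  # A systemless value becomes UNCLEAR only if "stage"/"staging" occurs within
  # this many characters before it (or the value was matched by a
  # keyword-anchored rule); otherwise it is dropped as noise.
  unclear_anchor_chars: 15

stage_value_rules:
  # Ranges like "II-III" or "2-3" expand to both values.
  - id: value_range
    pattern: '(?<![\d.])\b(i{1,3}[ab]?|[1-3][ab]?)\s*[-/]\s*(i{1,3}[ab]?|[1-3][ab]?)\b(?![.,]?\d)'
    range: true
    anchored: false
  # Value directly anchored to the word stage/staging ("stage III", "staging: 2").
  - id: value_after_keyword
    pattern: '\bstag(?:e[sd]?|ing)\s*(?:is|was|of|[:=])?\s*(i{1,3}[ab]?|[1-3][ab]?)\b(?![.,]?\d)'
    group: 1
    anchored: true
  # Bare roman numeral "I" is too ambiguous on its own (the pronoun); it is
  # only a value when it directly follows a staging-system token.
  - id: value_after_system
    pattern: '\b(?:r[- ]?iss|international\s+staging\s+system|iss|durie[- /]?\s*salmon|d[- ]?s)[\s:=-]*(i[ab]?)\b'
    group: 1
    anchored: false
  - id: value_bare_roman
    pattern: '\b(?:iii|ii)[ab]?\b'
    anchored: false
  # Bare arabic 1-3; guarded against decimals, thousands separators, and
  # number-with-unit readings ("3 mg", "2 tabs").
  - id: value_bare_arabic
    pattern: '(?<![\d.,])\b[1-3][ab]?\b(?![.,]?\d)(?!\s*(?:%|mg|mcg|ml|gm?\b|tabs?\b|tablets?|units?\b|cm\b|mm\b|kg\b|lbs?\b|hrs?\b|hours?|days?|weeks?|wks?\b|months?|years?|yrs?\b|times\b|cycles?\b|doses?\b|lines?\b|am\b|pm\b|x\b))'
    anchored: false

staging_system_rules:
  - id: sys_riss_long
    pattern: '\brevised\s+international\s+staging\s+system\b'
    system: RISS
  - id: sys_riss_reviss
    pattern: '\brevised\s+iss\b'
    system: RISS
  - id: sys_riss
    pattern: '\br[- ]?iss\b'
    system: RISS
  - id: sys_iss_long
    pattern: '\binternational\s+staging\s+system\b'
    system: ISS
  - id: sys_iss
    pattern: '\biss\b'
    system: ISS
  - id: sys_ds_long
    pattern: '\bdurie[- /]?\s*salmon\b'
    system: DS
  # Bare "DS"/"D-S" is kept as a staging system only when an MM mention or a
  # stage value lies within the association window (precision guard against
  # the many non-staging uses of "DS").
  - id: sys_ds_bare
    pattern: '\bd[- ]?s\b'
    system: DS
    bare: true

other_disease_rules:
  - id: dz_ckd_long
    pattern: '\bchronic\s+kidney\s+disease\b'
  - id: dz_ckd
    pattern: '\bckd\b'
  - id: dz_esrd_long
    pattern: '\bend[- ]stage\s+renal\s+disease\b'
  - id: dz_esrd
    pattern: '\besrd\b'
  - id: dz_nyha
    pattern: '\bnyha\b'
  - id: dz_chf
    pattern: '\bheart\s+failure\b'
  - id: dz_cirrhosis
    pattern: '\bcirrhosis\b'
  - id: dz_copd
    pattern: '\bcopd\b'
  - id: dz_diabetes
    pattern: '\bdiabet(?:es|ic)\b'
  - id: dz_other_cancer
    pattern: '\b(?:lung|breast|prostate|colon|colorectal|bladder|gastric|pancreatic|ovarian|cervical|renal|hepatocellular|head\s+and\s+neck|skin)\s+(?:cancer|carcinoma|ca)\b'
  - id: dz_carcinoma
    pattern: '\b(?:adeno)?carcinoma\b'
  - id: dz_lymphoma
    pattern: '\blymphoma\b'
  - id: dz_melanoma
    pattern: '\bmelanoma\b'
  - id: dz_sarcoma
    pattern: '\bsarcoma\b'
  - id: dz_hodgkin
    pattern: '\bhodgkin\b'

antibiotic_rules:
  - id: abx_bactrim
    pattern: '\bbactrim\b'
  - id: abx_septra
    pattern: '\bseptra\b'
  - id: abx_sulfatrim
    pattern: '\bsulfatrim\b'
  - id: abx_tmp_smx_long
    pattern: '\btrimethoprim[-/\s]*sulfamethoxazole\b'
  - id: abx_smx
    pattern: '\bsulfamethoxazole\b'
  - id: abx_tmp
    pattern: '\btrimethoprim\b'
  - id: abx_tmpsmx
    pattern: '\btmp[-/]?smx\b'
  - id: abx_cotrimoxazole
    pattern: '\bco-?trimoxazole\b'

mm_mention_rules:
  - id: mm_long
    pattern: '\bmultiple\s+myeloma\b'
  - id: mm_myeloma
    pattern: '\bmyeloma\b'
  - id: mm_plasma_cell
    pattern: '\bplasma\s+cell\s+(?:myeloma|neoplasm|dyscrasia)\b'
  - id: mm_abbrev
    pattern: '\bmm\b'

# Words that may sit between a staging system and a stage value without
# breaking their association ("stage III by Durie-Salmon").
connectives: [by, per, on, using, of, is, was, stage, stages, staged, staging]

value_map:
  I: 1
  II: 2
  III: 3
  '1': 1
  '2': 2
  '3': 3

system_map:
  ISS: ISS
  INTERNATIONAL STAGING SYSTEM: ISS
  R-ISS: RISS
  RISS: RISS
  REVISED ISS: RISS
  REVISED INTERNATIONAL STAGING SYSTEM: RISS
  DS: DS
  D-S: DS
  DURIE-SALMON: DS
  DURIE SALMON: DS
  DURIE/SALMON: DS
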