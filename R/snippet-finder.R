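# Candidate detection and snippet windowing. A snippet is the fixed character
# window (default 100 before / 200 after) cut around each trigger match; the
# downstream extractor only ever sees snippet text.

#' Snippet window configuration
#'
#' @param chars_before,chars_after Window extent in characters around the
#'   trigger match (defaults 100 and 200).
#' @param patterns Ordered character vector of case-insensitive PCRE trigger
#'   patterns; see [default_trigger_patterns()]. The trigger set deliberately
#'   over-generates (high recall): downstream rules do the filtering.
#' @return A list of class `snippet_window_config`.
#' @export
snippet_window_config <- function(chars_before = 100L, chars_after = 200L,
                                  patterns = default_trigger_patterns()) {
  stopifnot(chars_before >= 0, chars_after >= 0, length(patterns) > 0)
  structure(list(chars_before = as.integer(chars_before),
                 chars_after = as.integer(chars_after),
                 patterns = as.character(patterns)),
            class = "snippet_window_config")
}

#' Default trigger patterns for candidate stage mentions
#'
#' Broad, ordered, case-insensitive patterns covering the word
#' "stage"/"staging", the system abbreviations ISS / R-ISS / RISS, "Durie"
#' (with or without "-Salmon"), and the bare "DS" / "D-S" token.
#'
#' @return Character vector of PCRE patterns.
#' @export
default_trigger_patterns <- function() {
  c("\\br[- ]?iss\\b",
    "\\biss\\b",
    "\\bstag(?:ing|e[sd]?)\\b",
    "\\bdurie(?:[- /]?salmon)?\\b",
    "\\bd[- ]?s\\b")
}

# All matches of one case-insensitive PCRE pattern, as 0-based half-open
# [start, end) character offsets.
pcre_match_spans <- function(text, pattern) {
  if (is.na(text) || !nzchar(text)) {
    return(tibble(start = integer(), end = integer()))
  }
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(tibble(start = integer(), end = integer()))
  start <- as.integer(m) - 1L
  tibble(start = start, end = start + attr(m, "match.length"))
}

#' Find candidate stage mentions in note text
#'
#' Runs every trigger pattern over the text and resolves overlapping matches
#' leftmost-longest (so "ISS" inside "R-ISS" yields one candidate, not two).
#'
#' @param text Note text (a single string).
#' @param config A [snippet_window_config()].
#' @return Tibble of candidate matches, left to right, with 0-based half-open
#'   `start`/`end` offsets and `matched_text`.
#' @export
find_stage_candidates <- function(text, config = snippet_window_config()) {
  hits <- bind_rows(lapply(config$patterns, function(p) pcre_match_spans(text, p)))
  if (nrow(hits) == 0) {
    return(tibble(start = integer(), end = integer(), matched_text = character()))
  }
  hits <- hits[order(hits$start, -hits$end), , drop = FALSE]
  keep <- logical(nrow(hits))
  last_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- hits$end[i]
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits$matched_text <- substr_offsets(text, hits$start, hits$end)
  as_tibble(hits)
}

# substring by 0-based half-open character offsets
substr_offsets <- function(text, start, end) {
  substring(text, start + 1L, end)
}

#' Cut a snippet window around one candidate match
#'
#' The window is `[max(0, start - chars_before), min(nchar, end +
#' chars_after))`, clamped at the note boundaries; the snippet inherits the
#' note's patient id, date, and type.
#'
#' @param note One-row `mm_notes` tibble (or list with the note fields).
#' @param match One-row candidate tibble from [find_stage_candidates()].
#' @param config A [snippet_window_config()].
#' @return One-row `mm_snippets` tibble.
#' @export
make_snippet <- function(note, match, config = snippet_window_config()) {
  n <- nchar(note$text)
  if (match$start < 0 || match$end > n || match$start >= match$end) {
    abort("candidate match offsets out of bounds for note text")
  }
  ws <- max(0L, as.integer(match$start) - config$chars_before)
  we <- min(n, as.integer(match$end) + config$chars_after)
  new_mm_tbl(tibble(
    snippet_id = paste0(note$note_id, ":", match$start),
    note_id = note$note_id,
    patient_id = note$patient_id,
    note_date = note$note_date,
    note_type = if ("note_type" %in% names(note)) note$note_type else NA_character_,
    window_start = ws, window_end = we,
    text = substr_offsets(note$text, ws, we),
    trigger_start = as.integer(match$start), trigger_end = as.integer(match$end),
    trigger_text = match$matched_text
  ), "mm_snippets")
}

#' Build all snippets for a corpus
#'
#' One snippet per candidate per note; ids are deterministic
#' (`note_id:trigger_start`), output ordered by note order then offset.
#'
#' @param notes A `mm_notes` tibble.
#' @param config A [snippet_window_config()].
#' @return A `mm_snippets` tibble.
#' @export
snippets_from_corpus <- function(notes, config = snippet_window_config()) {
  out <- lapply(seq_len(nrow(notes)), function(i) {
    note <- notes[i, ]
    cand <- find_stage_candidates(note$text, config)
    if (nrow(cand) == 0) return(NULL)
    bind_rows(lapply(seq_len(nrow(cand)), function(j) make_snippet(note, cand[j, ], config)))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) out <- empty_snippets()
  new_mm_tbl(out, "mm_snippets")
}
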