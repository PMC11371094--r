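# The snippet-level extractor: label spans, resolve same-category overlaps,
# suppress non-MM context, then associate stage values with staging systems.
# All offsets are 0-based half-open character positions within snippet text.

pcre_rule_spans <- function(text, pattern, group = 0L) {
  if (is.na(text) || !nzchar(text)) return(tibble(start = integer(), end = integer()))
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(tibble(start = integer(), end = integer()))
  if (group == 0L) {
    start <- as.integer(m) - 1L
    len <- attr(m, "match.length")
  } else {
    start <- attr(m, "capture.start")[, group] - 1L
    len <- attr(m, "capture.length")[, group]
  }
  tibble(start = as.integer(start), end = as.integer(start + len))
}

empty_spans <- function() {
  tibble(category = character(), start = integer(), end = integer(),
         raw = character(), normalized = character(), values = list(),
         rule_id = character(), rule_priority = integer(),
         anchored = logical(), bare = logical())
}

#' Label spans in snippet text
#'
#' Runs every span rule in the rule set over the text and emits one span per
#' match: stage values (with their normalized integer value(s); a value that
#' fails normalization, e.g. "IV", is silently rejected), staging systems
#' (with the canonical system code), non-MM diseases, antibiotics, and MM
#' mentions. Overlaps are not yet resolved.
#'
#' @param text Snippet text.
#' @param rules A [stage_ruleset()].
#' @return Span tibble with columns `category`, `start`, `end`, `raw`,
#'   `normalized`, `values` (list-column of integer stage values, non-empty
#'   for `STAGE_VALUE` spans only), `rule_id`, `rule_priority`, `anchored`,
#'   `bare`.
#' @export
label_spans <- function(text, rules = stage_ruleset()) {
  out <- lapply(seq_len(nrow(rules$spans)), function(i) {
    r <- rules$spans[i, ]
    hits <- pcre_rule_spans(text, r$pattern, r$group)
    if (nrow(hits) == 0) return(NULL)
    raw <- substr_offsets(text, hits$start, hits$end)
    vals <- rep(list(integer()), nrow(hits))
    normalized <- rep(NA_character_, nrow(hits))
    if (r$category == "STAGE_VALUE") {
      vals <- lapply(raw, normalize_value_span, is_range = r$range, rules = rules)
      ok <- !vapply(vals, is.null, logical(1))
      hits <- hits[ok, , drop = FALSE]
      raw <- raw[ok]
      vals <- vals[ok]
      if (nrow(hits) == 0) return(NULL)
      normalized <- vapply(vals, function(v) paste(v, collapse = "-"), character(1))
    } else if (r$category == "STAGING_SYSTEM") {
      normalized <- rep(r$system, nrow(hits))
      vals <- rep(list(integer()), nrow(hits))
    } else {
      normalized <- rep(r$rule_id, nrow(hits))
      vals <- rep(list(integer()), nrow(hits))
    }
    tibble(category = r$category, start = hits$start, end = hits$end, raw = raw,
           normalized = normalized, values = vals, rule_id = r$rule_id,
           rule_priority = r$rule_priority, anchored = r$anchored, bare = r$bare)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) return(empty_spans())
  out[order(out$start, out$end), ]
}

spans_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# Nearest-edge character distance between two spans (0 when they touch or
# overlap).
span_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1, s1 - e2))
}

#' Resolve same-category span overlaps
#'
#' Among spans of the same category that overlap in character range, only the
#' span from the earliest rule (lowest `rule_priority`) survives; ties break
#' leftmost then longest. Overlaps across categories are all retained.
#'
#' @param spans Span tibble from [label_spans()].
#' @return Span tibble with overlaps resolved.
#' @export
resolve_overlaps <- function(spans) {
  if (nrow(spans) < 2) return(spans)
  ord <- order(spans$rule_priority, spans$start, -(spans$end - spans$start))
  keep <- logical(nrow(spans))
  for (i in ord) {
    kept <- which(keep & spans$category == spans$category[i])
    clash <- any(spans_overlap(spans$start[i], spans$end[i],
                               spans$start[kept], spans$end[kept]))
    keep[i] <- !clash
  }
  out <- spans[keep, , drop = FALSE]
  out[order(out$start, out$end), ]
}

#' Suppress stage spans arising from non-MM context
#'
#' Three suppression rules, applied after overlap resolution:
#' * a `STAGE_VALUE` span within the disease-suppression window of an
#'   `OTHER_DISEASE` span is discarded (chronic kidney disease stage,
#'   other-cancer stage, ...);
#' * a `DS` staging-system span within the window of an `ANTIBIOTIC` span is
#'   discarded (the "Bactrim DS" double-strength trap);
#' * a bare-token `DS` span with neither an MM mention nor a stage value
#'   within the association window is discarded.
#'
#' @param spans Span tibble (overlap-resolved).
#' @param rules A [stage_ruleset()].
#' @return Span tibble with suppressed spans removed.
#' @export
suppress_nonmm_context <- function(spans, rules = stage_ruleset()) {
  if (nrow(spans) == 0) return(spans)
  w_dz <- rules$windows$disease_suppression_chars
  w_assoc <- rules$windows$association_chars
  near_any <- function(i, targets, window) {
    if (length(targets) == 0) return(FALSE)
    any(span_gap(spans$start[i], spans$end[i],
                 spans$start[targets], spans$end[targets]) <= window)
  }
  dz <- which(spans$category == "OTHER_DISEASE")
  abx <- which(spans$category == "ANTIBIOTIC")
  drop <- logical(nrow(spans))
  for (i in which(spans$category == "STAGE_VALUE")) {
    drop[i] <- near_any(i, dz, w_dz)
  }
  for (i in which(spans$category == "STAGING_SYSTEM" & spans$normalized == "DS")) {
    if (spans$bare[i] && near_any(i, abx, w_dz)) drop[i] <- TRUE
  }
  # bare-DS support requirement, assessed against surviving values
  vals <- which(spans$category == "STAGE_VALUE" & !drop)
  mm <- which(spans$category == "MM_MENTION")
  for (i in which(spans$category == "STAGING_SYSTEM" & spans$bare & !drop)) {
    if (!near_any(i, c(vals, mm), w_assoc)) drop[i] <- TRUE
  }
  spans[!drop, , drop = FALSE]
}

connective_only <- function(between, connectives) {
  pat <- paste0("^[\\s[:punct:]]*(?:(?:",
                paste(connectives, collapse = "|"),
                ")\\b[\\s[:punct:]]*)*$")
  grepl(pat, between, perl = TRUE, ignore.case = TRUE)
}

#' Associate stage values with staging systems
#'
#' Each surviving `STAGE_VALUE` span links to the best `STAGING_SYSTEM` span
#' within the association window. Candidates are ranked by (1) whether the
#' text between the two spans consists only of connectives/punctuation
#' ("stage III **by** Durie-Salmon"), (2) nearest-edge distance, (3) a
#' preference for a system that precedes the value, then position. A system
#' cannot associate across another stage value or system span. A value with
#' no system in range becomes `(UNCLEAR, value)` when anchored to a nearby
#' "stage"/"staging" keyword, and is dropped otherwise. If the final set
#' contains any named-system label, all UNCLEAR labels are removed (a clearly
#' documented system always wins over an unclear one).
#'
#' @param spans Suppressed span tibble.
#' @param rules A [stage_ruleset()].
#' @param text The snippet text the spans came from.
#' @return Deduplicated label tibble with columns `system`, `value`, and
#'   provenance offsets `value_start`, `value_end`, `system_start`,
#'   `system_end` (NA for UNCLEAR).
#' @export
associate_stage_labels <- function(spans, rules = stage_ruleset(), text = "") {
  vals <- spans[spans$category == "STAGE_VALUE", , drop = FALSE]
  syss <- spans[spans$category == "STAGING_SYSTEM", , drop = FALSE]
  others <- spans[spans$category %in% c("STAGE_VALUE", "STAGING_SYSTEM"), , drop = FALSE]
  w_assoc <- rules$windows$association_chars
  w_anchor <- rules$windows$unclear_anchor_chars
  out <- list()
  for (i in seq_len(nrow(vals))) {
    v <- vals[i, ]
    chosen <- NULL
    if (nrow(syss) > 0) {
      gap <- span_gap(v$start, v$end, syss$start, syss$end)
      cand <- which(gap <= w_assoc)
      # no association across an intervening value or system span
      cand <- cand[vapply(cand, function(j) {
        lo <- min(v$end, syss$end[j]); hi <- max(v$start, syss$start[j])
        if (lo > hi) return(TRUE)
        blockers <- spans_overlap(lo, hi, others$start, others$end) &
          !(others$start == v$start & others$end == v$end) &
          !(others$start == syss$start[j] & others$end == syss$end[j])
        !any(blockers)
      }, logical(1))]
      if (length(cand) > 0) {
        between <- vapply(cand, function(j) {
          lo <- min(v$end, syss$end[j]); hi <- max(v$start, syss$start[j])
          if (lo >= hi) "" else substr_offsets(text, lo, hi)
        }, character(1))
        precedes <- ifelse(syss$start[cand] < v$start, 0L, 1L)
        # a preceding system links strongly across connectives/punctuation
        # ("ISS: 3", "ISS stage 3"); a following system needs an explicit
        # linking word ("stage III by Durie-Salmon"), not a bare comma
        rank <- ifelse(connective_only(between, rules$connectives) &
                         (precedes == 0L |
                            grepl("\\b(?:by|per|using|on)\\b", between,
                                  perl = TRUE, ignore.case = TRUE)),
                       0L, 1L)
        ord <- order(rank, gap[cand], precedes, syss$start[cand])
        chosen <- syss[cand[ord[1]], ]
      }
    }
    if (!is.null(chosen)) {
      out[[length(out) + 1L]] <- tibble(
        system = chosen$normalized, value = v$values[[1]],
        value_start = v$start, value_end = v$end,
        system_start = chosen$start, system_end = chosen$end)
    } else {
      anchored <- v$anchored
      if (!anchored && nzchar(text)) {
        back <- substr_offsets(text, max(0L, v$start - w_anchor), v$start)
        anchored <- grepl("\\bstag", back, perl = TRUE, ignore.case = TRUE)
      }
      if (anchored) {
        out[[length(out) + 1L]] <- tibble(
          system = "UNCLEAR", value = v$values[[1]],
          value_start = v$start, value_end = v$end,
          system_start = NA_integer_, system_end = NA_integer_)
      }
    }
  }
  labels <- bind_rows(out)
  if (nrow(labels) == 0) return(empty_prediction_labels())
  if (any(labels$system != "UNCLEAR")) {
    labels <- labels[labels$system != "UNCLEAR", , drop = FALSE]
  }
  labels <- labels[order(labels$value_start, labels$system, labels$value), ]
  labels[!duplicated(labels[, c("system", "value")]), , drop = FALSE]
}

#' Extract stage labels from raw text
#'
#' The full four-stage extractor on one string: [label_spans()] then
#' [resolve_overlaps()] then [suppress_nonmm_context()] then
#' [associate_stage_labels()]. An empty result encodes "not stage".
#'
#' @param text Snippet text.
#' @param rules A [stage_ruleset()].
#' @return Label tibble as from [associate_stage_labels()].
#' @export
#' @examples
#' rules <- stage_ruleset()
#' extract_stage_text("multiple myeloma, ISS stage III", rules)
#' extract_stage_text("Bactrim DS 800-160 bid", rules)
extract_stage_text <- function(text, rules = stage_ruleset()) {
  spans <- label_spans(text, rules)
  spans <- resolve_overlaps(spans)
  spans <- suppress_nonmm_context(spans, rules)
  associate_stage_labels(spans, rules, text)
}

#' Extract the stage label set for one snippet
#'
#' @param snippet One-row `mm_snippets` tibble.
#' @param rules A [stage_ruleset()].
#' @return One-row `mm_predictions` tibble (`snippet_id`, note metadata,
#'   list-column `labels` with provenance offsets; empty labels = "not
#'   stage").
#' @export
extract_snippet_stage <- function(snippet, rules = stage_ruleset()) {
  labels <- extract_stage_text(snippet$text, rules)
  new_mm_tbl(tibble(snippet_id = snippet$snippet_id,
                    note_id = snippet$note_id,
                    patient_id = snippet$patient_id,
                    note_date = snippet$note_date,
                    note_type = if ("note_type" %in% names(snippet)) snippet$note_type else NA_character_,
                    labels = list(labels)),
             "mm_predictions")
}

#' Extract stage labels for a snippet collection
#'
#' @param snippets A `mm_snippets` tibble.
#' @param rules A [stage_ruleset()].
#' @return A `mm_predictions` tibble, one row per snippet, in snippet order.
#' @export
extract_snippets <- function(snippets, rules = stage_ruleset()) {
  rows <- lapply(seq_len(nrow(snippets)), function(i) {
    extract_snippet_stage(snippets[i, ], rules)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(snippet_id = character(), note_id = character(),
                  patient_id = character(), note_date = as.Date(character()),
                  note_type = character(), labels = list())
  }
  new_mm_tbl(out, "mm_predictions")
}
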