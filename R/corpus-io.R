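# Corpus, annotation and prediction I/O. Canonical on-disk format is JSONL
# (one object per line); CSV is accepted for notes only, since free text with
# embedded newlines is fragile in CSV. Dates are ISO-8601 days; all character
# offsets are 0-based half-open, counted in characters.

#' Construct a stage label set
#'
#' A stage label is a (staging system, stage value) pair; a set of them is the
#' atomic extraction output for one snippet. An empty set encodes "not stage".
#'
#' @param system Character vector of staging-system codes (see
#'   [staging_systems()]).
#' @param value Integer vector of stage values in `{1, 2, 3}`.
#' @return A tibble with columns `system` and `value`.
#' @export
#' @examples
#' stage_labels(c("ISS", "RISS"), c(3, 2))
#' stage_labels() # "not stage"
stage_labels <- function(system = character(), value = integer()) {
  system <- as.character(system)
  value <- as.integer(value)
  stopifnot(length(system) == length(value))
  if (length(system) > 0) {
    bad <- !system %in% STAGING_SYSTEMS
    if (any(bad)) {
      abort(paste0("unknown staging system: ", paste(unique(system[bad]), collapse = ", ")))
    }
    if (any(!value %in% 1:3)) abort("stage value must be in {1, 2, 3}")
  }
  tibble(system = system, value = value)
}

# Validity rule shared by annotations and predictions: a label set never mixes
# UNCLEAR with a named system (the clear label wins).
assert_clear_over_unclear <- function(labels, what = "label set") {
  if (nrow(labels) > 0 && any(labels$system == "UNCLEAR") &&
      any(labels$system != "UNCLEAR")) {
    abort(paste0(what, " mixes UNCLEAR with a named staging system"))
  }
  invisible(labels)
}

new_mm_tbl <- function(x, class) {
  structure(as_tibble(x), class = c(class, class(as_tibble(x))))
}

parse_note_date <- function(x, line = NULL) {
  d <- suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
  if (any(is.na(d)) || any(format(d, "%Y-%m-%d") != as.character(x))) {
    where <- if (is.null(line)) "" else paste0(" at line ", line)
    abort(paste0("unparseable date '", x[is.na(d) | TRUE][1], "'", where,
                 " (expected YYYY-MM-DD)"))
  }
  d
}

required_fields <- function(rec, fields, line, path) {
  missing <- setdiff(fields, names(rec))
  if (length(missing) > 0) {
    abort(paste0(basename(path), " line ", line, ": missing required field(s) ",
                 paste(missing, collapse = ", ")))
  }
}

#' Read clinical notes from JSONL or CSV
#'
#' One record per line (JSONL) or row (CSV) with fields `note_id`,
#' `patient_id`, `note_date` (ISO-8601), `note_type`, `text`. Raw note-type
#' strings may be mapped to the canonical vocabulary (`HEM_ONC`, `PATHOLOGY`,
#' `OTHER`) via `note_type_map`; unmapped values fall back to `OTHER` with a
#' warning. Malformed records raise an error naming the offending line.
#'
#' @param path Path to a `.jsonl` or `.csv` file.
#' @param note_type_map Optional named character vector mapping raw note-type
#'   strings (names) to canonical codes (values). Canonical codes always map
#'   to themselves.
#' @return A `mm_notes` tibble in file order with columns `note_id`,
#'   `patient_id`, `note_date` (`Date`), `note_type`, `text`.
#' @export
read_notes <- function(path, note_type_map = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    recs <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
    lines <- seq_len(nrow(df)) + 1L # header offset, for error messages
  } else {
    raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
    keep <- nzchar(trimws(raw))
    recs <- lapply(which(keep), function(i) {
      tryCatch(jsonlite::fromJSON(raw[[i]], simplifyVector = TRUE),
               error = function(e) abort(paste0(basename(path), " line ", i,
                                                ": invalid JSON (", conditionMessage(e), ")")))
    })
    lines <- which(keep)
  }
  if (length(recs) == 0) {
    return(new_mm_tbl(tibble(note_id = character(), patient_id = character(),
                             note_date = as.Date(character()),
                             note_type = character(), text = character()),
                      "mm_notes"))
  }
  fields <- c("note_id", "patient_id", "note_date", "note_type", "text")
  rows <- map2(recs, lines, function(rec, ln) {
    required_fields(rec, fields, ln, path)
    tibble(note_id = as.character(rec$note_id),
           patient_id = as.character(rec$patient_id),
           note_date = parse_note_date(rec$note_date, ln),
           note_type = as.character(rec$note_type),
           text = as.character(rec$text))
  })
  notes <- bind_rows(rows)
  if (anyDuplicated(notes$note_id)) {
    abort(paste0("duplicate note_id in ", basename(path), ": ",
                 notes$note_id[duplicated(notes$note_id)][1]))
  }
  notes$note_type <- canonical_note_type(notes$note_type, note_type_map)
  new_mm_tbl(notes, "mm_notes")
}

canonical_note_type <- function(raw, note_type_map = NULL) {
  map <- stats::setNames(NOTE_TYPES, NOTE_TYPES)
  if (!is.null(note_type_map)) map <- c(map, note_type_map)
  out <- unname(map[raw])
  unknown <- is.na(out)
  if (any(unknown)) {
    warn(paste0("unknown note_type value(s) mapped to OTHER: ",
                paste(unique(raw[unknown]), collapse = ", ")))
    out[unknown] <- "OTHER"
  }
  out
}

labels_from_json <- function(x, where) {
  if (is.null(x) || length(x) == 0) return(stage_labels())
  if (is.data.frame(x)) {
    lab <- stage_labels(normalize_system_token(x$system, where), x$value)
  } else {
    lab <- bind_rows(lapply(x, function(l) {
      stage_labels(normalize_system_token(l$system, where), l$value)
    }))
  }
  assert_clear_over_unclear(lab, where)
  dplyr::distinct(lab)
}

# Gold files may spell systems loosely ("R-ISS", "unclear"); normalize to the
# canonical enum, erroring on anything unrecognized.
normalize_system_token <- function(x, where) {
  canon <- toupper(gsub("[^A-Za-z]", "", as.character(x)))
  out <- dplyr::case_match(canon,
    c("RISS", "REVISEDISS", "REVISEDINTERNATIONALSTAGINGSYSTEM") ~ "RISS",
    c("ISS", "INTERNATIONALSTAGINGSYSTEM") ~ "ISS",
    c("DS", "DURIESALMON") ~ "DS",
    c("UNCLEAR", "UNCLEARSTAGE") ~ "UNCLEAR"
  )
  if (any(is.na(out))) {
    abort(paste0(where, ": unknown staging system '", x[is.na(out)][1], "'"))
  }
  out
}

#' Read gold annotations
#'
#' @param path Path to a JSONL annotation file.
#' @param level `"snippet"` for snippet-level label sets (`snippet_id`,
#'   `labels`; an empty `labels` array means "not stage") or `"patient"` for
#'   patient-level stage at the index date (`patient_id`, `index_date`,
#'   `per_system`, `missing`).
#' @return A `mm_snippet_gold` tibble (`snippet_id`, list-column `labels`) or
#'   a `mm_patient_gold` tibble (`patient_id`, `index_date`, list-column
#'   `per_system` of named integer vectors, `missing`).
#' @export
read_annotations <- function(path, level = c("snippet", "patient")) {
  level <- match.arg(level)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  idx <- which(nzchar(trimws(raw)))
  recs <- lapply(idx, function(i) {
    tryCatch(jsonlite::fromJSON(raw[[i]], simplifyVector = FALSE),
             error = function(e) abort(paste0(basename(path), " line ", i,
                                              ": invalid JSON")))
  })
  if (level == "snippet") {
    rows <- map2(recs, idx, function(rec, ln) {
      required_fields(rec, c("snippet_id", "labels"), ln, path)
      tibble(snippet_id = as.character(rec$snippet_id),
             labels = list(labels_from_json(rec$labels,
                                            paste0(basename(path), " line ", ln))))
    })
    out <- bind_rows(rows)
    if (nrow(out) == 0) out <- tibble(snippet_id = character(), labels = list())
    return(new_mm_tbl(out, "mm_snippet_gold"))
  }
  rows <- map2(recs, idx, function(rec, ln) {
    required_fields(rec, c("patient_id", "index_date"), ln, path)
    ps <- rec$per_system
    if (is.null(ps) || length(ps) == 0) {
      per <- stats::setNames(integer(), character())
    } else {
      sys <- normalize_system_token(names(ps), paste0(basename(path), " line ", ln))
      val <- as.integer(unlist(ps, use.names = FALSE))
      if (any(!val %in% 1:3)) {
        abort(paste0(basename(path), " line ", ln, ": stage value outside {1,2,3}"))
      }
      per <- stats::setNames(val, sys)
    }
    tibble(patient_id = as.character(rec$patient_id),
           index_date = parse_note_date(rec$index_date, ln),
           per_system = list(per),
           missing = length(per) == 0)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(patient_id = character(), index_date = as.Date(character()),
                  per_system = list(), missing = logical())
  }
  new_mm_tbl(out, "mm_patient_gold")
}

labels_to_json <- function(labels) {
  if (is.null(labels) || nrow(labels) == 0) return(list())
  lapply(seq_len(nrow(labels)), function(i) {
    rec <- list(system = labels$system[i], value = labels$value[i])
    for (f in c("value_start", "value_end", "system_start", "system_end")) {
      if (f %in% names(labels) && !is.na(labels[[f]][i])) rec[[f]] <- labels[[f]][i]
    }
    rec
  })
}

write_jsonl <- function(objs, path) {
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) abort(paste0("output directory does not exist: ", dirname(path)))
  lines <- vapply(objs, function(o) {
    as.character(jsonlite::toJSON(o, auto_unbox = TRUE, null = "null", digits = NA))
  }, character(1))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort(paste0("cannot write to ", path)))
  on.exit(close(con))
  if (length(lines) > 0) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Write package records to JSONL
#'
#' Generic writer for every container the pipeline produces (notes, snippets,
#' snippet/patient gold, predictions, patient stage records). Output is
#' re-readable by the corresponding reader, so `read(write(x))` returns `x`.
#'
#' @param records A `mm_notes`, `mm_snippets`, `mm_snippet_gold`,
#'   `mm_patient_gold`, `mm_predictions`, or `mm_patient_stage` tibble.
#' @param path Output file path (JSONL).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) UseMethod("write_records")

#' @export
write_records.default <- function(records, path) {
  abort(paste0("no JSONL writer for class ", paste(class(records), collapse = "/")))
}

#' @export
write_records.mm_notes <- function(records, path) {
  write_jsonl(lapply(seq_len(nrow(records)), function(i) {
    list(note_id = records$note_id[i], patient_id = records$patient_id[i],
         note_date = format(records$note_date[i], "%Y-%m-%d"),
         note_type = records$note_type[i], text = records$text[i])
  }), path)
}

#' @export
write_records.mm_snippet_gold <- function(records, path) {
  write_jsonl(lapply(seq_len(nrow(records)), function(i) {
    list(snippet_id = records$snippet_id[i],
         labels = labels_to_json(records$labels[[i]][, c("system", "value")]))
  }), path)
}

#' @export
write_records.mm_patient_gold <- function(records, path) {
  write_jsonl(lapply(seq_len(nrow(records)), function(i) {
    per <- records$per_system[[i]]
    list(patient_id = records$patient_id[i],
         index_date = format(records$index_date[i], "%Y-%m-%d"),
         per_system = if (length(per) == 0) stats::setNames(list(), character()) else as.list(per),
         missing = records$missing[i])
  }), path)
}

#' @export
write_records.mm_snippets <- function(records, path) {
  write_jsonl(lapply(seq_len(nrow(records)), function(i) {
    list(snippet_id = records$snippet_id[i], note_id = records$note_id[i],
         patient_id = records$patient_id[i],
         note_date = format(records$note_date[i], "%Y-%m-%d"),
         note_type = records$note_type[i],
         window_start = records$window_start[i], window_end = records$window_end[i],
         text = records$text[i],
         trigger = list(start = records$trigger_start[i], end = records$trigger_end[i],
                        matched_text = records$trigger_text[i]))
  }), path)
}

#' @export
write_records.mm_predictions <- function(records, path) {
  write_jsonl(lapply(seq_len(nrow(records)), function(i) {
    rec <- list(snippet_id = records$snippet_id[i],
                labels = labels_to_json(records$labels[[i]]))
    for (f in c("note_id", "patient_id", "note_type")) {
      if (f %in% names(records)) rec[[f]] <- records[[f]][i]
    }
    if ("note_date" %in% names(records)) {
      rec$note_date <- format(records$note_date[i], "%Y-%m-%d")
    }
    rec
  }), path)
}

#' @export
write_records.mm_patient_stage <- function(records, path) {
  write_jsonl(lapply(seq_len(nrow(records)), function(i) {
    asg <- records$assignments[[i]]
    list(patient_id = records$patient_id[i],
         index_date = format(records$index_date[i], "%Y-%m-%d"),
         assignments = if (nrow(asg) == 0) list() else
           lapply(seq_len(nrow(asg)), function(j) {
             list(system = asg$system[j], value = asg$value[j],
                  source_note_id = asg$source_note_id[j],
                  source_note_date = format(asg$source_note_date[j], "%Y-%m-%d"),
                  day_distance = asg$day_distance[j])
           }),
         missing = records$missing[i])
  }), path)
}

#' Read snippets, predictions, or patient stage records
#'
#' Readers for the remaining JSONL schemas produced by [write_records()].
#'
#' @param path Path to a JSONL file.
#' @return `read_snippets()` a `mm_snippets` tibble; `read_predictions()` a
#'   `mm_predictions` tibble; `read_patient_stage()` a `mm_patient_stage`
#'   tibble.
#' @name io-readers
NULL

read_jsonl_records <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  idx <- which(nzchar(trimws(raw)))
  list(recs = lapply(idx, function(i) jsonlite::fromJSON(raw[[i]], simplifyVector = FALSE)),
       lines = idx)
}

#' @rdname io-readers
#' @export
read_snippets <- function(path) {
  x <- read_jsonl_records(path)
  rows <- map2(x$recs, x$lines, function(rec, ln) {
    required_fields(rec, c("snippet_id", "note_id", "text", "window_start",
                           "window_end", "trigger"), ln, path)
    tibble(snippet_id = rec$snippet_id, note_id = rec$note_id,
           patient_id = rec$patient_id %||% NA_character_,
           note_date = parse_note_date(rec$note_date, ln),
           note_type = rec$note_type %||% NA_character_,
           window_start = as.integer(rec$window_start),
           window_end = as.integer(rec$window_end),
           text = rec$text,
           trigger_start = as.integer(rec$trigger$start),
           trigger_end = as.integer(rec$trigger$end),
           trigger_text = rec$trigger$matched_text)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- empty_snippets()
  new_mm_tbl(out, "mm_snippets")
}

#' @rdname io-readers
#' @export
read_predictions <- function(path) {
  x <- read_jsonl_records(path)
  rows <- map2(x$recs, x$lines, function(rec, ln) {
    required_fields(rec, c("snippet_id", "labels"), ln, path)
    lab <- labels_from_provenance_json(rec$labels, paste0(basename(path), " line ", ln))
    tibble(snippet_id = rec$snippet_id,
           note_id = rec$note_id %||% NA_character_,
           patient_id = rec$patient_id %||% NA_character_,
           note_date = if (is.null(rec$note_date)) as.Date(NA) else parse_note_date(rec$note_date, ln),
           note_type = rec$note_type %||% NA_character_,
           labels = list(lab))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(snippet_id = character(), note_id = character(),
                  patient_id = character(), note_date = as.Date(character()),
                  note_type = character(), labels = list())
  }
  new_mm_tbl(out, "mm_predictions")
}

labels_from_provenance_json <- function(x, where) {
  if (is.null(x) || length(x) == 0) return(empty_prediction_labels())
  out <- bind_rows(lapply(x, function(l) {
    tibble(system = normalize_system_token(l$system, where),
           value = as.integer(l$value),
           value_start = as.integer(l$value_start %||% NA_integer_),
           value_end = as.integer(l$value_end %||% NA_integer_),
           system_start = as.integer(l$system_start %||% NA_integer_),
           system_end = as.integer(l$system_end %||% NA_integer_))
  }))
  assert_clear_over_unclear(out, where)
  out
}

#' @rdname io-readers
#' @export
read_patient_stage <- function(path) {
  x <- read_jsonl_records(path)
  rows <- map2(x$recs, x$lines, function(rec, ln) {
    required_fields(rec, c("patient_id", "index_date", "assignments", "missing"), ln, path)
    asg <- if (length(rec$assignments) == 0) empty_assignments() else
      bind_rows(lapply(rec$assignments, function(a) {
        tibble(system = normalize_system_token(a$system, path), value = as.integer(a$value),
               source_note_id = a$source_note_id,
               source_note_date = parse_note_date(a$source_note_date, ln),
               day_distance = as.integer(a$day_distance))
      }))
    tibble(patient_id = rec$patient_id,
           index_date = parse_note_date(rec$index_date, ln),
           assignments = list(asg), missing = isTRUE(rec$missing))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(patient_id = character(), index_date = as.Date(character()),
                  assignments = list(), missing = logical())
  }
  new_mm_tbl(out, "mm_patient_stage")
}

#' Read per-patient index dates
#'
#' @param path JSONL file with one `{patient_id, index_date}` object per line.
#' @return Tibble with `patient_id` and `index_date` (`Date`).
#' @export
read_index_dates <- function(path) {
  x <- read_jsonl_records(path)
  rows <- map2(x$recs, x$lines, function(rec, ln) {
    required_fields(rec, c("patient_id", "index_date"), ln, path)
    tibble(patient_id = as.character(rec$patient_id),
           index_date = parse_note_date(rec$index_date, ln))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- tibble(patient_id = character(), index_date = as.Date(character()))
  out
}

#' @export
write_records.data.frame <- function(records, path) {
  # index-date tables are plain tibbles
  if (identical(sort(names(records)), c("index_date", "patient_id"))) {
    return(write_jsonl(lapply(seq_len(nrow(records)), function(i) {
      list(patient_id = records$patient_id[i],
           index_date = format(records$index_date[i], "%Y-%m-%d"))
    }), path))
  }
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_prediction_labels <- function() {
  tibble(system = character(), value = integer(),
         value_start = integer(), value_end = integer(),
         system_start = integer(), system_end = integer())
}

empty_assignments <- function() {
  tibble(system = character(), value = integer(), source_note_id = character(),
         source_note_date = as.Date(character()), day_distance = integer())
}

empty_snippets <- function() {
  tibble(snippet_id = character(), note_id = character(), patient_id = character(),
         note_date = as.Date(character()), note_type = character(),
         window_start = integer(), window_end = integer(), text = character(),
         trigger_start = integer(), trigger_end = integer(), trigger_text = character())
}
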