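# Patient-level roll-up: aggregate snippet-level stage labels into one
# per-system stage assignment at the treatment-initiation index date, using a
# note-type filter and a +/- 1-year window around the index date.

#' Roll-up configuration
#'
#' @param window_days Half-width of the note-date window around the index
#'   date, in days, applied both before and after (default 365; endpoints
#'   inclusive).
#' @param eligible_note_types Note types whose snippets may contribute
#'   (default hematology/oncology notes and pathology reports).
#' @param tie_break How to break a tie when two notes are equidistant from
#'   the index date: `"PREFER_ON_OR_BEFORE"` (default; initial staging
#'   usually precedes treatment) or `"PREFER_AFTER"`.
#' @return A list of class `rollup_config`.
#' @export
rollup_config <- function(window_days = 365L,
                          eligible_note_types = c("HEM_ONC", "PATHOLOGY"),
                          tie_break = c("PREFER_ON_OR_BEFORE", "PREFER_AFTER")) {
  tie_break <- match.arg(tie_break)
  stopifnot(window_days > 0, length(eligible_note_types) > 0)
  structure(list(window_days = as.integer(window_days),
                 eligible_note_types = as.character(eligible_note_types),
                 tie_break = tie_break),
            class = "rollup_config")
}

#' Filter one patient's notes for the roll-up
#'
#' Keeps notes whose type is eligible and whose date lies within
#' `window_days` of the index date (inclusive on both endpoints).
#'
#' @param notes `mm_notes` tibble, all belonging to one patient.
#' @param index_date The patient's treatment-initiation date.
#' @param config A [rollup_config()].
#' @return The filtered `mm_notes` tibble.
#' @export
select_notes <- function(notes, index_date, config = rollup_config()) {
  dd <- abs(as.integer(notes$note_date - as.Date(index_date)))
  keep <- notes$note_type %in% config$eligible_note_types & dd <= config$window_days
  notes[keep, , drop = FALSE]
}

# Flatten a predictions tibble into one row per (snippet, label).
flatten_labels <- function(predictions) {
  rows <- lapply(seq_len(nrow(predictions)), function(i) {
    lab <- predictions$labels[[i]]
    if (is.null(lab) || nrow(lab) == 0) return(NULL)
    tibble(snippet_id = predictions$snippet_id[i],
           note_id = predictions$note_id[i],
           note_date = predictions$note_date[i],
           system = lab$system, value = lab$value,
           value_start = if ("value_start" %in% names(lab)) lab$value_start else NA_integer_)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(snippet_id = character(), note_id = character(),
                  note_date = as.Date(character()), system = character(),
                  value = integer(), value_start = integer())
  }
  out
}

#' Roll snippet predictions up to one patient-level stage record
#'
#' Independently for each staging system (R-ISS, ISS, DS, unclear stage):
#' locate the note closest in days to the index date among notes whose
#' snippets carry a label for that system, and assign that note's value for
#' the system. Equidistant notes break per the config (default: the note on
#' or before the index date wins), then by earlier `note_id`; if the chosen
#' note carries two different values for the system, the label whose value
#' span starts earliest in the earliest snippet wins. A system with no
#' labeled snippet gets no assignment; a patient with no labels at all is
#' recorded as missing.
#'
#' @param predictions `mm_predictions` tibble for one patient, carrying
#'   `note_id`, `note_date` and `note_type`; all predictions must come from
#'   notes that pass [select_notes()] (anything else is a contract error).
#' @param index_date The patient's treatment-initiation date.
#' @param config A [rollup_config()].
#' @param patient_id Optional patient id recorded in the output.
#' @return One-row `mm_patient_stage` tibble with an `assignments`
#'   list-column (`system`, `value`, `source_note_id`, `source_note_date`,
#'   `day_distance`) and a `missing` flag.
#' @export
rollup_patient_stage <- function(predictions, index_date,
                                 config = rollup_config(),
                                 patient_id = NA_character_) {
  index_date <- as.Date(index_date)
  if (nrow(predictions) > 0) {
    dd <- abs(as.integer(predictions$note_date - index_date))
    bad_window <- dd > config$window_days
    bad_type <- if ("note_type" %in% names(predictions)) {
      !predictions$note_type %in% config$eligible_note_types
    } else FALSE
    if (any(bad_window | bad_type)) {
      abort("predictions include notes outside the roll-up filter; apply select_notes() first")
    }
  }
  flat <- flatten_labels(predictions)
  if (is.na(patient_id) && nrow(predictions) > 0 && "patient_id" %in% names(predictions)) {
    patient_id <- predictions$patient_id[1]
  }
  assignments <- list()
  for (sys in STAGING_SYSTEMS) {
    rows <- flat[flat$system == sys, , drop = FALSE]
    if (nrow(rows) == 0) next
    rows$day_distance <- abs(as.integer(rows$note_date - index_date))
    before_rank <- if (config$tie_break == "PREFER_ON_OR_BEFORE") {
      ifelse(rows$note_date <= index_date, 0L, 1L)
    } else {
      ifelse(rows$note_date > index_date, 0L, 1L)
    }
    ord <- order(rows$day_distance, before_rank, rows$note_id)
    chosen_note <- rows$note_id[ord[1]]
    in_note <- rows[rows$note_id == chosen_note, , drop = FALSE]
    pick <- in_note[order(in_note$snippet_id, in_note$value_start, in_note$value), ][1, ]
    assignments[[sys]] <- tibble(system = sys, value = pick$value,
                                 source_note_id = pick$note_id,
                                 source_note_date = pick$note_date,
                                 day_distance = pick$day_distance)
  }
  asg <- bind_rows(assignments)
  if (nrow(asg) == 0) asg <- empty_assignments()
  new_mm_tbl(tibble(patient_id = patient_id, index_date = index_date,
                    assignments = list(asg), missing = nrow(asg) == 0),
             "mm_patient_stage")
}

#' Roll up a whole corpus of predictions
#'
#' Joins predictions to note metadata, applies the note-type and window
#' filters per patient, and produces one stage record per patient in
#' `index_dates` (patients with no eligible stage-bearing snippet come out
#' missing).
#'
#' @param predictions `mm_predictions` tibble (any patients).
#' @param notes `mm_notes` tibble supplying `note_date`/`note_type`/
#'   `patient_id` for each `note_id`.
#' @param index_dates Tibble with `patient_id` and `index_date`.
#' @param config A [rollup_config()].
#' @return A `mm_patient_stage` tibble, one row per patient in
#'   `index_dates` order.
#' @export
rollup_patients <- function(predictions, notes, index_dates,
                            config = rollup_config()) {
  meta <- notes[, c("note_id", "patient_id", "note_date", "note_type")]
  preds <- predictions
  preds$patient_id <- NULL; preds$note_date <- NULL; preds$note_type <- NULL
  preds <- left_join(preds, meta, by = "note_id")
  rows <- lapply(seq_len(nrow(index_dates)), function(i) {
    pid <- index_dates$patient_id[i]
    idx <- index_dates$index_date[i]
    p <- preds[!is.na(preds$patient_id) & preds$patient_id == pid, , drop = FALSE]
    dd <- abs(as.integer(p$note_date - idx))
    p <- p[p$note_type %in% config$eligible_note_types & dd <= config$window_days, , drop = FALSE]
    rollup_patient_stage(p, idx, config, patient_id = pid)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(patient_id = character(), index_date = as.Date(character()),
                  assignments = list(), missing = logical())
  }
  new_mm_tbl(out, "mm_patient_stage")
}

#' Collapse a stage record to one preferred system
#'
#' Optional post-processing for downstream analyses that want a single stage
#' per patient under a staging-system hierarchy (for example prefer R-ISS,
#' then ISS, then DS).
#'
#' @param records `mm_patient_stage` tibble.
#' @param prefer Character vector of systems in preference order.
#' @return Tibble with `patient_id`, `system`, `value` (`NA` when no
#'   preferred system has an assignment).
#' @export
apply_stage_preference <- function(records, prefer = c("RISS", "ISS", "DS")) {
  stopifnot(all(prefer %in% STAGING_SYSTEMS))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    asg <- records$assignments[[i]]
    hit <- prefer[prefer %in% asg$system]
    if (length(hit) == 0) {
      tibble(patient_id = records$patient_id[i], system = NA_character_,
             value = NA_integer_)
    } else {
      j <- which(asg$system == hit[1])
      tibble(patient_id = records$patient_id[i], system = hit[1],
             value = asg$value[j])
    }
  })
  bind_rows(rows)
}
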