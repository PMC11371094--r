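# Seeded synthetic corpus generator. Emulates oncology-note text with staging
# sentences in many surface forms, distractor sentences (CKD stage,
# other-cancer stage, antibiotic "DS"), and neutral filler prose, together
# with internally consistent gold at the mention and patient level. Gold is
# always computed from the generation slots, never by running the extractor.

#' Synthetic corpus configuration
#'
#' Defaults describe the study conditions the generator emulates: 200
#' patients (the size of the annotated patient-level set), a handful of
#' notes per patient spread around the treatment-initiation date (some
#' outside the 1-year roll-up window, some of ineligible type), about a
#' third of notes carrying a true staging sentence, all four systems
#' represented, and a realistic sprinkling of distractors.
#'
#' @param seed Integer seed; the same config is byte-identical across runs.
#' @param n_patients Number of patients.
#' @param notes_per_patient Integer range `c(min, max)` of notes per patient.
#' @param p_stage_mention Probability a note carries a true staging sentence.
#' @param system_mix Named distribution over RISS/ISS/DS/UNCLEAR for staging
#'   sentences.
#' @param value_mix Distribution over stages 1/2/3.
#' @param p_distractor Probability of injecting a distractor sentence.
#' @param p_multi_label Probability a staging sentence names two systems.
#' @param index_window_days Note dates are drawn uniformly within this many
#'   days of the index date (wider than the 365-day roll-up window, so the
#'   window filter is exercised).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_patients = 200L,
                             notes_per_patient = c(3L, 10L),
                             p_stage_mention = 0.35,
                             system_mix = c(RISS = 0.25, ISS = 0.35, DS = 0.2, UNCLEAR = 0.2),
                             value_mix = c(0.3, 0.4, 0.3),
                             p_distractor = 0.25,
                             p_multi_label = 0.1,
                             index_window_days = 550L) {
  stopifnot(n_patients >= 0, length(notes_per_patient) == 2,
            notes_per_patient[1] >= 1,
            notes_per_patient[2] >= notes_per_patient[1],
            all(c(p_stage_mention, p_distractor, p_multi_label) >= 0),
            all(c(p_stage_mention, p_distractor, p_multi_label) <= 1),
            abs(sum(system_mix) - 1) < 1e-8, abs(sum(value_mix) - 1) < 1e-8,
            setequal(names(system_mix), STAGING_SYSTEMS))
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 notes_per_patient = as.integer(notes_per_patient),
                 p_stage_mention = p_stage_mention,
                 system_mix = system_mix[STAGING_SYSTEMS],
                 value_mix = value_mix,
                 p_distractor = p_distractor, p_multi_label = p_multi_label,
                 index_window_days = as.integer(index_window_days)),
            class = "generator_config")
}

# Neutral clinical filler; none of these sentences contains a trigger, a
# numeral 1-3, or any lexicon term of the rule set.
filler_sentences <- function() {
  c("Vital signs reviewed and within normal limits.",
    "Patient ambulating without assistance.",
    "Medication adherence reviewed in detail.",
    "No fevers, chills, or night sweats reported.",
    "Appetite remains good and weight is steady.",
    "Laboratory results reviewed with the patient.",
    "Follow-up appointment scheduled with the clinic.",
    "Family present and questions were answered.",
    "Physical exam unremarkable on today's evaluation.",
    "Patient reports improved energy since the last visit.",
    "Plan reviewed and agreed upon with the care team.",
    "Sleep quality reported as adequate overall.",
    "Denies chest pain, shortness of breath, or palpitations.",
    "Immunizations reviewed and found current.",
    "Counseled regarding diet and regular exercise.",
    "Neurologic examination grossly intact throughout.",
    "Skin warm and dry without lesions noted.",
    "Continues home medications without reported side effects.",
    "Social support at home remains adequate.",
    "Will continue close monitoring going forward.",
    "Reviewed prior imaging with the patient today.",
    "Pain well controlled on the current regimen.",
    "Mood and affect appropriate during the encounter.",
    "Hydration encouraged and tolerated well.")
}

sample_prob <- function(x, prob) x[sample.int(length(x), 1, prob = prob)]

# One staging sentence drawn from the clear/unclear/multi templates under the
# configured mixes. Returns text plus slot-derived gold.
sample_staging_sentence <- function(config) {
  multi <- stats::runif(1) < config$p_multi_label
  if (multi) {
    named <- c("RISS", "ISS", "DS")
    sys <- sample(named, 2)
    vals <- sample(1:3, 2, replace = TRUE)
    return(render_template("m1", system = sys[1], value = vals[1],
                           system2 = sys[2], value2 = vals[2]))
  }
  sys <- sample_prob(STAGING_SYSTEMS, config$system_mix)
  val <- sample_prob(1:3, config$value_mix)
  if (sys == "UNCLEAR") {
    render_template(sample(paste0("u", 1:4), 1), value = val)
  } else {
    render_template(sample(paste0("c", 1:8), 1), system = sys, value = val)
  }
}

sample_distractor_sentence <- function() {
  tid <- sample(c(paste0("d", 1:9), paste0("n", 5:6)), 1)
  tpl <- stage_templates()
  tpl <- tpl[tpl$template_id == tid, ]
  if (grepl("{VAL}", tpl$text, fixed = TRUE)) {
    render_template(tpl, value = sample(1:3, 1),
                    num_form = if (tid == "d5") "roman" else NULL)
  } else {
    render_template(tpl)
  }
}

#' Generate one synthetic patient history
#'
#' Draws an index date, a set of dated, typed notes around it (note types
#' mixed over HEM_ONC/PATHOLOGY/OTHER; dates spread wider than the roll-up
#' window), staging and distractor sentences embedded in filler prose, and
#' returns internally consistent gold at both levels: mention-level label
#' sets with note provenance, and the patient-level stage derived from those
#' mentions by brute-force day-distance minimization under the roll-up tie
#' rules. Distractor sentences are kept at least two filler sentences away
#' from staging sentences so mention gold stays unambiguous.
#'
#' Uses the session RNG: seed it (or call via [generate_corpus()]) for
#' reproducibility.
#'
#' @param config A [generator_config()].
#' @param patient_id Patient identifier.
#' @param rollup A [rollup_config()] defining the patient-gold semantics.
#' @return List with `notes` (`mm_notes`), `mention_gold`
#'   (`mm_predictions`-shaped, one row per staging sentence), `patient_gold`
#'   (one-row `mm_patient_gold`), and `index_date`.
#' @export
generate_patient_history <- function(config = generator_config(),
                                     patient_id = "p0001",
                                     rollup = rollup_config()) {
  filler <- filler_sentences()
  index_date <- as.Date("2008-01-01") + sample.int(3000L, 1)
  n_notes <- sample(seq(config$notes_per_patient[1], config$notes_per_patient[2]), 1)
  notes <- list()
  mentions <- list()
  for (j in seq_len(n_notes)) {
    note_id <- sprintf("%s_n%03d", patient_id, j)
    note_date <- index_date + sample.int(2L * config$index_window_days + 1L, 1) -
      config$index_window_days - 1L
    note_type <- sample_prob(NOTE_TYPES, c(0.6, 0.15, 0.25))
    has_stage <- stats::runif(1) < config$p_stage_mention
    has_distractor <- stats::runif(1) < config$p_distractor
    sentences <- sample(filler, sample(2:4, 1))
    stage_sent <- if (has_stage) sample_staging_sentence(config) else NULL
    distract_sent <- if (has_distractor) sample_distractor_sentence() else NULL
    parts <- sentences[1]
    stage_offset <- NA_integer_
    if (!is.null(stage_sent)) {
      stage_offset <- nchar(paste(c(parts, ""), collapse = " "))
      parts <- c(parts, paste0(stage_sent$text, "."))
    }
    if (!is.null(distract_sent)) {
      # >= 2 filler sentences between a staging and a distractor sentence
      parts <- c(parts, sample(filler, 2), paste0(distract_sent$text, "."))
    }
    parts <- c(parts, sentences[-1])
    text <- paste(parts, collapse = " ")
    notes[[j]] <- tibble(note_id = note_id, patient_id = patient_id,
                         note_date = note_date, note_type = note_type, text = text)
    if (!is.null(stage_sent)) {
      mentions[[length(mentions) + 1L]] <- tibble(
        snippet_id = sprintf("%s:m%04d", note_id, stage_offset),
        note_id = note_id, patient_id = patient_id,
        note_date = note_date, note_type = note_type,
        labels = list(mutate(stage_sent$gold,
                             value_start = stage_offset, value_end = NA_integer_,
                             system_start = NA_integer_, system_end = NA_integer_)))
    }
  }
  notes <- new_mm_tbl(bind_rows(notes), "mm_notes")
  mention_gold <- if (length(mentions) == 0) {
    tibble(snippet_id = character(), note_id = character(),
           patient_id = character(), note_date = as.Date(character()),
           note_type = character(), labels = list())
  } else bind_rows(mentions)
  mention_gold <- new_mm_tbl(mention_gold, "mm_predictions")
  per_system <- brute_force_patient_stage(mention_gold, index_date, rollup)
  no_stage <- length(per_system) == 0
  patient_gold <- new_mm_tbl(
    tibble(patient_id = patient_id, index_date = index_date,
           per_system = list(per_system), missing = no_stage),
    "mm_patient_gold")
  list(notes = notes, mention_gold = mention_gold, patient_gold = patient_gold,
       index_date = index_date)
}

# Independent brute-force reference for the patient-level stage: enumerate
# every (system, labeled mention) pair, restrict to eligible note types and
# the day window, and minimize day distance under the documented tie rules.
# Deliberately written as a flat search, separate from rollup_patient_stage().
brute_force_patient_stage <- function(mention_gold, index_date, rollup = rollup_config()) {
  best <- stats::setNames(integer(), character())
  for (sys in STAGING_SYSTEMS) {
    best_key <- NULL
    best_val <- NA_integer_
    for (i in seq_len(nrow(mention_gold))) {
      if (!mention_gold$note_type[i] %in% rollup$eligible_note_types) next
      dd <- abs(as.integer(mention_gold$note_date[i] - index_date))
      if (dd > rollup$window_days) next
      lab <- mention_gold$labels[[i]]
      rows <- which(lab$system == sys)
      for (r in rows) {
        on_or_before <- as.integer(mention_gold$note_date[i] > index_date)
        if (rollup$tie_break == "PREFER_AFTER") on_or_before <- 1L - on_or_before
        vs <- if ("value_start" %in% names(lab)) lab$value_start[r] else 0L
        key <- list(dd, on_or_before, mention_gold$note_id[i],
                    mention_gold$snippet_id[i], vs, lab$value[r])
        if (is.null(best_key) || key_less(key, best_key)) {
          best_key <- key
          best_val <- lab$value[r]
        }
      }
    }
    if (!is.null(best_key)) best[sys] <- best_val
  }
  best
}

key_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (is.na(a[[k]]) || is.na(b[[k]])) next
    if (a[[k]] < b[[k]]) return(TRUE)
    if (a[[k]] > b[[k]]) return(FALSE)
  }
  FALSE
}

#' Generate a full synthetic corpus on disk
#'
#' Fully seeded and reproducible: the same config produces byte-identical
#' files. Writes `notes.jsonl`, `snippet_gold.jsonl` (mention-level gold with
#' note provenance), `patient_gold.jsonl`, and `index_dates.jsonl` in the
#' corpus_io schemas.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @param rollup A [rollup_config()] defining the patient-gold semantics.
#' @return Invisibly, a list with the four file paths and the in-memory
#'   `notes`, `mention_gold`, `patient_gold`, `index_dates` objects.
#' @export
generate_corpus <- function(config = generator_config(), out_dir,
                            rollup = rollup_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- withr::with_seed(config$seed, {
    pats <- lapply(seq_len(config$n_patients), function(i) {
      generate_patient_history(config, sprintf("p%04d", i), rollup)
    })
    pats
  })
  notes <- if (length(sim) == 0) {
    new_mm_tbl(tibble(note_id = character(), patient_id = character(),
                      note_date = as.Date(character()), note_type = character(),
                      text = character()), "mm_notes")
  } else new_mm_tbl(bind_rows(lapply(sim, `[[`, "notes")), "mm_notes")
  mention_gold <- if (length(sim) == 0) {
    new_mm_tbl(tibble(snippet_id = character(), note_id = character(),
                      patient_id = character(), note_date = as.Date(character()),
                      note_type = character(), labels = list()), "mm_predictions")
  } else new_mm_tbl(bind_rows(lapply(sim, `[[`, "mention_gold")), "mm_predictions")
  patient_gold <- if (length(sim) == 0) {
    new_mm_tbl(tibble(patient_id = character(), index_date = as.Date(character()),
                      per_system = list(), missing = logical()), "mm_patient_gold")
  } else new_mm_tbl(bind_rows(lapply(sim, `[[`, "patient_gold")), "mm_patient_gold")
  index_dates <- tibble(patient_id = patient_gold$patient_id,
                        index_date = patient_gold$index_date)
  paths <- list(notes = file.path(out_dir, "notes.jsonl"),
                snippet_gold = file.path(out_dir, "snippet_gold.jsonl"),
                patient_gold = file.path(out_dir, "patient_gold.jsonl"),
                index_dates = file.path(out_dir, "index_dates.jsonl"))
  write_records(notes, paths$notes)
  write_records(mention_gold, paths$snippet_gold)
  write_records(patient_gold, paths$patient_gold)
  write_records(index_dates, paths$index_dates)
  invisible(list(paths = paths, notes = notes, mention_gold = mention_gold,
                 patient_gold = patient_gold, index_dates = index_dates))
}
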