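# Shared fixtures and independent oracles. Oracles are deliberately naive
# re-implementations (exhaustive scans, flat searches) kept separate from the
# package's code paths.

make_note <- function(note_id = "n1", patient_id = "p1",
                      note_date = as.Date("2015-06-01"),
                      note_type = "HEM_ONC", text = "") {
  structure(tibble::tibble(note_id = note_id, patient_id = patient_id,
                           note_date = note_date, note_type = note_type,
                           text = text),
            class = c("mm_notes", class(tibble::tibble())))
}

label_key <- function(labels) {
  if (is.null(labels) || nrow(labels) == 0) return("")
  paste(sort(paste(labels$system, labels$value)), collapse = ";")
}

# Oracle for candidate detection: test every substring of the text against
# every trigger pattern in full, then apply leftmost-longest greedily. The
# default triggers all begin and end on a word boundary, so the boundary is
# checked by hand against the characters surrounding the substring.
oracle_candidates <- function(text, patterns) {
  n <- nchar(text)
  is_word <- function(ch) grepl("[A-Za-z0-9_]", ch)
  hits <- list()
  for (i in seq_len(n)) {
    if (i > 1 && is_word(substring(text, i - 1, i - 1))) next
    for (j in i:n) {
      if (j < n && is_word(substring(text, j + 1, j + 1))) next
      sub <- substring(text, i, j)
      for (p in patterns) {
        if (grepl(paste0("^(?:", p, ")$"), sub, perl = TRUE, ignore.case = TRUE)) {
          hits[[length(hits) + 1]] <- c(start = i - 1L, end = j)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  h <- unique(do.call(rbind, hits))
  h <- h[order(h[, "start"], -h[, "end"]), , drop = FALSE]
  kept <- NULL
  last_end <- -1L
  for (r in seq_len(nrow(h))) {
    if (h[r, "start"] >= last_end) {
      kept <- rbind(kept, h[r, , drop = FALSE])
      last_end <- h[r, "end"]
    }
  }
  tibble::tibble(start = as.integer(kept[, "start"]), end = as.integer(kept[, "end"]))
}

# Oracle for same-category overlap resolution: repeatedly discard any span
# that overlaps a surviving same-category span of strictly better
# (priority, start, -length) order.
oracle_resolve_overlaps <- function(spans) {
  if (nrow(spans) < 2) return(spans)
  better <- function(i, j) { # is i better than j
    ki <- c(spans$rule_priority[i], spans$start[i], -(spans$end[i] - spans$start[i]))
    kj <- c(spans$rule_priority[j], spans$start[j], -(spans$end[j] - spans$start[j]))
    d <- ki - kj
    nz <- which(d != 0)
    length(nz) > 0 && d[nz[1]] < 0
  }
  ord <- order(spans$rule_priority, spans$start, -(spans$end - spans$start))
  alive <- logical(nrow(spans))
  for (i in ord) {
    clash <- FALSE
    for (j in which(alive)) {
      if (spans$category[j] == spans$category[i] &&
          spans$start[i] < spans$end[j] && spans$start[j] < spans$end[i] &&
          better(j, i)) clash <- TRUE
    }
    alive[i] <- !clash
  }
  out <- spans[alive, , drop = FALSE]
  out[order(out$start, out$end), ]
}

# Oracle for the patient-level roll-up: flat exhaustive search over every
# (system, label occurrence) pair with explicit lexicographic keys.
oracle_patient_assignments <- function(predictions, index_date,
                                       config = rollup_config()) {
  rows <- list()
  for (i in seq_len(nrow(predictions))) {
    lab <- predictions$labels[[i]]
    if (is.null(lab) || nrow(lab) == 0) next
    for (r in seq_len(nrow(lab))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        system = lab$system[r], value = lab$value[r],
        note_id = predictions$note_id[i],
        note_date = predictions$note_date[i],
        snippet_id = predictions$snippet_id[i],
        value_start = if ("value_start" %in% names(lab)) lab$value_start[r] else 0L)
    }
  }
  out <- list()
  if (length(rows) > 0) {
    flat <- do.call(rbind, rows)
    flat$dd <- abs(as.integer(flat$note_date - as.Date(index_date)))
    flat$after <- as.integer(flat$note_date > as.Date(index_date))
    if (config$tie_break == "PREFER_AFTER") flat$after <- 1L - flat$after
    for (sys in staging_systems()) {
      f <- flat[flat$system == sys, , drop = FALSE]
      if (nrow(f) == 0) next
      f <- f[order(f$dd, f$after, f$note_id, f$snippet_id, f$value_start, f$value), ]
      out[[sys]] <- f$value[1]
    }
  }
  unlist(out)
}

assignments_as_vector <- function(record_row) {
  asg <- record_row$assignments[[1]]
  stats::setNames(asg$value, asg$system)
}

same_named_vector <- function(a, b) {
  length(a) == length(b) && setequal(names(a), names(b)) &&
    all(a[names(b)] == b)
}
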