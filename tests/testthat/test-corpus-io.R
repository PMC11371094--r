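test_that("notes read from JSONL in file order, with parsed dates", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"note_id":"a","patient_id":"p1","note_date":"2015-06-01","note_type":"HEM_ONC","text":"line one\\nline two"}',
    '{"note_id":"b","patient_id":"p2","note_date":"2016-01-31","note_type":"PATHOLOGY","text":""}'
  ), path)
  notes <- read_notes(path)
  expect_s3_class(notes, "mm_notes")
  expect_equal(nrow(notes), 2)
  expect_equal(notes$note_id, c("a", "b"))
  expect_equal(notes$note_date, as.Date(c("2015-06-01", "2016-01-31")))
  expect_match(notes$text[1], "\n")
})

test_that("empty file yields an empty collection", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  file.create(path)
  expect_equal(nrow(read_notes(path)), 0)
})

test_that("a record lacking note_date errors naming the line", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"note_id":"a","patient_id":"p1","note_date":"2015-06-01","note_type":"OTHER","text":"x"}',
    '{"note_id":"b","patient_id":"p1","note_type":"OTHER","text":"y"}'
  ), path)
  expect_error(read_notes(path), "line 2")
  writeLines('{"note_id":"a","patient_id":"p1","note_date":"06/01/2015","note_type":"OTHER","text":"x"}', path)
  expect_error(read_notes(path), "line 1")
})

test_that("unknown note types map to OTHER with a warning; config map applies", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"note_id":"a","patient_id":"p1","note_date":"2015-06-01","note_type":"HEMATOLOGY/ONCOLOGY NOTE","text":"x"}',
    '{"note_id":"b","patient_id":"p1","note_date":"2015-06-02","note_type":"TELEPHONE NOTE","text":"y"}'
  ), path)
  expect_warning(notes <- read_notes(path), "TELEPHONE")
  expect_equal(notes$note_type, c("OTHER", "OTHER"))
  notes <- suppressWarnings(read_notes(
    path, note_type_map = c("HEMATOLOGY/ONCOLOGY NOTE" = "HEM_ONC")))
  expect_equal(notes$note_type[1], "HEM_ONC")
})

test_that("notes read from CSV too, and duplicate note ids are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(note_id = c("a", "b"), patient_id = "p1",
                              note_date = "2015-06-01", note_type = "HEM_ONC",
                              text = c("multi\nline", "plain")),
                   path, row.names = FALSE)
  notes <- read_notes(path)
  expect_equal(nrow(notes), 2)
  expect_match(notes$text[1], "\n")
  dup <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(rep('{"note_id":"a","patient_id":"p1","note_date":"2015-06-01","note_type":"OTHER","text":"x"}', 2), dup)
  expect_error(read_notes(dup), "duplicate")
})

test_that("snippet annotations parse labels, including empty = not stage", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"snippet_id":"s1","labels":[{"system":"ISS","value":3}]}',
    '{"snippet_id":"s2","labels":[]}',
    '{"snippet_id":"s3","labels":[{"system":"R-ISS","value":2},{"system":"DS","value":1}]}'
  ), path)
  ann <- read_annotations(path, "snippet")
  expect_equal(ann$labels[[1]], stage_labels("ISS", 3))
  expect_equal(nrow(ann$labels[[2]]), 0)
  expect_setequal(ann$labels[[3]]$system, c("RISS", "DS"))
  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"snippet_id":"s1","labels":[{"system":"TNM","value":2}]}', bad)
  expect_error(read_annotations(bad, "snippet"), "unknown staging system")
})

test_that("patient annotations respect the missing invariant", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"patient_id":"p1","index_date":"2012-03-04","per_system":{"ISS":2,"UNCLEAR":3}}',
    '{"patient_id":"p2","index_date":"2013-05-06","per_system":{}}'
  ), path)
  ann <- read_annotations(path, "patient")
  expect_false(ann$missing[1])
  expect_true(ann$missing[2])
  expect_equal(ann$per_system[[1]][["ISS"]], 2L)
  expect_equal(length(ann$per_system[[2]]), 0)
})

test_that("every container round-trips through JSONL identically", {
  dir <- withr::local_tempdir()
  notes <- make_note(c("a", "b", "c"), "p1", as.Date("2015-06-01") + 0:2,
                     c("HEM_ONC", "PATHOLOGY", "OTHER"),
                     c("first note", "second\nnote", ""))
  p <- file.path(dir, "notes.jsonl")
  write_records(notes, p)
  expect_equal(as.data.frame(read_notes(p)), as.data.frame(notes))

  gold <- structure(tibble::tibble(
    snippet_id = c("s1", "s2"),
    labels = list(stage_labels(c("ISS", "RISS"), c(3, 2)), stage_labels())),
    class = c("mm_snippet_gold", class(tibble::tibble())))
  p <- file.path(dir, "gold.jsonl")
  write_records(gold, p)
  back <- read_annotations(p, "snippet")
  expect_equal(label_key(back$labels[[1]]), label_key(gold$labels[[1]]))
  expect_equal(nrow(back$labels[[2]]), 0)

  pg <- structure(tibble::tibble(
    patient_id = c("p1", "p2"), index_date = as.Date(c("2012-03-04", "2013-05-06")),
    per_system = list(c(ISS = 2L, DS = 3L), stats::setNames(integer(), character())),
    missing = c(FALSE, TRUE)),
    class = c("mm_patient_gold", class(tibble::tibble())))
  p <- file.path(dir, "patient_gold.jsonl")
  write_records(pg, p)
  back <- read_annotations(p, "patient")
  expect_equal(back$per_system[[1]][c("ISS", "DS")], pg$per_system[[1]])
  expect_equal(back$missing, pg$missing)

  idx <- tibble::tibble(patient_id = c("p1", "p2"),
                        index_date = as.Date(c("2012-03-04", "2013-05-06")))
  p <- file.path(dir, "index.jsonl")
  write_records(idx, p)
  expect_equal(read_index_dates(p), idx)
})

test_that("snippets and predictions round-trip with provenance", {
  dir <- withr::local_tempdir()
  note <- make_note(text = paste0(strrep("x ", 60), "ISS stage III. ", strrep("y ", 110)))
  sn <- snippets_from_corpus(note)
  p <- file.path(dir, "snippets.jsonl")
  write_records(sn, p)
  back <- read_snippets(p)
  expect_equal(as.data.frame(back), as.data.frame(sn))

  pred <- extract_snippets(sn, stage_ruleset())
  p <- file.path(dir, "pred.jsonl")
  write_records(pred, p)
  back <- read_predictions(p)
  expect_equal(back$snippet_id, pred$snippet_id)
  expect_equal(back$labels[[1]]$system, pred$labels[[1]]$system)
  expect_equal(back$labels[[1]]$value_start, pred$labels[[1]]$value_start)
})

test_that("writing to an unwritable path errors naming the path", {
  notes <- make_note()
  expect_error(write_records(notes, "/nonexistent-dir-xyz/notes.jsonl"),
               "nonexistent-dir-xyz")
})
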