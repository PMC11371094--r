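rules <- stage_ruleset()

test_that("stage values normalize with subclass stripping and rejection", {
  expect_equal(normalize_stage_value(c("III", "2", "IIIA", "iiib", "1A", "i"), rules),
               c(3L, 2L, 3L, 3L, 1L, 1L))
  expect_true(is.na(normalize_stage_value("IV", rules)))
  expect_true(is.na(normalize_stage_value("4", rules)))
  expect_true(is.na(normalize_stage_value("IIIC", rules)))
})

test_that("system names normalize across spelling variants", {
  expect_equal(
    normalize_system_name(c("International Staging System", "R-ISS", "RISS",
                            "Revised ISS", "Durie-Salmon", "Durie Salmon",
                            "Durie/Salmon", "D-S", "ds", "iss"), rules),
    c("ISS", "RISS", "RISS", "RISS", "DS", "DS", "DS", "DS", "DS", "ISS"))
  expect_error(normalize_system_name("TNM", rules), "normalization map")
})

test_that("span labeling finds values, systems, diseases and antibiotics", {
  sp <- label_spans("ISS stage III", rules)
  expect_setequal(sp$category, c("STAGING_SYSTEM", "STAGE_VALUE"))
  sys <- sp[sp$category == "STAGING_SYSTEM", ]
  expect_equal(sys$normalized, "ISS")
  expect_equal(sys$raw, "ISS")

  sp <- label_spans("CKD stage 3", rules)
  expect_true(any(sp$category == "OTHER_DISEASE"))
  expect_true(any(sp$category == "STAGE_VALUE" & sp$raw == "3"))

  sp <- label_spans("on Bactrim DS bid, myeloma stable", rules)
  expect_true(any(sp$category == "ANTIBIOTIC"))
  expect_true(any(sp$category == "MM_MENTION"))

  expect_equal(nrow(label_spans("", rules)), 0)
  # raw always equals the text slice
  tx <- "multiple myeloma, R-ISS stage II-III per report"
  sp <- label_spans(tx, rules)
  expect_equal(sp$raw, substring(tx, sp$start + 1, sp$end))
})

test_that("overlap resolution keeps the earliest rule, matching the oracle", {
  spans <- tibble::tibble(
    category = c("STAGE_VALUE", "STAGE_VALUE", "STAGING_SYSTEM"),
    start = c(10L, 10L, 9L), end = c(13L, 13L, 14L),
    raw = c("III", "III", "x"), normalized = c("3", "3", "ISS"),
    values = list(3L, 3L, integer()),
    rule_id = c("r2", "r5", "s1"), rule_priority = c(2L, 5L, 7L),
    anchored = FALSE, bare = FALSE)
  out <- resolve_overlaps(spans)
  expect_equal(sort(out$rule_id), c("r2", "s1")) # cross-category kept

  # R-ISS vs inner ISS on real text
  sp <- resolve_overlaps(label_spans("R-ISS stage II", rules))
  sys <- sp[sp$category == "STAGING_SYSTEM", ]
  expect_equal(nrow(sys), 1)
  expect_equal(sys$normalized, "RISS")

  # property: agreement with the exhaustive pairwise oracle on random spans
  withr::with_seed(11, {
    for (rep in 1:25) {
      n <- sample(2:8, 1)
      start <- sample(0:30, n, replace = TRUE)
      spans <- tibble::tibble(
        category = sample(c("STAGE_VALUE", "STAGING_SYSTEM"), n, replace = TRUE),
        start = as.integer(start), end = as.integer(start + sample(1:6, n, replace = TRUE)),
        raw = "x", normalized = "y", values = replicate(n, integer(), simplify = FALSE),
        rule_id = paste0("r", 1:n), rule_priority = sample(1:10, n),
        anchored = FALSE, bare = FALSE)
      expect_equal(resolve_overlaps(spans)$rule_id,
                   oracle_resolve_overlaps(spans)$rule_id)
    }
  })
})

test_that("non-MM context suppresses stage values and bare DS", {
  expect_equal(nrow(extract_stage_text("CKD stage III", rules)), 0)
  expect_equal(nrow(extract_stage_text("Bactrim DS bid", rules)), 0)
  expect_equal(label_key(extract_stage_text("ISS stage III", rules)), "ISS 3")
  # bare DS without MM or value support is not a staging system
  expect_equal(nrow(extract_stage_text("patient discharged, DS discussed", rules)), 0)
})

test_that("association follows proximity, direction and connectives", {
  expect_equal(label_key(extract_stage_text("R-ISS 2 and ISS 3", rules)),
               "ISS 3;RISS 2")
  expect_equal(label_key(extract_stage_text("stage II myeloma", rules)),
               "UNCLEAR 2")
  # systemless trailing value folds into the clear label set
  expect_equal(label_key(extract_stage_text("ISS stage III, previously stage 3", rules)),
               "ISS 3")
  # a clear label suppresses a co-occurring unclear one
  expect_equal(label_key(extract_stage_text("ISS stage III, previously stage 1", rules)),
               "ISS 3")
  expect_equal(label_key(extract_stage_text("stage III by Durie-Salmon", rules)),
               "DS 3")
  expect_equal(label_key(extract_stage_text("R-ISS stage 3, ISS stage 1", rules)),
               "ISS 1;RISS 3")
})

test_that("full extraction composes the four stages", {
  expect_equal(label_key(extract_stage_text("known multiple myeloma, ISS stage III, on therapy", rules)),
               "ISS 3")
  expect_equal(nrow(extract_stage_text("Bactrim DS 800-160 bid", rules)), 0)
  expect_equal(label_key(extract_stage_text("stage II-III by Durie-Salmon", rules)),
               "DS 2;DS 3")
  note <- make_note(text = paste0(strrep("x ", 60), "ISS stage III. ", strrep("y ", 110)))
  sn <- snippets_from_corpus(note)
  pred <- extract_snippet_stage(sn[1, ], rules)
  expect_s3_class(pred, "mm_predictions")
  expect_equal(label_key(pred$labels[[1]]), "ISS 3")
})

test_that("predictions never mix UNCLEAR with a named system and stay in range", {
  suite <- template_fixture_suite()
  for (i in seq_len(nrow(suite))) {
    lab <- extract_stage_text(suite$text[i], rules)
    expect_true(all(lab$value %in% 1:3))
    expect_true(all(lab$system %in% staging_systems()))
    if (nrow(lab) > 0 && any(lab$system != "UNCLEAR")) {
      expect_false(any(lab$system == "UNCLEAR"))
    }
    expect_false(any(duplicated(lab[, c("system", "value")])))
  }
})

test_that("extraction is deterministic and suppression is monotone", {
  suite <- template_fixture_suite()
  texts <- suite$text[seq(1, nrow(suite), by = 3)]
  again <- stage_ruleset()
  for (tx in texts) {
    expect_identical(extract_stage_text(tx, rules), extract_stage_text(tx, again))
  }
  # widen the other-disease lexicon: label sets may only shrink
  cfg <- yaml::read_yaml(system.file("extdata", "rules.yaml", package = "mmstage"))
  cfg$other_disease_rules <- c(cfg$other_disease_rules,
                               list(list(id = "dz_extra", pattern = "\\bmyeloma\\b")))
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  wider <- stage_ruleset(tmp)
  for (tx in texts) {
    base <- extract_stage_text(tx, rules)
    shrunk <- extract_stage_text(tx, wider)
    expect_true(all(paste(shrunk$system, shrunk$value) %in%
                      paste(base$system, base$value)), info = tx)
  }
})
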