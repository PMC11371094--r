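# Template cases: short slot-filled sentences with gold labels computed from
# the slots (never by running the extractor), covering every staging system,
# stage value, numeral form, multi-label shape, and distractor class. The
# rendered suite doubles as the extractor's fixture suite and as the staging
# sentences of the synthetic corpus generator.

#' Sentence templates for staging mentions and distractors
#'
#' @return Tibble with `template_id`, `category` (`clear`, `unclear`,
#'   `multi`, `distractor`, `not_stage`, `hard`), `text` with `{SYS}`,
#'   `{SYS2}`, `{VAL}`, `{VAL2}` slots, and `roman1_ok` (whether the template
#'   supports the bare roman numeral I, which the rules only recognise
#'   adjacent to a system token or the word "stage").
#' @export
stage_templates <- function() {
  if (!is.null(.mmstage_cache$templates)) return(.mmstage_cache$templates)
  tribble_tpl <- function(id, category, text, roman1_ok = TRUE) {
    tibble(template_id = id, category = category, text = text, roman1_ok = roman1_ok)
  }
  out <- bind_rows(
    tribble_tpl("c1", "clear", "{SYS} stage {VAL}"),
    tribble_tpl("c2", "clear", "{SYS} {VAL}"),
    tribble_tpl("c3", "clear", "stage {VAL} by {SYS}"),
    tribble_tpl("c4", "clear", "stage {VAL} per {SYS}"),
    tribble_tpl("c5", "clear", "{SYS} stage: {VAL}"),
    tribble_tpl("c6", "clear", "known multiple myeloma, {SYS} stage {VAL}, plan to continue current therapy"),
    tribble_tpl("c7", "clear", "Assessment: myeloma {SYS} {VAL}, counseled regarding prognosis"),
    tribble_tpl("c8", "clear", "staging per {SYS} was {VAL}", roman1_ok = FALSE),
    tribble_tpl("u1", "unclear", "stage {VAL} myeloma"),
    tribble_tpl("u2", "unclear", "multiple myeloma, stage {VAL}"),
    tribble_tpl("u3", "unclear", "stage {VAL} disease, plan chemotherapy"),
    tribble_tpl("u4", "unclear", "MM stage {VAL} documented at diagnosis"),
    tribble_tpl("m1", "multi", "{SYS} {VAL} and {SYS2} {VAL2}"),
    tribble_tpl("m2", "multi", "stage {VAL}-{VAL2} by {SYS}"),
    tribble_tpl("m3", "multi", "{SYS} stage {VAL}, {SYS2} stage {VAL2}"),
    tribble_tpl("m4", "multi", "{SYS} stage {VAL}/{VAL2}"),
    tribble_tpl("d1", "distractor", "CKD stage {VAL}, follow renal function"),
    tribble_tpl("d2", "distractor", "chronic kidney disease stage {VAL} with stable creatinine"),
    tribble_tpl("d3", "distractor", "Bactrim DS 800-160 by mouth twice daily"),
    tribble_tpl("d4", "distractor", "history of stage {VAL} lung cancer, s/p resection"),
    tribble_tpl("d5", "distractor", "NYHA class {VAL} heart failure symptoms"),
    tribble_tpl("d6", "distractor", "stage {VAL} breast carcinoma in remote history"),
    tribble_tpl("d7", "distractor", "Septra DS one tab daily for prophylaxis"),
    tribble_tpl("d8", "distractor", "end-stage renal disease on dialysis"),
    tribble_tpl("d9", "distractor", "prostate cancer, stage {VAL}, s/p radiation"),
    tribble_tpl("n1", "not_stage", "no staging information available in outside records"),
    tribble_tpl("n2", "not_stage", "bone marrow biopsy pending; staging to follow"),
    tribble_tpl("n3", "not_stage", "discussed staging workup and prognosis at length"),
    tribble_tpl("n4", "not_stage", "patient tolerating treatment well, no new complaints"),
    tribble_tpl("n5", "not_stage", "Bactrim DS for PJP prophylaxis"),
    tribble_tpl("n6", "not_stage", "wound healing well, staged dressing changes continue"),
    tribble_tpl("h1", "hard",
      paste0("{SYS} stage {VAL} at diagnosis. Renal function has remained stable ",
             "throughout the interval under observation; CKD stage {VAL2} chronic")),
    tribble_tpl("h2", "hard",
      paste0("On Bactrim DS for pneumocystis prophylaxis, tolerating well without ",
             "rash or nausea reported. Durie-Salmon stage {VAL} myeloma confirmed at diagnosis")),
    tribble_tpl("h3", "hard",
      paste0("Previously documented as stage {VAL2} without a named system in outside ",
             "records from prior years. Today {SYS} {VAL} was confirmed by the treating oncologist")),
    tribble_tpl("h4", "hard",
      paste0("Remote history of stage {VAL2} colon cancer treated surgically, currently ",
             "without any evidence of recurrence on recent surveillance imaging studies. ",
             "Now with multiple myeloma, {SYS} stage {VAL}"))
  )
  .mmstage_cache$templates <- out
  out
}

.mmstage_cache <- new.env(parent = emptyenv())

#' Surface spellings of a staging system
#'
#' @param system A canonical system code (`"RISS"`, `"ISS"`, `"DS"`).
#' @return Character vector of surface forms, canonical form first.
#' @export
system_surface_forms <- function(system) {
  switch(system,
         RISS = c("R-ISS", "RISS", "Revised ISS", "Revised International Staging System"),
         ISS = c("ISS", "International Staging System"),
         DS = c("DS", "D-S", "Durie-Salmon", "Durie Salmon", "Durie/Salmon"),
         abort(paste0("no surface forms for system ", system)))
}

value_surface <- function(value, num_form = c("roman", "arabic"), suffix = "") {
  num_form <- match.arg(num_form)
  base <- if (num_form == "roman") c("I", "II", "III")[value] else as.character(value)
  paste0(base, suffix)
}

#' Render a template case
#'
#' Fills the template slots with concrete system spellings and stage values
#' and returns the rendered text together with its gold label set, computed
#' from the slots (never by running the extractor). Unspecified surface
#' choices (system spelling, roman vs arabic numerals, a Durie-Salmon A/B
#' subclass suffix) are drawn from the session RNG, so seed the RNG for
#' reproducible rendering.
#'
#' @param template One row of [stage_templates()] (or a `template_id`
#'   string).
#' @param system,system2 Canonical system codes for the `{SYS}`/`{SYS2}`
#'   slots (ignored when the template has none; `hard` templates with a
#'   fixed system, like the Bactrim/Durie-Salmon case, ignore `system` too).
#' @param value,value2 Stage values in `{1, 2, 3}` for `{VAL}`/`{VAL2}`.
#' @param sys_form,sys2_form,num_form,num2_form,suffix Optional explicit
#'   surface choices; `NULL` means sample one.
#' @return List with `text` and `gold` (a [stage_labels()] tibble).
#' @export
render_template <- function(template, system = NULL, value = NULL,
                            system2 = NULL, value2 = NULL,
                            sys_form = NULL, sys2_form = NULL,
                            num_form = NULL, num2_form = NULL, suffix = NULL) {
  if (is.character(template)) {
    tpls <- stage_templates()
    template <- tpls[tpls$template_id == template, ]
    if (nrow(template) == 0) abort("unknown template id")
  }
  text <- template$text
  if (!is.null(value)) stopifnot(value %in% 1:3)
  if (!is.null(value2)) stopifnot(value2 %in% 1:3)
  pick_num <- function(nf, v) {
    if (!is.null(nf)) return(nf)
    nf <- sample(c("roman", "arabic"), 1)
    # bare roman I is out of rule scope in non-adjacent templates
    if (nf == "roman" && identical(v, 1L) && !template$roman1_ok) nf <- "arabic"
    nf
  }
  has <- function(slot) grepl(slot, text, fixed = TRUE)
  if (has("{SYS}") && template$category %in% c("clear", "multi", "hard")) {
    if (is.null(system)) abort(paste0("template ", template$template_id, " needs a system"))
    if (is.null(sys_form)) sys_form <- sample(system_surface_forms(system), 1)
    text <- sub("{SYS}", sys_form, text, fixed = TRUE)
  }
  if (has("{SYS2}")) {
    if (is.null(system2)) abort(paste0("template ", template$template_id, " needs system2"))
    if (is.null(sys2_form)) sys2_form <- sample(system_surface_forms(system2), 1)
    text <- sub("{SYS2}", sys2_form, text, fixed = TRUE)
  }
  if (has("{VAL}")) {
    if (is.null(value)) abort(paste0("template ", template$template_id, " needs a value"))
    value <- as.integer(value)
    nf <- pick_num(num_form, value)
    if (is.null(suffix)) {
      suffix <- if (identical(system, "DS") && template$category %in% c("clear", "hard") &&
                    stats::runif(1) < 0.3) sample(c("A", "B"), 1) else ""
    }
    if (nf == "roman" && identical(value, 1L) && !template$roman1_ok) nf <- "arabic"
    text <- sub("{VAL}", value_surface(value, nf, suffix), text, fixed = TRUE)
  }
  if (has("{VAL2}")) {
    if (is.null(value2)) abort(paste0("template ", template$template_id, " needs value2"))
    value2 <- as.integer(value2)
    nf2 <- num2_form %||% if (template$template_id %in% c("m2", "m4")) {
      # range slots share one numeral form
      if (grepl("\\b(?:III|II|I)[AB]?\\b", text)) "roman" else "arabic"
    } else sample(c("roman", "arabic"), 1)
    text <- sub("{VAL2}", value_surface(value2, nf2), text, fixed = TRUE)
  }
  gold <- switch(template$category,
    clear = stage_labels(system, value),
    unclear = stage_labels("UNCLEAR", value),
    multi = {
      if (template$template_id %in% c("m2", "m4")) {
        stage_labels(c(system, system), c(value, value2))
      } else {
        stage_labels(c(system, system2), c(value, value2))
      }
    },
    distractor = stage_labels(),
    not_stage = stage_labels(),
    hard = {
      if (template$template_id == "h2") stage_labels("DS", value)
      else stage_labels(system, value)
    },
    abort("unknown template category"))
  list(text = text, gold = dplyr::distinct(gold))
}

#' The bundled template fixture suite
#'
#' Deterministically enumerates every template over systems, values, surface
#' spellings and numeral forms: all clear templates over the three named
#' systems and three stages, the unclear and multi-label shapes, stage
#' ranges, Durie-Salmon subclass suffixes, and every distractor and
#' not-stage case. Gold is computed from the generation slots.
#'
#' @return Tibble with `case_id`, `template_id`, `category`, `text`, and a
#'   `gold` list-column of label tibbles.
#' @export
template_fixture_suite <- function() {
  tpls <- stage_templates()
  cases <- list()
  add <- function(tpl_id, ...) {
    tpl <- tpls[tpls$template_id == tpl_id, ]
    r <- render_template(tpl, ...)
    cases[[length(cases) + 1L]] <<- tibble(
      case_id = sprintf("%s_%03d", tpl_id, sum(grepl(paste0("^", tpl_id, "_"),
                                                     names(cases))) + length(cases)),
      template_id = tpl_id, category = tpl$category,
      text = r$text, gold = list(r$gold))
  }
  named <- c("RISS", "ISS", "DS")
  k <- 0L
  for (tid in paste0("c", 1:8)) {
    tpl <- tpls[tpls$template_id == tid, ]
    for (sys in named) {
      forms <- system_surface_forms(sys)
      for (v in 1:3) {
        k <- k + 1L
        nf <- if (k %% 2 == 0) "arabic" else "roman"
        if (nf == "roman" && v == 1L && !tpl$roman1_ok) nf <- "arabic"
        suf <- if (sys == "DS" && nf == "roman" && v == 3L && k %% 3 == 0) "A" else ""
        add(tid, system = sys, value = v,
            sys_form = forms[(k %% length(forms)) + 1L], num_form = nf, suffix = suf)
      }
    }
  }
  for (tid in paste0("u", 1:4)) {
    for (v in 1:3) {
      k <- k + 1L
      add(tid, value = v, num_form = if (k %% 2 == 0) "arabic" else "roman", suffix = "")
    }
  }
  pairs <- list(c("RISS", "ISS"), c("ISS", "DS"), c("DS", "RISS"))
  for (p in pairs) {
    add("m1", system = p[1], value = 2L, system2 = p[2], value2 = 3L,
        sys_form = system_surface_forms(p[1])[1], sys2_form = system_surface_forms(p[2])[1],
        num_form = "arabic", num2_form = "arabic", suffix = "")
    add("m1", system = p[1], value = 1L, system2 = p[2], value2 = 2L,
        sys_form = system_surface_forms(p[1])[1], sys2_form = system_surface_forms(p[2])[1],
        num_form = "arabic", num2_form = "arabic", suffix = "")
    add("m3", system = p[1], value = 3L, system2 = p[2], value2 = 1L,
        sys_form = system_surface_forms(p[1])[1], sys2_form = system_surface_forms(p[2])[1],
        num_form = "arabic", num2_form = "arabic", suffix = "")
  }
  for (sys in named) {
    add("m2", system = sys, value = 2L, value2 = 3L,
        sys_form = system_surface_forms(sys)[1], num_form = "roman",
        num2_form = "roman", suffix = "")
    add("m2", system = sys, value = 1L, value2 = 2L,
        sys_form = system_surface_forms(sys)[1], num_form = "arabic",
        num2_form = "arabic", suffix = "")
    add("m4", system = sys, value = 2L, value2 = 3L,
        sys_form = system_surface_forms(sys)[1], num_form = "arabic",
        num2_form = "arabic", suffix = "")
  }
  dvals <- c(d1 = 3L, d2 = 2L, d4 = 1L, d5 = 3L, d6 = 2L, d9 = 2L)
  for (tid in paste0("d", 1:9)) {
    v <- if (tid %in% names(dvals)) dvals[[tid]] else NULL
    nf <- if (tid == "d5") "roman" else if (!is.null(v) && v == 1L) "arabic" else "roman"
    if (is.null(v)) add(tid) else add(tid, value = v, num_form = nf, suffix = "")
  }
  for (tid in paste0("n", 1:6)) add(tid)
  for (sys in named) {
    add("h1", system = sys, value = 3L, value2 = 2L,
        sys_form = system_surface_forms(sys)[1], num_form = "roman",
        num2_form = "arabic", suffix = "")
    add("h3", system = sys, value = 2L, value2 = 3L,
        sys_form = system_surface_forms(sys)[1], num_form = "arabic",
        num2_form = "roman", suffix = "")
    add("h4", system = sys, value = 1L, value2 = 3L,
        sys_form = system_surface_forms(sys)[1], num_form = "arabic",
        num2_form = "roman", suffix = "")
  }
  add("h2", value = 3L, num_form = "roman", suffix = "")
  out <- bind_rows(cases)
  out$case_id <- sprintf("%s_%03d", out$template_id, seq_len(nrow(out)))
  out
}
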