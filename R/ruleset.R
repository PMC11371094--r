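# Rule-set loading and the two normalizers. Every lexicon, proximity window
# and connective pattern lives in a YAML config (inst/extdata/rules.yaml by
# default) so the rules can be iterated on without code changes.

#' Load the extraction rule set
#'
#' Reads span-labeling rules (stage values, staging systems, non-MM diseases,
#' antibiotics, MM mentions), normalization maps, connectives, and proximity
#' windows from a YAML file. The order of rules in the file is the overlap
#' priority: when same-category spans overlap, the earlier rule's span wins.
#'
#' @param path Path to a rules YAML file; default is the rule set shipped with
#'   the package.
#' @return An object of class `stage_ruleset`: a list with a `spans` rule
#'   table, `windows`, `connectives`, `value_map`, and `system_map`.
#' @export
stage_ruleset <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rules.yaml", package = "mmstage", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  needed <- c("stage_value_rules", "staging_system_rules", "other_disease_rules",
              "antibiotic_rules", "mm_mention_rules", "windows", "value_map",
              "system_map", "connectives")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0) {
    abort(paste0("rules file ", path, " lacks section(s): ",
                 paste(missing, collapse = ", ")))
  }
  rule_tbl <- function(rules, category) {
    bind_rows(lapply(rules, function(r) {
      tibble(category = category,
             rule_id = r$id,
             pattern = r$pattern,
             group = as.integer(r$group %||% 0L),
             system = r$system %||% NA_character_,
             bare = isTRUE(r$bare),
             anchored = isTRUE(r$anchored),
             range = isTRUE(r$range))
    }))
  }
  spans <- bind_rows(
    rule_tbl(cfg$stage_value_rules, "STAGE_VALUE"),
    rule_tbl(cfg$staging_system_rules, "STAGING_SYSTEM"),
    rule_tbl(cfg$other_disease_rules, "OTHER_DISEASE"),
    rule_tbl(cfg$antibiotic_rules, "ANTIBIOTIC"),
    rule_tbl(cfg$mm_mention_rules, "MM_MENTION")
  )
  spans$rule_priority <- seq_len(nrow(spans))
  if (anyDuplicated(spans$rule_id)) abort("rule ids must be unique")
  w <- cfg$windows
  stopifnot(w$disease_suppression_chars >= 0, w$association_chars >= 0,
            w$unclear_anchor_chars >= 0)
  structure(list(
    spans = spans,
    windows = list(disease_suppression_chars = as.integer(w$disease_suppression_chars),
                   association_chars = as.integer(w$association_chars),
                   unclear_anchor_chars = as.integer(w$unclear_anchor_chars)),
    connectives = as.character(cfg$connectives),
    value_map = stats::setNames(as.integer(unlist(cfg$value_map)),
                                toupper(names(cfg$value_map))),
    system_map = stats::setNames(toupper(unlist(cfg$system_map)),
                                 toupper(names(cfg$system_map))),
    source = path
  ), class = "stage_ruleset")
}

#' @export
print.stage_ruleset <- function(x, ...) {
  cat("<stage_ruleset> ", nrow(x$spans), " span rules from ", x$source, "\n", sep = "")
  cat("  windows: suppression ", x$windows$disease_suppression_chars,
      " / association ", x$windows$association_chars,
      " / unclear anchor ", x$windows$unclear_anchor_chars, " chars\n", sep = "")
  invisible(x)
}

#' Normalize a matched stage-value string
#'
#' Roman numerals I/II/III (any case) and arabic 1/2/3 map to integers 1-3.
#' A trailing Durie-Salmon subclass letter A/B is stripped first (subclasses
#' are collapsed: "IIIA" is stage 3). Anything else is rejected.
#'
#' @param raw Character vector of matched stage-value strings.
#' @param rules A [stage_ruleset()] (for the value map).
#' @return Integer vector; `NA` marks a rejected value (rejection is a value,
#'   not an error).
#' @export
#' @examples
#' normalize_stage_value(c("III", "2", "IIIA", "IV"))
normalize_stage_value <- function(raw, rules = stage_ruleset()) {
  x <- toupper(trimws(raw))
  x <- sub("(?<=.)[AB]$", "", x, perl = TRUE) # strip DS subclass suffix
  out <- unname(rules$value_map[x])
  as.integer(out)
}

# Range-aware version used by span labeling: "II-III" -> c(2, 3).
# Returns NULL when any component fails to normalize.
normalize_value_span <- function(raw, is_range, rules) {
  if (is_range) {
    parts <- strsplit(trimws(raw), "\\s*[-/]\\s*")[[1]]
    vals <- normalize_stage_value(parts, rules)
    if (length(vals) == 0 || anyNA(vals)) return(NULL)
    return(unique(as.integer(vals)))
  }
  v <- normalize_stage_value(raw, rules)
  if (is.na(v)) NULL else v
}

#' Normalize a matched staging-system string
#'
#' Maps surface variants to the canonical system codes: "International
#' Staging System" to ISS, "R-ISS"/"RISS"/"Revised ISS" to RISS,
#' "DS"/"D-S"/"Durie-Salmon" (hyphen, space or slash) to DS. Matching is
#' case-insensitive. An unknown string is a contract error: the span patterns
#' and the map must stay in sync.
#'
#' @param raw Character vector of matched system strings.
#' @param rules A [stage_ruleset()].
#' @return Character vector of canonical system codes.
#' @export
#' @examples
#' normalize_system_name(c("International Staging System", "R-ISS", "Durie-Salmon"))
normalize_system_name <- function(raw, rules = stage_ruleset()) {
  x <- toupper(trimws(gsub("\\s+", " ", raw)))
  out <- unname(rules$system_map[x])
  if (anyNA(out)) {
    abort(paste0("staging-system string not in normalization map: '",
                 raw[is.na(out)][1], "'"))
  }
  out
}
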