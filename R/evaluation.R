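# Per-system contingency-table evaluation and the dev/val split. Scoring is
# unit-level (snippet or patient) with exact set matching per system: a unit
# counts TP only when the predicted and gold value sets for that system are
# equal and non-empty.

#' Round half up
#'
#' Reporting convention for precision/recall/F1: decimal rounding with ties
#' away from zero (0.925 -> 0.93), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Reduce package containers to per-unit value sets
#'
#' Normalizes any of the label-bearing containers (snippet predictions or
#' gold, patient stage records or gold) into one tibble row per unit with a
#' `labels` list-column of `(system, value)` pairs, ready for
#' [build_contingency()].
#'
#' @param x A `mm_predictions`, `mm_snippet_gold`, `mm_patient_stage`, or
#'   `mm_patient_gold` tibble.
#' @return Tibble with `unit_id` and `labels` (list of tibbles).
#' @export
label_sets <- function(x) {
  if (inherits(x, "mm_predictions") || inherits(x, "mm_snippet_gold")) {
    return(tibble(unit_id = x$snippet_id,
                  labels = lapply(x$labels, function(l) l[, c("system", "value")])))
  }
  if (inherits(x, "mm_patient_stage")) {
    return(tibble(unit_id = x$patient_id,
                  labels = lapply(x$assignments, function(a) {
                    tibble(system = a$system, value = a$value)
                  })))
  }
  if (inherits(x, "mm_patient_gold")) {
    return(tibble(unit_id = x$patient_id,
                  labels = lapply(x$per_system, function(per) {
                    tibble(system = names(per), value = as.integer(unname(per)))
                  })))
  }
  if (is.data.frame(x) && all(c("unit_id", "labels") %in% names(x))) {
    return(as_tibble(x[, c("unit_id", "labels")]))
  }
  abort("cannot derive per-unit label sets from this object")
}

#' Build a per-system contingency table
#'
#' For each unit, let P be the predicted stage values for `system` and G the
#' gold values. The unit is TP when `P == G` and both non-empty; TN when both
#' empty; FP when the prediction contains a spurious value (counted once per
#' unit, even if a value was also missed); FN when a gold value was missed
#' and nothing spurious was predicted. Cells therefore sum to the unit count.
#'
#' @param predictions,gold Per-unit label sets (see [label_sets()]); must
#'   cover the same unit ids.
#' @param system A staging-system code.
#' @return One-row tibble: `system`, `tp`, `tn`, `fp`, `fn`.
#' @export
build_contingency <- function(predictions, gold, system) {
  stopifnot(system %in% STAGING_SYSTEMS)
  p <- label_sets(predictions)
  g <- label_sets(gold)
  if (nrow(p) != nrow(g) || !setequal(p$unit_id, g$unit_id)) {
    abort("predictions and gold must cover the same unit ids")
  }
  g <- g[match(p$unit_id, g$unit_id), ]
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(p))) {
    pv <- sort(unique(p$labels[[i]]$value[p$labels[[i]]$system == system]))
    gv <- sort(unique(g$labels[[i]]$value[g$labels[[i]]$system == system]))
    if (length(pv) == 0 && length(gv) == 0) {
      tn <- tn + 1L
    } else if (length(pv) > 0 && identical(pv, gv)) {
      tp <- tp + 1L
    } else if (length(setdiff(pv, gv)) > 0) {
      fp <- fp + 1L
    } else {
      fn <- fn + 1L
    }
  }
  tibble(system = system, tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Precision, recall and F1 from a contingency table
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`, F1 their harmonic
#' mean, computed exactly and reported rounded (half-up). A zero denominator
#' yields `NA` (undefined), never 0.
#'
#' @param table One-row contingency tibble (or anything with `tp`, `fp`,
#'   `fn`).
#' @param digits Reporting precision (default 2 decimals).
#' @return One-row tibble with rounded `precision`, `recall`, `f1` and exact
#'   `precision_raw`, `recall_raw`, `f1_raw`.
#' @export
#' @examples
#' compute_metrics(tibble::tibble(tp = 204, tn = 832, fp = 2, fn = 3))
compute_metrics <- function(table, digits = 2) {
  stopifnot(all(c(table$tp, table$fp, table$fn) >= 0))
  prec <- if (table$tp + table$fp > 0) table$tp / (table$tp + table$fp) else NA_real_
  rec <- if (table$tp + table$fn > 0) table$tp / (table$tp + table$fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  out <- tibble(precision = round_half_up(prec, digits),
                recall = round_half_up(rec, digits),
                f1 = round_half_up(f1, digits))
  out$precision_raw <- prec
  out$recall_raw <- rec
  out$f1_raw <- f1
  out
}

#' Evaluate predictions against gold, per staging system
#'
#' One report row per system in {RISS, ISS, DS, UNCLEAR}: contingency cells
#' plus precision/recall/F1. "Not stage" is scored implicitly as the
#' all-systems-empty case (it drives the TN cells); no separate row is
#' emitted. With `group_by`, rows repeat per group value.
#'
#' @param predictions,gold Label-bearing containers (see [label_sets()]).
#' @param group_by Optional named character vector (or tibble with `unit_id`
#'   and one grouping column) assigning each unit to a group.
#' @param digits Reporting precision for the metrics.
#' @return Tibble with one row per system (times groups), columns `system`,
#'   `tp`, `tn`, `fp`, `fn`, `precision`, `recall`, `f1` (plus `group` and
#'   the `*_raw` metrics).
#' @export
evaluate_corpus <- function(predictions, gold, group_by = NULL, digits = 2) {
  p <- label_sets(predictions)
  g <- label_sets(gold)
  if (nrow(p) == 0) abort("nothing to evaluate: empty unit set")
  one_report <- function(psub, gsub, group) {
    rows <- lapply(STAGING_SYSTEMS, function(sys) {
      tab <- build_contingency(psub, gsub, sys)
      dplyr::bind_cols(tab, compute_metrics(tab, digits))
    })
    out <- bind_rows(rows)
    if (!is.null(group)) out <- dplyr::bind_cols(tibble(group = group), out)
    out
  }
  if (is.null(group_by)) return(one_report(p, g, NULL))
  if (is.data.frame(group_by)) {
    grp <- stats::setNames(group_by[[setdiff(names(group_by), "unit_id")[1]]],
                           group_by$unit_id)
  } else {
    grp <- group_by
  }
  groups <- sort(unique(unname(grp[p$unit_id])))
  bind_rows(lapply(groups, function(gv) {
    ids <- p$unit_id[grp[p$unit_id] == gv]
    one_report(p[p$unit_id %in% ids, ], g[g$unit_id %in% ids, ], gv)
  }))
}

#' Random development/validation split
#'
#' Splits unit ids into a development and a validation partition: validation
#' gets `floor(val_fraction * N)` ids chosen by a seeded permutation, the
#' remainder goes to development. Both partitions preserve input order.
#'
#' @param unit_ids Vector of distinct unit ids.
#' @param val_fraction Validation fraction in (0, 1) (default 0.2).
#' @param seed Integer seed driving the permutation.
#' @return List with elements `dev` and `val`.
#' @export
#' @examples
#' split_dev_val(sprintf("s%04d", 1:10), 0.2, seed = 7)
split_dev_val <- function(unit_ids, val_fraction = 0.2, seed = 1L) {
  if (length(unit_ids) == 0) return(list(dev = unit_ids, val = unit_ids))
  if (anyDuplicated(unit_ids)) abort("unit ids must be distinct")
  stopifnot(val_fraction > 0, val_fraction < 1)
  n_val <- floor(val_fraction * length(unit_ids))
  shuffled <- withr::with_seed(seed, sample(unit_ids))
  val_set <- shuffled[seq_len(n_val)]
  list(dev = unit_ids[!unit_ids %in% val_set],
       val = unit_ids[unit_ids %in% val_set])
}

#' Reference validation contingency cells
#'
#' The per-system TP/TN/FP/FN cells published for the original VA deployment
#' of this staging pipeline, at the snippet level (1,041 held-out snippets)
#' and the patient level (100 held-out patients), together with the
#' precision/recall/F1 values reported alongside them. Shipped so the
#' metric arithmetic can be recomputed and checked; the underlying notes are
#' restricted and not distributed.
#'
#' @return Tibble with `level`, `system`, `tp`, `tn`, `fp`, `fn`, and the
#'   `reported_*` metric columns.
#' @export
reference_validation_cells <- function() {
  path <- system.file("extdata", "reference_validation_cells.csv",
                      package = "mmstage", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
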