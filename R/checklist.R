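#' Automation feasibility classes
#'
#' The closed set of automation feasibility classes used to label chart-check
#' items. `"Full"` means a check can potentially be fully automated;
#' `"Partial"` means automation can verify that information is present (e.g.
#' a document exists) but not that its content is correct; `"Full/Partial"`
#' means partial automation today with full automation attainable under
#' stated practice changes; `"No"` means manual inspection only.
#'
#' @return Character vector of the four valid class tokens, ordered from
#'   least to most residual manual burden.
#' @export
#' @examples
#' automation_classes()
automation_classes <- function() {
  c("Full", "Full/Partial", "Partial", "No")
}

#' Manual-burden weighting score for an automation class
#'
#' Maps an automation feasibility class to the weighting score used to scale
#' residual manual check time and residual detectable errors:
#' `Full` = 0, `Partial` = 0.5, `No` = 1. A class between two levels is
#' scored as their average, so `Full/Partial` = (0 + 0.5)/2 = 0.25.
#'
#' @param class Character vector of class tokens from [automation_classes()].
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
#' @examples
#' automation_weight(c("Full", "Full/Partial", "Partial", "No"))
automation_weight <- function(class) {
  w <- c("Full" = 0, "Full/Partial" = 0.25, "Partial" = 0.5, "No" = 1)
  bad <- setdiff(unique(class), names(w))
  if (length(bad) > 0L) {
    stop("unknown automation class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(w[class])
}

# Scenario name -> checklist class column. "none" is synthesized (all "No").
.scenario_columns <- c(
  auto_tg275    = "class_tg275",
  auto_umms_tool = "class_umms_tool",
  auto_umms_exp = "class_umms_exp"
)

#' Automation scenario names
#'
#' The four automation levels the benefit simulator understands: `none`
#' (fully manual review: every item behaves as class `No`), `auto_umms_tool`
#' (items automated by the in-house comparison tool plus commercial dose
#' verification), `auto_tg275` (feasibility classes as surveyed in TG-275),
#' and `auto_umms_exp` (feasibility classes from the expert re-evaluation).
#'
#' @return Character vector of scenario names.
#' @export
scenario_names <- function() c("none", names(.scenario_columns))

.checklist_columns <- c(
  "item_id", "source", "category", "description", "rpn", "use_frequency",
  "recommended", "class_tg275", "class_umms_tool", "class_umms_exp"
)

.categories <- c("PatientAssessment", "Simulation", "TreatmentPlanning")

new_checklist <- function(items, name) {
  structure(list(name = name, items = items), class = "checklist")
}

#' @export
print.checklist <- function(x, ...) {
  cat("<checklist>", x$name, "-", nrow(x$items), "items\n")
  tab <- table(factor(x$items$category, levels = .categories))
  cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.checklist <- function(x) nrow(x$items)

validate_checklist_items <- function(items, where = "checklist") {
  if (nrow(items) == 0L) {
    stop(where, ": checklist has no items", call. = FALSE)
  }
  if (anyNA(items$item_id) || any(!nzchar(items$item_id))) {
    stop(where, ": missing item_id", call. = FALSE)
  }
  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup) > 0L) {
    stop(where, ": duplicate item_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(items$category), .categories)
  if (length(bad_cat) > 0L) {
    stop(where, ": unknown category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  for (col in .scenario_columns) {
    vals <- items[[col]]
    bad <- setdiff(unique(vals[!is.na(vals)]), automation_classes())
    if (length(bad) > 0L) {
      stop(where, ": unknown automation class in ", col, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  uf <- items$use_frequency
  if (any(!is.na(uf) & (uf < 0 | uf > 1))) {
    stop(where, ": use_frequency outside [0, 1]", call. = FALSE)
  }
  if (any(!is.na(items$rpn) & items$rpn < 0)) {
    stop(where, ": negative rpn", call. = FALSE)
  }
  invisible(items)
}

#' Read a chart-check checklist from CSV
#'
#' Reads one flat CSV table carrying check items with their FMEA risk
#' attributes (risk priority number and use frequency, where available) and
#' one automation feasibility class column per scenario. Empty cells mean
#' the attribute is absent, never zero. Row order is preserved.
#'
#' The required header is
#' `item_id, source, category, description, rpn, use_frequency, recommended,
#' class_tg275, class_umms_tool, class_umms_exp`.
#'
#' @param path Path to a UTF-8 CSV file with the documented header.
#' @param format Input format; only `"csv"` is supported.
#' @param name Checklist name; defaults to the file name without extension.
#' @return A `checklist` object: a list with `$name` and `$items`
#'   (a data.frame, one row per check item).
#' @export
#' @examples
#' p <- system.file("extdata", "table3_tg275_items.csv", package = "chartcheckr")
#' cl <- load_checklist(p)
#' length(cl)
load_checklist <- function(path, format = c("csv"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(.checklist_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("checklist CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, .checklist_columns]
  blank_to_na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA_character_, trimws(x))
  items <- data.frame(
    item_id = blank_to_na(raw$item_id),
    source = blank_to_na(raw$source),
    category = blank_to_na(raw$category),
    description = raw$description,
    rpn = suppressWarnings(as.integer(blank_to_na(raw$rpn))),
    use_frequency = suppressWarnings(as.numeric(blank_to_na(raw$use_frequency))),
    recommended = as.logical(blank_to_na(raw$recommended)),
    class_tg275 = blank_to_na(raw$class_tg275),
    class_umms_tool = blank_to_na(raw$class_umms_tool),
    class_umms_exp = blank_to_na(raw$class_umms_exp),
    stringsAsFactors = FALSE
  )
  # a non-numeric rpn/use cell must not silently become NA-absent
  had_rpn <- !is.na(blank_to_na(raw$rpn))
  if (any(had_rpn & is.na(items$rpn))) {
    stop("non-integer rpn value in ", path, call. = FALSE)
  }
  had_uf <- !is.na(blank_to_na(raw$use_frequency))
  if (any(had_uf & is.na(items$use_frequency))) {
    stop("non-numeric use_frequency value in ", path, call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  validate_checklist_items(items, where = basename(path))
  new_checklist(items, name)
}

#' Write a checklist back to CSV
#'
#' Inverse of [load_checklist()]: absent attributes are written as empty
#' cells, so a load/write/load round trip reproduces item ids, categories
#' and classes exactly.
#'
#' @param checklist A `checklist` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(checklist, path) {
  stopifnot(inherits(checklist, "checklist"))
  out <- checklist$items
  for (col in names(out)) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", as.character(v))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Filter a checklist down to its high-priority items
#'
#' Retains exactly the items with risk priority number strictly greater than
#' `rpn_min` and use frequency strictly greater than `use_min` (both
#' inequalities strict), preserving order. This is the rule that derives a
#' priority checklist from a full FMEA-scored list, e.g. RPN > 100 and
#' use > 60%.
#'
#' @param checklist A `checklist` object whose items all carry `rpn` and
#'   `use_frequency`; an item missing either attribute aborts the run rather
#'   than being silently dropped.
#' @param rpn_min RPN threshold (strict).
#' @param use_min Use-frequency threshold in `[0, 1]` (strict).
#' @return A `checklist` containing the retained sub-collection.
#' @export
filter_priority <- function(checklist, rpn_min = 100, use_min = 0.60) {
  stopifnot(inherits(checklist, "checklist"))
  items <- checklist$items
  if (nrow(items) == 0L) return(checklist)
  missing <- is.na(items$rpn) | is.na(items$use_frequency)
  if (any(missing)) {
    stop("filter_priority: items without rpn/use_frequency: ",
         paste(utils::head(items$item_id[missing], 5L), collapse = ", "),
         if (sum(missing) > 5L) ", ...", call. = FALSE)
  }
  keep <- items$rpn > rpn_min & items$use_frequency > use_min
  new_checklist(items[keep, , drop = FALSE],
                paste0(checklist$name, "_priority"))
}

#' Per-item automation classes under a scenario
#'
#' Resolves a scenario name to the mapping item id -> automation class.
#' Scenario `"none"` needs no stored column: with no automation every item
#' is class `"No"` by definition.
#'
#' @param checklist A `checklist` object.
#' @param scenario One of [scenario_names()].
#' @return Named character vector, item_id -> class.
#' @export
scenario_classes <- function(checklist, scenario) {
  stopifnot(inherits(checklist, "checklist"))
  scenario <- match.arg(scenario, scenario_names())
  items <- checklist$items
  if (scenario == "none") {
    cls <- rep("No", nrow(items))
  } else {
    cls <- items[[.scenario_columns[[scenario]]]]
    if (anyNA(cls)) {
      stop("scenario '", scenario, "' has no class for item(s): ",
           paste(utils::head(items$item_id[is.na(cls)], 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  stats::setNames(cls, items$item_id)
}

#' Tally automation classes under a scenario
#'
#' Counts how many checklist items fall in each automation feasibility class
#' under the given scenario. Counts always sum to the number of items.
#'
#' @inheritParams scenario_classes
#' @return Named integer vector over all four classes (zero-filled).
#' @export
#' @examples
#' p <- system.file("extdata", "table3_tg275_items.csv", package = "chartcheckr")
#' tally_classes(load_checklist(p), "auto_umms_exp")
tally_classes <- function(checklist, scenario) {
  cls <- scenario_classes(checklist, scenario)
  tab <- table(factor(cls, levels = automation_classes()))
  stats::setNames(as.integer(tab), names(tab))
}
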