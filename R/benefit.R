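#' Load manual check-time profiles
#'
#' Reads the packaged (or a user-supplied) table of average manual initial
#' chart check times: one row per (checklist, summary statistic, technique)
#' with the total minutes a physicist needs to work through the list by
#' hand.
#'
#' @param path CSV with columns `checklist_name, stat, technique,
#'   total_minutes`; defaults to the packaged survey summary.
#' @return data.frame of time profiles.
#' @export
load_time_profiles <- function(path = system.file("extdata", "table2_time_profiles.csv",
                                                  package = "chartcheckr")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("checklist_name", "stat", "technique", "total_minutes")
  if (!all(need %in% names(d)))
    stop("time profile CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(d$total_minutes <= 0)) stop("total_minutes must be > 0", call. = FALSE)
  d
}

#' Load baseline detectable-error percentages per workflow step
#'
#' @param path CSV with columns `step, percent_detectable`; defaults to the
#'   packaged incident-learning baseline (patient assessment 7.7%,
#'   simulation 28.2%, treatment planning 49.2% of potentially detectable
#'   events).
#' @return Named numeric vector, step -> percent.
#' @export
load_baseline_errors <- function(path = system.file("extdata", "table4_baseline_errors.csv",
                                                    package = "chartcheckr")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("step", "percent_detectable") %in% names(d)))
    stop("baseline CSV must have columns: step, percent_detectable", call. = FALSE)
  if (any(d$percent_detectable < 0)) stop("percentages must be >= 0", call. = FALSE)
  stats::setNames(d$percent_detectable, d$step)
}

resolve_total_minutes <- function(time_profile) {
  if (is.numeric(time_profile) && length(time_profile) == 1L) return(time_profile)
  if (is.list(time_profile) && !is.null(time_profile$total_minutes))
    return(time_profile$total_minutes)
  stop("time_profile must be a total-minutes number or a list with $total_minutes",
       call. = FALSE)
}

#' Residual manual check time under an automation scenario
#'
#' Each item's manual time is scaled by its automation weighting score
#' ([automation_weight()]): a fully automated item costs nothing, a
#' non-automatable item keeps its full manual time. Per-item minutes, when
#' supplied, must cover every item; otherwise the checklist total is
#' allocated uniformly across items.
#'
#' @param checklist A `checklist`.
#' @param scenario One of [scenario_names()]; every item must carry a class
#'   for it.
#' @param time_profile Total minutes for the checklist (a number, or a list
#'   with `$total_minutes` and optionally `$per_item_minutes`, a named
#'   vector item_id -> minutes).
#' @return Residual manual minutes.
#' @export
#' @examples
#' p <- system.file("extdata", "table3_tg275_items.csv", package = "chartcheckr")
#' cl <- load_checklist(p)
#' residual_time(cl, "auto_umms_exp", 72.8)
residual_time <- function(checklist, scenario, time_profile) {
  w <- automation_weight(scenario_classes(checklist, scenario))
  n <- length(w)
  per_item <- NULL
  if (is.list(time_profile) && !is.null(time_profile$per_item_minutes))
    per_item <- time_profile$per_item_minutes
  if (is.null(per_item)) {
    total <- resolve_total_minutes(time_profile)
    t_i <- rep(total / n, n)
  } else {
    missing <- setdiff(checklist$items$item_id, names(per_item))
    if (length(missing) > 0L)
      stop("per-item minutes missing for: ", paste(utils::head(missing, 5L), collapse = ", "),
           call. = FALSE)
    t_i <- unname(per_item[checklist$items$item_id])
  }
  sum(t_i * w)
}

#' Manual check-time reduction in percent
#'
#' @param residual Residual minutes under automation.
#' @param total Fully manual minutes.
#' @return `100 * (1 - residual/total)`.
#' @export
time_reduction_percent <- function(residual, total) {
  stopifnot(total > 0)
  100 * (1 - residual / total)
}

#' Residual detectable-error percentage per workflow step
#'
#' Scales each workflow step's baseline percentage of potentially
#' detectable events by the step's non-automated burden. Under the default
#' `weighted` model the burden is the mean automation weight of the step's
#' items (so partially automatable items get partial credit); under
#' `count` any item with nonzero weight counts fully, i.e. the burden is
#' the plain fraction of items that are not fully automated.
#'
#' @param checklist A `checklist` whose items carry workflow-step
#'   categories.
#' @param scenario One of [scenario_names()].
#' @param baseline Named numeric, step -> baseline percent
#'   ([load_baseline_errors()]).
#' @param error_model `"weighted"` (default) or `"count"`.
#' @return Named numeric, step -> residual percent; steps with no items are
#'   absent from the result.
#' @export
residual_error_percent <- function(checklist, scenario,
                                   baseline = load_baseline_errors(),
                                   error_model = c("weighted", "count")) {
  error_model <- match.arg(error_model)
  w <- automation_weight(scenario_classes(checklist, scenario))
  if (error_model == "count") w <- as.numeric(w > 0)
  cat_of <- checklist$items$category
  out <- numeric(0)
  for (step in names(baseline)) {
    idx <- which(cat_of == step)
    if (length(idx) == 0L) next
    out[step] <- baseline[[step]] * sum(w[idx]) / length(idx)
  }
  out
}

#' Simulate automation benefit across checklists, scenarios and techniques
#'
#' One report row per (checklist, scenario, technique) combination:
#' residual manual minutes, time reduction, and residual detectable-error
#' percent per workflow step. Deterministic; rows ordered by checklist,
#' then scenario (in the order given), then technique.
#'
#' @param checklists Named list of `checklist` objects.
#' @param scenarios Character vector of [scenario_names()].
#' @param time_profiles data.frame from [load_time_profiles()]; rows are
#'   selected by `checklist_name` and `stat`.
#' @param baseline Named numeric from [load_baseline_errors()].
#' @param stat Which time summary to use (`"median"`, `"max"` or `"min"`).
#' @return data.frame of benefit reports, residual error columns named
#'   `residual_err_<step>` (percent, one decimal as reported).
#' @export
simulate_benefit <- function(checklists, scenarios,
                             time_profiles = load_time_profiles(),
                             baseline = load_baseline_errors(),
                             stat = "median") {
  stopifnot(length(checklists) > 0, !is.null(names(checklists)))
  rows <- list()
  for (cname in names(checklists)) {
    cl <- checklists[[cname]]
    tp <- time_profiles[time_profiles$checklist_name == cname &
                          time_profiles$stat == stat, ]
    if (nrow(tp) == 0L)
      stop("no time profile rows for checklist '", cname, "' stat '", stat, "'",
           call. = FALSE)
    for (sc in scenarios) {
      sc <- match.arg(sc, scenario_names())
      err <- residual_error_percent(cl, sc, baseline)
      for (r in seq_len(nrow(tp))) {
        total <- tp$total_minutes[r]
        res <- residual_time(cl, sc, total)
        row <- data.frame(checklist = cname, scenario = sc,
                          technique = tp$technique[r], stat = stat,
                          total_minutes = total,
                          residual_minutes = res,
                          time_reduction_percent = time_reduction_percent(res, total),
                          stringsAsFactors = FALSE)
        for (step in names(err)) {
          row[[paste0("residual_err_", step)]] <- round(err[[step]], 1)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(checklist = character(0), scenario = character(0),
                      technique = character(0), stat = character(0),
                      total_minutes = numeric(0), residual_minutes = numeric(0),
                      time_reduction_percent = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
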