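# shared builders for small hand-checkable cases

fixture_checklist <- function() {
  load_checklist(system.file("extdata", "table3_tg275_items.csv",
                             package = "chartcheckr"))
}

# one-beam snapshot small enough to reason about by hand
tiny_snapshot <- function(system = "TPS", mu = 200, technique = "THREE_D",
                          n_leaves = 4L) {
  cp <- function(i, w) control_point(i, w,
                                     mlc_bank_A = rep(-10, n_leaves),
                                     mlc_bank_B = rep(10, n_leaves),
                                     gantry_angle = 0)
  plan_snapshot(
    system = system, patient_id = "PT000001", plan_name = "PLAN_T",
    technique = technique,
    prescription = prescription(5040, 180, 28, template_name = "Pelvis"),
    course_name = "Pelvis",
    beams = list(beam("B01", mu = mu,
                      control_points = list(cp(0L, 0), cp(1L, 1)))),
    user_origin = c(0, 0, 0)
  )
}

# synthetic checklist with controlled classes, for benefit-model arithmetic
toy_checklist <- function(classes_exp,
                          categories = rep("TreatmentPlanning", length(classes_exp)),
                          rpn = NULL, use_frequency = NULL) {
  n <- length(classes_exp)
  items <- data.frame(
    item_id = sprintf("X-%02d", seq_len(n)), source = "TG275",
    category = categories, description = "toy item",
    rpn = if (is.null(rpn)) rep(NA_integer_, n) else as.integer(rpn),
    use_frequency = if (is.null(use_frequency)) rep(NA_real_, n) else use_frequency,
    recommended = NA,
    class_tg275 = rep("No", n), class_umms_tool = NA_character_,
    class_umms_exp = classes_exp, stringsAsFactors = FALSE
  )
  chartcheckr:::new_checklist(items, "toy")
}

# independent recursive tree diff over two snapshots, producing the same
# path notation as the compare engine; used to cross-check manifests.
tree_diff_paths <- function(a, b, prefix = "", skip = c("system")) {
  paths <- character(0)
  note <- function(p) paths <<- c(paths, p)
  join <- function(p, name) if (nzchar(p)) paste0(p, ".", name) else name
  walk <- function(x, y, p) {
    if (is.null(x) != is.null(y)) { note(p); return(invisible(NULL)) }
    if (is.null(x)) return(invisible(NULL))
    if (is.list(x)) {
      nms <- names(x)
      if (is.null(nms)) {
        if (length(x) != length(y)) { note(p); return(invisible(NULL)) }
        for (i in seq_along(x)) walk(x[[i]], y[[i]], sprintf("%s[%d]", p, i))
      } else {
        for (nm in union(nms, names(y))) {
          if (nzchar(p) || !(nm %in% skip)) walk(x[[nm]], y[[nm]], join(p, nm))
        }
      }
      return(invisible(NULL))
    }
    if (length(x) > 1L || length(y) > 1L) {
      if (length(x) != length(y)) { note(p); return(invisible(NULL)) }
      nms <- names(x)
      for (i in seq_along(x)) {
        if (!identical(x[[i]], y[[i]])) {
          note(if (is.null(nms)) sprintf("%s[%d]", p, i) else join(p, nms[i]))
        }
      }
      return(invisible(NULL))
    }
    if (!identical(x, y)) note(p)
  }
  walk(unclass(a), unclass(b), prefix)
  paths
}

snapshot_error_types <- function() {
  setdiff(error_types(), "hotspot_injected")
}
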