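#' Rule-check policy configuration
#'
#' Numeric thresholds for the bespoke rule checks. None of these is a
#' published standard; they ship as institution-tunable defaults and can be
#' overridden per key or loaded from YAML ([read_policy_yaml()]). The one
#' fixed quantity is the hotspot threshold: a hotspot is dose strictly
#' greater than 110% of the total prescription dose.
#'
#' @param slice_thickness_max_mm Named numeric, max CT slice thickness (mm)
#'   per technique.
#' @param hu_high_z_threshold HU above which density-override review is
#'   flagged.
#' @param iso_target_offset_max_mm Advisory max isocenter-to-target-centroid
#'   distance (mm).
#' @param mono_iso_tol_mm Max pairwise isocenter spread (mm) for a
#'   mono-isocenter plan.
#' @param srs_jaw_mlc_gap_mm Length-2 allowed band (mm) for the jaw-to-leaf
#'   gap of SRS fields.
#' @param hotspot_threshold_fraction Fixed at 1.10.
#' @param localization_tol_mm Max user-origin-to-localization-point distance
#'   (mm).
#' @return A `policy_config` list.
#' @export
policy_config <- function(slice_thickness_max_mm = c(SRS = 1.25, SBRT = 1.25,
                                                     IMRT_VMAT = 3, THREE_D = 3,
                                                     SIMPLE_2D = 3, ELECTRON = 3),
                          hu_high_z_threshold = 2000,
                          iso_target_offset_max_mm = 50,
                          mono_iso_tol_mm = 0.1,
                          srs_jaw_mlc_gap_mm = c(0, 5),
                          hotspot_threshold_fraction = 1.10,
                          localization_tol_mm = 1) {
  stopifnot(all(slice_thickness_max_mm > 0), hu_high_z_threshold > 0,
            iso_target_offset_max_mm > 0, mono_iso_tol_mm > 0,
            length(srs_jaw_mlc_gap_mm) == 2L,
            srs_jaw_mlc_gap_mm[1] <= srs_jaw_mlc_gap_mm[2],
            identical(as.numeric(hotspot_threshold_fraction), 1.10),
            localization_tol_mm > 0)
  structure(list(slice_thickness_max_mm = slice_thickness_max_mm,
                 hu_high_z_threshold = hu_high_z_threshold,
                 iso_target_offset_max_mm = iso_target_offset_max_mm,
                 mono_iso_tol_mm = mono_iso_tol_mm,
                 srs_jaw_mlc_gap_mm = srs_jaw_mlc_gap_mm,
                 hotspot_threshold_fraction = 1.10,
                 localization_tol_mm = localization_tol_mm),
            class = "policy_config")
}

#' Read a rule-check policy from YAML
#'
#' @param path YAML file with keys matching the arguments of
#'   [policy_config()]; omitted keys keep their defaults.
#' @return A `policy_config`.
#' @export
read_policy_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$slice_thickness_max_mm))
    args$slice_thickness_max_mm <- unlist(y$slice_thickness_max_mm)
  for (k in c("hu_high_z_threshold", "iso_target_offset_max_mm",
              "mono_iso_tol_mm", "hotspot_threshold_fraction",
              "localization_tol_mm")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$srs_jaw_mlc_gap_mm)) args$srs_jaw_mlc_gap_mm <- unlist(y$srs_jaw_mlc_gap_mm)
  do.call(policy_config, args)
}

check_result <- function(check_id, verdict, detail, linked_items = character(0)) {
  verdict <- match.arg(verdict, c("pass", "fail", "not_applicable"))
  structure(list(check_id = check_id, linked_items = linked_items,
                 verdict = verdict, detail = detail),
            class = "check_result")
}

#' @export
print.check_result <- function(x, ...) {
  cat(sprintf("[%s] %s: %s\n", toupper(x$verdict), x$check_id, x$detail))
  invisible(x)
}

#' Fractionation arithmetic check
#'
#' Verifies that the prescribed total dose equals dose per fraction times
#' the number of fractions, within `tol_cGy`.
#'
#' @param rx A [prescription()].
#' @param tol_cGy Allowed absolute mismatch, cGy (default 0).
#' @return A `check_result`.
#' @export
#' @examples
#' check_fractionation(prescription(5040, 180, 28))
check_fractionation <- function(rx, tol_cGy = 0) {
  product <- rx$dose_per_fraction * rx$n_fractions
  diff <- abs(rx$total_dose - product)
  if (diff <= tol_cGy) {
    check_result("fractionation", "pass",
                 sprintf("total %g cGy = %g cGy/fx x %d fx", rx$total_dose,
                         rx$dose_per_fraction, rx$n_fractions))
  } else {
    check_result("fractionation", "fail",
                 sprintf(paste0("total dose %g cGy but %g cGy/fx x %d fx = %g cGy ",
                                "(|diff| %g > tol %g cGy)"),
                         rx$total_dose, rx$dose_per_fraction, rx$n_fractions,
                         product, diff, tol_cGy))
  }
}

#' BB / user origin vs localization point consistency
#'
#' @param user_origin User origin, mm.
#' @param localization_point Localization (BB) point, mm, or `NULL`.
#' @param tol_mm Max Euclidean distance, mm.
#' @return A `check_result`; `not_applicable` when no localization point is
#'   recorded.
#' @export
check_localization_consistency <- function(user_origin, localization_point,
                                           tol_mm = 1) {
  if (is.null(localization_point)) {
    return(check_result("localization_consistency", "not_applicable",
                        "no localization point recorded"))
  }
  d <- sqrt(sum((user_origin - localization_point)^2))
  if (d <= tol_mm) {
    check_result("localization_consistency", "pass",
                 sprintf("user origin to localization point distance %.2f mm", d))
  } else {
    check_result("localization_consistency", "fail",
                 sprintf("distance %.2f mm > tolerance %g mm", d, tol_mm))
  }
}

#' Mono-isocenter check
#'
#' All treatment beams of a mono-isocenter plan must share one isocenter:
#' the maximum pairwise isocenter distance must not exceed `tol_mm`.
#' Vacuously passes for a single beam.
#'
#' @param beams List of [beam()]s; setup beams are ignored.
#' @param tol_mm Max pairwise spread, mm.
#' @return A `check_result`.
#' @export
check_mono_isocenter <- function(beams, tol_mm = 0.1) {
  tx <- Filter(function(b) !b$is_setup_beam, beams)
  if (length(tx) <= 1L) {
    return(check_result("mono_isocenter", "pass",
                        "single treatment beam; spread vacuously 0 mm"))
  }
  isos <- do.call(rbind, lapply(tx, `[[`, "isocenter"))
  dmax <- max(stats::dist(isos))
  if (dmax <= tol_mm) {
    check_result("mono_isocenter", "pass",
                 sprintf("max pairwise isocenter distance %.3f mm", dmax))
  } else {
    check_result("mono_isocenter", "fail",
                 sprintf("max pairwise isocenter distance %.3f mm > tolerance %g mm",
                         dmax, tol_mm))
  }
}

#' Isocenter-to-target-centroid offset check
#'
#' @param isocenter Plan isocenter, mm.
#' @param target One row of [summarize_structures()] for the Target
#'   structure, or `NULL` when the plan has no target.
#' @param max_mm Advisory distance limit, mm.
#' @return A `check_result`.
#' @export
check_isocenter_target_offset <- function(isocenter, target, max_mm = 50) {
  if (is.null(target) || (is.data.frame(target) && nrow(target) == 0L)) {
    return(check_result("isocenter_target_offset", "not_applicable",
                        "no Target structure"))
  }
  if (is.data.frame(target)) target <- as.list(target[1, ])
  if (isTRUE(target$degenerate)) {
    return(check_result("isocenter_target_offset", "not_applicable",
                        "Target structure is degenerate (no contour points)"))
  }
  centroid <- c(target$centroid_x, target$centroid_y, target$centroid_z)
  d <- sqrt(sum((isocenter - centroid)^2))
  if (d <= max_mm) {
    check_result("isocenter_target_offset", "pass",
                 sprintf("isocenter is %.1f mm from target centroid", d))
  } else {
    check_result("isocenter_target_offset", "fail",
                 sprintf("isocenter is %.1f mm from target centroid (> %g mm)",
                         d, max_mm))
  }
}

#' Dose grid coverage of the External contour
#'
#' @param dose_bbox,external_bbox Boxes as `list(min =, max =)` 3-vectors
#'   (mm); `dose_bbox = NULL` when no dose grid is available.
#' @return A `check_result`; fails naming the first uncovered axis.
#' @export
check_dose_grid_covers_external <- function(dose_bbox, external_bbox) {
  if (is.null(dose_bbox)) {
    return(check_result("dose_grid_covers_external", "not_applicable",
                        "no dose grid available"))
  }
  axes <- c("x", "y", "z")
  for (a in 1:3) {
    if (external_bbox$min[a] < dose_bbox$min[a] - 1e-9 ||
        external_bbox$max[a] > dose_bbox$max[a] + 1e-9) {
      return(check_result("dose_grid_covers_external", "fail",
                          sprintf("External extends beyond dose grid on %s axis (External [%g, %g], grid [%g, %g] mm)",
                                  axes[a], external_bbox$min[a], external_bbox$max[a],
                                  dose_bbox$min[a], dose_bbox$max[a])))
    }
  }
  check_result("dose_grid_covers_external", "pass",
               "External bounding box inside dose grid on all axes")
}

#' High-Z / HU screening of the planning CT
#'
#' Fails when the maximum HU inside the External contour exceeds the
#' configured high-Z threshold, flagging the plan for density-override
#' review. Both maxima are always reported.
#'
#' @param hu_stats Output of [compute_hu_stats()].
#' @param cfg A [policy_config()].
#' @return A `check_result`.
#' @export
check_hu_limits <- function(hu_stats, cfg = policy_config()) {
  inside <- hu_stats$max_hu_inside
  outside <- hu_stats$max_hu_outside
  both <- sprintf("max HU inside External %g, outside %s", inside,
                  if (is.na(outside)) "<absent: External covers grid>" else
                    sprintf("%g", outside))
  if (inside > cfg$hu_high_z_threshold) {
    check_result("hu_limits", "fail",
                 sprintf("%s; inside max exceeds high-Z threshold %g HU - review density overrides",
                         both, cfg$hu_high_z_threshold))
  } else {
    check_result("hu_limits", "pass", both)
  }
}

#' CT slice thickness vs planning technique
#'
#' @param technique Plan technique.
#' @param slice_thickness_mm CT slice thickness, mm.
#' @param cfg A [policy_config()] carrying per-technique limits; a technique
#'   missing from the mapping is a policy error.
#' @return A `check_result`.
#' @export
check_slice_thickness <- function(technique, slice_thickness_mm,
                                  cfg = policy_config()) {
  if (!(technique %in% names(cfg$slice_thickness_max_mm))) {
    stop("policy has no slice thickness limit for technique '", technique, "'",
         call. = FALSE)
  }
  lim <- cfg$slice_thickness_max_mm[[technique]]
  if (slice_thickness_mm <= lim) {
    check_result("slice_thickness", "pass",
                 sprintf("%g mm slices within %g mm limit for %s",
                         slice_thickness_mm, lim, technique))
  } else {
    check_result("slice_thickness", "fail",
                 sprintf("%g mm slices exceed %g mm limit for %s",
                         slice_thickness_mm, lim, technique))
  }
}

#' Delta-couch policy check
#'
#' SRS plans require a stored couch shift; all other photon/electron plans
#' require the couch shift cleared (absent or exactly zero).
#'
#' @param technique Plan technique.
#' @param couch_delta Stored couch shift (cm 3-vector) or `NULL`.
#' @return A `check_result`.
#' @export
check_delta_couch <- function(technique, couch_delta) {
  if (technique %in% c("SRS", "SBRT")) {
    if (is.null(couch_delta)) {
      check_result("delta_couch", "fail",
                   sprintf("%s plan requires a stored delta couch but none is recorded",
                           technique))
    } else {
      check_result("delta_couch", "pass",
                   sprintf("delta couch present: (%s) cm",
                           paste(format(couch_delta), collapse = ", ")))
    }
  } else {
    if (is.null(couch_delta) || all(couch_delta == 0)) {
      check_result("delta_couch", "pass", "delta couch cleared")
    } else {
      check_result("delta_couch", "fail",
                   sprintf("non-SRS plan carries a nonzero delta couch (%s) cm",
                           paste(format(couch_delta), collapse = ", ")))
    }
  }
}

#' Jaw-to-MLC-leaf gap check for SRS fields
#'
#' For each control point, the gap between each X jaw and the nearest open
#' leaf tip on that side (leaf pairs open by more than 0.5 mm) must lie in
#' the configured band. Not applicable to non-SRS techniques.
#'
#' @param b A [beam()].
#' @param technique Plan technique.
#' @param cfg A [policy_config()].
#' @return A `check_result`.
#' @export
check_jaw_mlc_gap_srs <- function(b, technique, cfg = policy_config()) {
  if (!(technique %in% c("SRS", "SBRT"))) {
    return(check_result("jaw_mlc_gap_srs", "not_applicable",
                        paste0("technique ", technique, " carries no jaw-MLC gap requirement")))
  }
  lo <- cfg$srs_jaw_mlc_gap_mm[1]; hi <- cfg$srs_jaw_mlc_gap_mm[2]
  worst <- NULL
  for (cp in b$control_points) {
    open <- (cp$mlc_bank_B - cp$mlc_bank_A) > 0.5
    if (!any(open)) next
    jaws <- if (!is.null(cp$jaw_positions)) cp$jaw_positions else b$jaws
    gaps <- c(min(cp$mlc_bank_A[open]) - jaws[["x1"]],
              jaws[["x2"]] - max(cp$mlc_bank_B[open]))
    for (g in gaps) {
      if (is.null(worst) || abs(g - mean(c(lo, hi))) > abs(worst - mean(c(lo, hi))))
        worst <- g
      if (g < lo - 1e-9 || g > hi + 1e-9) {
        return(check_result("jaw_mlc_gap_srs", "fail",
                            sprintf("jaw-to-leaf gap %.1f mm outside allowed [%g, %g] mm",
                                    g, lo, hi)))
      }
    }
  }
  if (is.null(worst)) {
    return(check_result("jaw_mlc_gap_srs", "not_applicable",
                        "no open leaf pairs on this beam"))
  }
  check_result("jaw_mlc_gap_srs", "pass",
               sprintf("all jaw-to-leaf gaps within [%g, %g] mm (extreme %.1f mm)",
                       lo, hi, worst))
}

#' Hotspot check: dose above 110% of prescription
#'
#' Computes the fraction of dose-grid voxels strictly above
#' `hotspot_threshold_fraction` (1.10) times the prescription total dose.
#' Passes iff that fraction is zero; the detail reports the maximum dose
#' and its voxel location either way.
#'
#' @param dose_grid List with `values` (3D cGy array), as from
#'   [generate_dose_grid()].
#' @param rx A [prescription()].
#' @param cfg A [policy_config()].
#' @return A `check_result`; `$detail` names max dose, location and the
#'   hotspot voxel fraction (also attached as attribute
#'   `hotspot_fraction`).
#' @export
check_hotspot <- function(dose_grid, rx, cfg = policy_config()) {
  thr <- cfg$hotspot_threshold_fraction * rx$total_dose
  vals <- dose_grid$values
  n_hot <- sum(vals > thr)  # strictly greater: 110.0% exactly is not a hotspot
  frac <- n_hot / length(vals)
  mx <- max(vals)
  loc <- arrayInd(which.max(vals), dim(vals))
  detail <- sprintf("max dose %g cGy at voxel (%d, %d, %d); %d/%d voxels (fraction %g) above %g cGy (110%% of Rx)",
                    mx, loc[1], loc[2], loc[3], n_hot, length(vals), frac, thr)
  res <- if (n_hot == 0L) check_result("hotspot", "pass", detail)
         else check_result("hotspot", "fail", detail)
  attr(res, "hotspot_fraction") <- frac
  res
}

#' Course name vs prescription template name
#'
#' Passes when the trimmed, case-folded names agree.
#'
#' @param course_name OIS course name.
#' @param template_name Prescription template name.
#' @return A `check_result`.
#' @export
check_course_name <- function(course_name, template_name) {
  a <- tolower(trimws(course_name)); b <- tolower(trimws(template_name))
  if (identical(a, b)) {
    check_result("course_name", "pass",
                 sprintf("course '%s' matches prescription template", course_name))
  } else {
    check_result("course_name", "fail",
                 sprintf("course '%s' does not match prescription template '%s'",
                         course_name, template_name))
  }
}

# illustrative mapping of rule checks onto the packaged checklist's item ids
.check_links <- list(
  plan_comparison = c("TP-14", "TP-15", "TP-16"),
  fractionation = c("PA-01"),
  localization_consistency = c("SIM-06", "SIM-07"),
  mono_isocenter = c("SIM-06"),
  isocenter_target_offset = c("SIM-06", "TP-01"),
  dose_grid_covers_external = c("TP-03"),
  hu_limits = c("TP-04", "SIM-14"),
  slice_thickness = c("SIM-10"),
  delta_couch = c("TP-14"),
  jaw_mlc_gap_srs = c("TP-11"),
  hotspot = c("TP-07"),
  course_name = c("PA-01"),
  attestation_peer_review = c("PA-09"),
  attestation_billing_approval = c("PA-11"),
  attestation_consent_present = c("PA-08")
)

link_items <- function(check_id, checklist) {
  ids <- .check_links[[check_id]]
  if (is.null(ids) || is.null(checklist)) return(character(0))
  intersect(ids, checklist$items$item_id)
}

#' Run the whole automated rule-check battery on a case
#'
#' Orchestrates the TPS-vs-OIS comparison plus every applicable rule check.
#' A check whose required input is missing reports `not_applicable` with a
#' reason and the run continues. Results are keyed by check id and carry the
#' checklist item ids they stand in for (when a checklist is supplied).
#'
#' @param tps,ois The two `plan_snapshot`s.
#' @param structures Optional list of structures (see
#'   [summarize_structures()]).
#' @param ct Optional CT grid ([generate_ct_phantom()] shape).
#' @param dose_grid Optional dose grid ([generate_dose_grid()] shape).
#' @param checklist Optional [load_checklist()] result used to attach item
#'   ids to each check.
#' @param cfg A [policy_config()].
#' @param tol A [tolerance_profile()] for the comparison.
#' @return List with `report` (the `discrepancy_report`) and `checks`
#'   (named list of `check_result`s keyed by check id).
#' @export
run_all <- function(tps, ois, structures = NULL, ct = NULL, dose_grid = NULL,
                    checklist = NULL, cfg = policy_config(),
                    tol = tolerance_profile()) {
  report <- compare_plans(tps, ois, tol)
  checks <- list()
  add <- function(res) {
    res$linked_items <- link_items(res$check_id, checklist)
    checks[[res$check_id]] <<- res
  }

  add(check_fractionation(ois$prescription))
  add(check_localization_consistency(ois$user_origin, ois$localization_point,
                                     cfg$localization_tol_mm))
  add(check_mono_isocenter(ois$beams, cfg$mono_iso_tol_mm))
  add(check_delta_couch(ois$technique, ois$couch_delta))
  add(check_course_name(ois$course_name, ois$prescription$template_name))

  summaries <- if (!is.null(structures)) summarize_structures(structures) else NULL
  target <- if (!is.null(summaries)) summaries[summaries$role == "Target", ] else NULL
  add(check_isocenter_target_offset(ois$beams[[1]]$isocenter, target,
                                    cfg$iso_target_offset_max_mm))

  external <- NULL
  if (!is.null(structures)) {
    ext_idx <- which(vapply(structures, function(s) s$role == "External", TRUE))
    if (length(ext_idx) > 0L) external <- structures[[ext_idx[1]]]
  }

  if (!is.null(ct)) {
    add(check_slice_thickness(ois$technique, ct$spacing[3], cfg))
    if (!is.null(external)) {
      add(check_hu_limits(compute_hu_stats(ct, external), cfg))
    } else {
      add(check_result("hu_limits", "not_applicable", "no External structure"))
    }
  } else {
    add(check_result("slice_thickness", "not_applicable", "no CT available"))
    add(check_result("hu_limits", "not_applicable", "no CT available"))
  }

  if (!is.null(dose_grid)) {
    add(check_hotspot(dose_grid, ois$prescription, cfg))
    if (!is.null(summaries) && "External" %in% summaries$role) {
      ext_row <- summaries[summaries$role == "External", ][1, ]
      ext_bbox <- list(min = c(ext_row$bbox_min_x, ext_row$bbox_min_y, ext_row$bbox_min_z),
                       max = c(ext_row$bbox_max_x, ext_row$bbox_max_y, ext_row$bbox_max_z))
      add(check_dose_grid_covers_external(grid_bbox(dose_grid), ext_bbox))
    } else {
      add(check_result("dose_grid_covers_external", "not_applicable",
                       "no External structure"))
    }
  } else {
    add(check_result("hotspot", "not_applicable", "no dose grid available"))
    add(check_result("dose_grid_covers_external", "not_applicable",
                     "no dose grid available"))
  }

  add(check_jaw_mlc_gap_srs(ois$beams[[1]], ois$technique, cfg))

  if (length(ois$attestations) > 0L) {
    for (nm in names(ois$attestations)) {
      id <- paste0("attestation_", nm)
      res <- if (isTRUE(ois$attestations[[nm]])) {
        check_result(id, "pass", sprintf("'%s' attested in OIS", nm))
      } else {
        check_result(id, "fail", sprintf("'%s' not attested in OIS", nm))
      }
      add(res)
    }
  }

  list(report = report, checks = checks)
}

#' Write rule-check results as JSON keyed by check id
#'
#' @param checks Named list of `check_result`s from [run_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_checks_json <- function(checks, path) {
  payload <- lapply(checks, function(r) {
    list(verdict = ub(r$verdict), detail = ub(r$detail),
         linked_items = r$linked_items)
  })
  writeLines(jsonlite::toJSON(payload, digits = NA, pretty = TRUE), path)
  invisible(path)
}
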