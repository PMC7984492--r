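#' Tolerance profile for plan comparison
#'
#' A tolerance profile maps discrepancy field paths to the numeric tolerance
#' applied there, in the field's own units. The shipped default is zero for
#' everything: any difference between the planning-system export and the
#' record-and-verify export is flagged. Nonzero overrides exist only to
#' absorb known import/export rounding and are matched by field-path glob
#' (`*` matches any run of characters), e.g. `beams[*].mu`. When several
#' globs match a path the last one listed wins.
#'
#' @param default Default tolerance (>= 0); the norm is 0.
#' @param overrides Named numeric vector or list, glob -> tolerance.
#' @return A `tolerance_profile` object.
#' @export
#' @examples
#' tolerance_profile(overrides = c("beams[*].mu" = 0.01))
tolerance_profile <- function(default = 0, overrides = list()) {
  overrides <- unlist(overrides)
  if (length(overrides) > 0 && (is.null(names(overrides)) || any(!nzchar(names(overrides)))))
    stop("tolerance overrides must be named by field-path glob", call. = FALSE)
  if (default < 0 || any(overrides < 0))
    stop("tolerances must be >= 0", call. = FALSE)
  structure(list(default = as.numeric(default),
                 overrides = overrides),
            class = "tolerance_profile")
}

#' Read a tolerance profile from YAML
#'
#' @param path YAML file with keys `default` and `overrides` (a mapping
#'   field-path glob -> tolerance).
#' @return A [tolerance_profile()].
#' @export
read_tolerance_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  tolerance_profile(default = if (is.null(y$default)) 0 else y$default,
                    overrides = if (is.null(y$overrides)) list() else y$overrides)
}

glob_to_regex <- function(glob) {
  # escape regex metacharacters; the glob star becomes .*
  chars <- strsplit(glob, "", fixed = TRUE)[[1]]
  meta <- c(".", "\\", "|", "(", ")", "[", "]", "{", "}", "^", "$", "+", "?")
  esc <- vapply(chars, function(ch) {
    if (ch == "*") ".*" else if (ch %in% meta) paste0("\\", ch) else ch
  }, "", USE.NAMES = FALSE)
  paste0("^", paste(esc, collapse = ""), "$")
}

tolerance_for <- function(tol, field_path) {
  val <- tol$default
  if (length(tol$overrides) > 0L) {
    for (k in seq_along(tol$overrides)) {
      if (grepl(glob_to_regex(names(tol$overrides)[k]), field_path)) {
        val <- unname(tol$overrides[[k]])
      }
    }
  }
  val
}

#' Smallest angular separation between two angles
#'
#' Gantry, collimator and couch angles live on a circle; 359.9 and 0.1
#' degrees differ by 0.2 degrees, not 359.8. Differences are reduced to
#' `[0, 180]`.
#'
#' @param a,b Angles in degrees `[0, 360)`.
#' @return Absolute angular difference in degrees, in `[0, 180]`.
#' @export
#' @examples
#' angle_difference(359.8, 0.1)
angle_difference <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

new_discrepancy <- function(field_path, tps_value, ois_value,
                            abs_difference = NA_real_,
                            tolerance_applied = NA_real_,
                            severity = c("out_of_tolerance", "structural")) {
  severity <- match.arg(severity)
  list(field_path = field_path,
       tps_value = tps_value, ois_value = ois_value,
       abs_difference = abs_difference,
       tolerance_applied = tolerance_applied,
       severity = severity)
}

# mutable collector shared by the comparison walkers
new_collector <- function(tol) {
  env <- new.env(parent = emptyenv())
  env$found <- list()
  env$tol <- tol
  env
}

emit <- function(col, d) col$found[[length(col$found) + 1L]] <- d

cmp_numeric <- function(col, path, tv, ov, circular = FALSE) {
  d <- if (circular) angle_difference(tv, ov) else abs(tv - ov)
  tl <- tolerance_for(col$tol, path)
  if (d > tl) {
    emit(col, new_discrepancy(path, tv, ov, abs_difference = d,
                              tolerance_applied = tl))
  }
}

cmp_vector <- function(col, path, tv, ov) {
  if (length(tv) != length(ov)) {
    emit(col, new_discrepancy(path, length(tv), length(ov),
                              severity = "structural"))
    return(invisible(NULL))
  }
  for (i in seq_along(tv)) {
    cmp_numeric(col, sprintf("%s[%d]", path, i), tv[i], ov[i])
  }
}

cmp_categorical <- function(col, path, tv, ov) {
  a <- trimws(as.character(tv)); b <- trimws(as.character(ov))
  if (!identical(a, b)) {
    emit(col, new_discrepancy(path, tv, ov))
  }
}

# presence comparison; returns TRUE when both sides are present
cmp_presence <- function(col, path, tv, ov) {
  if (is.null(tv) != is.null(ov)) {
    emit(col, new_discrepancy(path,
                              if (is.null(tv)) "<absent>" else tv,
                              if (is.null(ov)) "<absent>" else ov,
                              severity = "structural"))
    return(FALSE)
  }
  !is.null(tv)
}

cmp_control_points <- function(col, base, tcps, ocps) {
  if (length(tcps) != length(ocps)) {
    emit(col, new_discrepancy(paste0(base, ".control_points"),
                              length(tcps), length(ocps),
                              severity = "structural"))
    return(invisible(NULL))
  }
  for (j in seq_along(tcps)) {
    tcp <- tcps[[j]]; ocp <- ocps[[j]]
    cpp <- sprintf("%s.control_points[%d]", base, j)
    cmp_numeric(col, paste0(cpp, ".cumulative_weight"),
                tcp$cumulative_weight, ocp$cumulative_weight)
    cmp_numeric(col, paste0(cpp, ".gantry_angle"),
                tcp$gantry_angle, ocp$gantry_angle, circular = TRUE)
    if (length(tcp$mlc_bank_A) != length(ocp$mlc_bank_A) ||
        length(tcp$mlc_bank_B) != length(ocp$mlc_bank_B)) {
      emit(col, new_discrepancy(paste0(cpp, ".mlc"),
                                length(tcp$mlc_bank_A), length(ocp$mlc_bank_A),
                                severity = "structural"))
    } else {
      cmp_vector(col, paste0(cpp, ".mlc_bank_A"), tcp$mlc_bank_A, ocp$mlc_bank_A)
      cmp_vector(col, paste0(cpp, ".mlc_bank_B"), tcp$mlc_bank_B, ocp$mlc_bank_B)
    }
    if (cmp_presence(col, paste0(cpp, ".jaw_positions"),
                     tcp$jaw_positions, ocp$jaw_positions)) {
      for (k in seq_along(.jaw_names)) {
        cmp_numeric(col, sprintf("%s.jaw_positions.%s", cpp, .jaw_names[k]),
                    tcp$jaw_positions[[k]], ocp$jaw_positions[[k]])
      }
    }
  }
}

cmp_beam <- function(col, base, tb, ob) {
  cmp_categorical(col, paste0(base, ".radiation_type"), tb$radiation_type, ob$radiation_type)
  cmp_categorical(col, paste0(base, ".energy"), tb$energy, ob$energy)
  cmp_numeric(col, paste0(base, ".mu"), tb$mu, ob$mu)
  cmp_vector(col, paste0(base, ".isocenter"), tb$isocenter, ob$isocenter)
  cmp_numeric(col, paste0(base, ".gantry_angle"), tb$gantry_angle, ob$gantry_angle,
              circular = TRUE)
  cmp_categorical(col, paste0(base, ".gantry_rotation_direction"),
                  tb$gantry_rotation_direction, ob$gantry_rotation_direction)
  cmp_numeric(col, paste0(base, ".collimator_angle"), tb$collimator_angle,
              ob$collimator_angle, circular = TRUE)
  cmp_numeric(col, paste0(base, ".couch_angle"), tb$couch_angle, ob$couch_angle,
              circular = TRUE)
  for (k in seq_along(.jaw_names)) {
    cmp_numeric(col, sprintf("%s.jaws.%s", base, .jaw_names[k]),
                tb$jaws[[k]], ob$jaws[[k]])
  }
  if (cmp_presence(col, paste0(base, ".ssd"), tb$ssd, ob$ssd)) {
    cmp_numeric(col, paste0(base, ".ssd"), tb$ssd, ob$ssd)
  }
  if (cmp_presence(col, paste0(base, ".wedge"), tb$wedge, ob$wedge)) {
    cmp_categorical(col, paste0(base, ".wedge"), tb$wedge, ob$wedge)
  }
  cmp_categorical(col, paste0(base, ".bolus_linked"), tb$bolus_linked, ob$bolus_linked)
  if (cmp_presence(col, paste0(base, ".applicator"), tb$applicator, ob$applicator)) {
    cmp_categorical(col, paste0(base, ".applicator"), tb$applicator, ob$applicator)
  }
  cmp_categorical(col, paste0(base, ".is_setup_beam"), tb$is_setup_beam, ob$is_setup_beam)
  cmp_control_points(col, base, tb$control_points, ob$control_points)
}

#' Compare the MLC apertures of two matched beams
#'
#' Aligns control points by index. A mismatch in control-point count or
#' leaf count is a structural discrepancy and suppresses per-leaf
#' comparison; otherwise every leaf of both banks is compared at
#' `tol_mm` and the maximum absolute leaf deviation is returned.
#'
#' @param tps_beam,ois_beam Matched [beam()]s.
#' @param tol_mm Per-leaf tolerance in mm (default 0).
#' @param base_path Field-path prefix used in emitted discrepancies.
#' @return List with `max_leaf_deviation` (mm; 0 when structure differs)
#'   and `discrepancies`.
#' @export
compare_mlc <- function(tps_beam, ois_beam, tol_mm = 0,
                        base_path = "beams[1]") {
  tol <- tolerance_profile(default = tol_mm)
  col <- new_collector(tol)
  cmp_control_points(col, base_path, tps_beam$control_points,
                     ois_beam$control_points)
  leaf <- grepl("mlc_bank_[AB]\\[", vapply(col$found, `[[`, "", "field_path"))
  max_dev <- 0
  if (length(tps_beam$control_points) == length(ois_beam$control_points)) {
    devs <- unlist(lapply(seq_along(tps_beam$control_points), function(j) {
      tcp <- tps_beam$control_points[[j]]; ocp <- ois_beam$control_points[[j]]
      if (length(tcp$mlc_bank_A) == length(ocp$mlc_bank_A) &&
          length(tcp$mlc_bank_B) == length(ocp$mlc_bank_B)) {
        c(abs(tcp$mlc_bank_A - ocp$mlc_bank_A), abs(tcp$mlc_bank_B - ocp$mlc_bank_B))
      } else numeric(0)
    }))
    if (length(devs) > 0) max_dev <- max(devs)
  }
  structural <- vapply(col$found, `[[`, "", "severity") == "structural"
  list(max_leaf_deviation = max_dev,
       discrepancies = col$found[leaf | structural])
}

#' Compare a TPS plan snapshot against its OIS counterpart
#'
#' Field-by-field comparison of the two exports of one plan under a
#' tolerance profile. Numeric fields are flagged when the absolute
#' difference exceeds the applicable tolerance (angles on the circle);
#' categorical fields when trimmed strings differ; structure (beam sets,
#' control-point counts, presence of optional fields) when it differs at
#' all. Beams are matched by `beam_name`, not by list order; a beam present
#' on one side only, or a duplicated beam name, is a structural
#' discrepancy. The report is deterministic and ordered by snapshot field
#' order.
#'
#' @param tps,ois `plan_snapshot`s of the same plan from the two systems.
#' @param tol A [tolerance_profile()]; defaults to all-zero.
#' @return A `discrepancy_report`: plan identity from both sides, the
#'   ordered discrepancy list, and `clean` (TRUE iff no discrepancies).
#' @export
#' @examples
#' pair <- generate_plan_pair(seed = 1, technique = "IMRT_VMAT", n_beams = 2)
#' compare_plans(pair$tps, pair$ois)$clean
compare_plans <- function(tps, ois, tol = tolerance_profile()) {
  validate_snapshot(tps)
  validate_snapshot(ois)
  stopifnot(inherits(tol, "tolerance_profile"))
  col <- new_collector(tol)

  cmp_categorical(col, "patient_id", tps$patient_id, ois$patient_id)
  cmp_categorical(col, "plan_name", tps$plan_name, ois$plan_name)
  cmp_categorical(col, "plan_label", tps$plan_label, ois$plan_label)
  cmp_categorical(col, "approval_status", tps$approval_status, ois$approval_status)
  cmp_categorical(col, "course_name", tps$course_name, ois$course_name)
  cmp_categorical(col, "patient_position", tps$patient_position, ois$patient_position)
  cmp_categorical(col, "technique", tps$technique, ois$technique)
  cmp_categorical(col, "machine_name", tps$machine_name, ois$machine_name)
  cmp_categorical(col, "tolerance_table_name", tps$tolerance_table_name,
                  ois$tolerance_table_name)

  trx <- tps$prescription; orx <- ois$prescription
  cmp_numeric(col, "prescription.total_dose", trx$total_dose, orx$total_dose)
  cmp_numeric(col, "prescription.dose_per_fraction", trx$dose_per_fraction,
              orx$dose_per_fraction)
  cmp_numeric(col, "prescription.n_fractions", trx$n_fractions, orx$n_fractions)
  cmp_categorical(col, "prescription.template_name", trx$template_name, orx$template_name)
  cmp_categorical(col, "prescription.approval", trx$approval, orx$approval)
  cmp_categorical(col, "prescription.site", trx$site, orx$site)
  cmp_categorical(col, "prescription.fractionation_pattern",
                  trx$fractionation_pattern, orx$fractionation_pattern)
  if (cmp_presence(col, "prescription.image_technique",
                   trx$image_technique, orx$image_technique)) {
    cmp_categorical(col, "prescription.image_technique",
                    trx$image_technique, orx$image_technique)
  }
  if (cmp_presence(col, "prescription.bolus_spec", trx$bolus_spec, orx$bolus_spec)) {
    cmp_numeric(col, "prescription.bolus_spec.thickness_mm",
                trx$bolus_spec$thickness_mm, orx$bolus_spec$thickness_mm)
    cmp_categorical(col, "prescription.bolus_spec.type",
                    trx$bolus_spec$type, orx$bolus_spec$type)
    cmp_categorical(col, "prescription.bolus_spec.frequency",
                    trx$bolus_spec$frequency, orx$bolus_spec$frequency)
  }

  cmp_vector(col, "user_origin", tps$user_origin, ois$user_origin)
  if (cmp_presence(col, "localization_point", tps$localization_point,
                   ois$localization_point)) {
    cmp_vector(col, "localization_point", tps$localization_point,
               ois$localization_point)
  }
  if (cmp_presence(col, "couch_delta", tps$couch_delta, ois$couch_delta)) {
    cmp_vector(col, "couch_delta", tps$couch_delta, ois$couch_delta)
  }

  tnames <- vapply(tps$beams, `[[`, "", "beam_name")
  onames <- vapply(ois$beams, `[[`, "", "beam_name")
  for (nm in unique(c(tnames[duplicated(tnames)], onames[duplicated(onames)]))) {
    emit(col, new_discrepancy(sprintf("beams[name=%s]", nm),
                              sum(tnames == nm), sum(onames == nm),
                              severity = "structural"))
  }
  if (!any(duplicated(tnames)) && !any(duplicated(onames))) {
    for (nm in setdiff(tnames, onames)) {
      emit(col, new_discrepancy(sprintf("beams[name=%s]", nm), "present",
                                "<absent>", severity = "structural"))
    }
    for (nm in setdiff(onames, tnames)) {
      emit(col, new_discrepancy(sprintf("beams[name=%s]", nm), "<absent>",
                                "present", severity = "structural"))
    }
    for (i in seq_along(tnames)) {
      if (tnames[i] %in% onames) {
        cmp_beam(col, sprintf("beams[%d]", i), tps$beams[[i]],
                 ois$beams[[which(onames == tnames[i])]])
      }
    }
  }

  t_att <- tps$attestations; o_att <- ois$attestations
  for (nm in union(names(t_att), names(o_att))) {
    pth <- paste0("attestations.", nm)
    if (!(nm %in% names(t_att)) || !(nm %in% names(o_att))) {
      emit(col, new_discrepancy(pth,
                                if (nm %in% names(t_att)) t_att[[nm]] else "<absent>",
                                if (nm %in% names(o_att)) o_att[[nm]] else "<absent>",
                                severity = "structural"))
    } else {
      cmp_categorical(col, pth, t_att[[nm]], o_att[[nm]])
    }
  }

  structure(list(
    patient_id = tps$patient_id,
    tps_plan = list(plan_name = tps$plan_name, plan_label = tps$plan_label,
                    approval_status = tps$approval_status),
    ois_plan = list(plan_name = ois$plan_name, plan_label = ois$plan_label,
                    approval_status = ois$approval_status),
    discrepancies = col$found,
    clean = length(col$found) == 0L
  ), class = "discrepancy_report")
}

#' Discrepancies of a report as a data frame
#'
#' @param report A `discrepancy_report` from [compare_plans()].
#' @return data.frame with one row per discrepancy (values as character).
#' @export
discrepancies_df <- function(report) {
  stopifnot(inherits(report, "discrepancy_report"))
  if (length(report$discrepancies) == 0L) {
    return(data.frame(field_path = character(0), tps_value = character(0),
                      ois_value = character(0), abs_difference = numeric(0),
                      tolerance_applied = numeric(0), severity = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(report$discrepancies, function(d) {
    data.frame(field_path = d$field_path,
               tps_value = paste(format(d$tps_value), collapse = ","),
               ois_value = paste(format(d$ois_value), collapse = ","),
               abs_difference = d$abs_difference,
               tolerance_applied = d$tolerance_applied,
               severity = d$severity, stringsAsFactors = FALSE)
  }))
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat("TPS vs OIS plan comparison - patient", x$patient_id, "\n")
  cat("  TPS:", x$tps_plan$plan_name, sprintf("[%s]", x$tps_plan$approval_status),
      "| OIS:", x$ois_plan$plan_name, sprintf("[%s]", x$ois_plan$approval_status), "\n")
  if (x$clean) {
    cat("  CLEAN: no discrepancies\n")
  } else {
    cat(sprintf("  %d discrepanc%s:\n", length(x$discrepancies),
                if (length(x$discrepancies) == 1L) "y" else "ies"))
    df <- discrepancies_df(x)
    for (i in seq_len(nrow(df))) {
      cat(sprintf("   - %-55s %s TPS=%s OIS=%s", df$field_path[i],
                  df$severity[i], df$tps_value[i], df$ois_value[i]))
      if (!is.na(df$abs_difference[i]))
        cat(sprintf(" |d|=%g tol=%g", df$abs_difference[i], df$tolerance_applied[i]))
      cat("\n")
    }
  }
  invisible(x)
}

#' Write a discrepancy report as JSON
#'
#' @param report A `discrepancy_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "discrepancy_report"))
  payload <- list(
    format = ub("chartcheckr-discrepancy-report"),
    patient_id = ub(report$patient_id),
    tps_plan = lapply(report$tps_plan, ub),
    ois_plan = lapply(report$ois_plan, ub),
    clean = ub(report$clean),
    discrepancies = lapply(report$discrepancies, function(d) {
      out <- list(field_path = ub(d$field_path),
                  tps_value = ub(paste(format(d$tps_value), collapse = ",")),
                  ois_value = ub(paste(format(d$ois_value), collapse = ",")),
                  severity = ub(d$severity))
      if (!is.na(d$abs_difference)) {
        out$abs_difference <- ub(d$abs_difference)
        out$tolerance_applied <- ub(d$tolerance_applied)
      }
      out
    })
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' Field paths flagged by a report
#'
#' @param report A `discrepancy_report`.
#' @return Character vector of flagged field paths (possibly empty).
#' @export
flagged_paths <- function(report) {
  vapply(report$discrepancies, `[[`, "", "field_path")
}
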