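#' @importFrom stats setNames
NULL

.techniques <- c("IMRT_VMAT", "THREE_D", "SIMPLE_2D", "SRS", "SBRT", "ELECTRON")
.systems <- c("TPS", "OIS")
.radiation_types <- c("photon", "electron")
.rotation_directions <- c("CW", "CCW", "NONE")
.jaw_names <- c("x1", "x2", "y1", "y2")

#' Construct a control point
#'
#' One sampled machine state of a dynamic (or static) delivery: cumulative
#' meterset weight, gantry angle and the MLC aperture at that instant.
#' Leaf positions are millimetres in the IEC beam-limiting-device frame;
#' bank A and bank B must have equal leaf counts and, per leaf pair,
#' bank A must not cross bank B.
#'
#' @param index Zero-based control point index.
#' @param cumulative_weight Cumulative meterset weight in `[0, 1]`.
#' @param mlc_bank_A,mlc_bank_B Numeric leaf position vectors (mm).
#' @param gantry_angle Gantry angle in degrees `[0, 360)`.
#' @param jaw_positions Optional named vector `(x1, x2, y1, y2)` in mm, or
#'   `NULL` when jaws do not move per control point.
#' @return A `control_point` list.
#' @export
control_point <- function(index, cumulative_weight, mlc_bank_A, mlc_bank_B,
                          gantry_angle = 0, jaw_positions = NULL) {
  structure(list(
    index = as.integer(index),
    cumulative_weight = as.numeric(cumulative_weight),
    gantry_angle = as.numeric(gantry_angle),
    mlc_bank_A = as.numeric(mlc_bank_A),
    mlc_bank_B = as.numeric(mlc_bank_B),
    jaw_positions = if (is.null(jaw_positions)) NULL else
      setNames(as.numeric(jaw_positions), .jaw_names)
  ), class = "control_point")
}

#' Construct a treatment or setup beam
#'
#' @param beam_name Beam identifier; beams are matched across systems by
#'   this name, so it must be unique within a plan.
#' @param radiation_type `"photon"` or `"electron"`.
#' @param energy Energy label as the machine spells it (e.g. `"6X"`, `"9E"`).
#' @param mu Monitor units (>= 0).
#' @param isocenter Isocenter, mm, DICOM patient coordinate system.
#' @param gantry_angle,collimator_angle,couch_angle IEC 61217 degrees.
#' @param gantry_rotation_direction `"CW"`, `"CCW"` or `"NONE"`.
#' @param jaws Named numeric `(x1, x2, y1, y2)`, mm.
#' @param control_points List of [control_point()]s; nonempty for treatment
#'   beams.
#' @param ssd Source-skin distance in mm, or `NULL` when not recorded.
#' @param wedge Wedge identifier, or `NULL` for an open field.
#' @param bolus_linked Whether a bolus is attached to the beam.
#' @param applicator Electron applicator identifier, or `NULL`.
#' @param is_setup_beam Setup (imaging) beams carry no meterset and are
#'   exempt from treatment-beam invariants.
#' @return A `beam` list.
#' @export
beam <- function(beam_name, radiation_type = "photon", energy = "6X", mu = 100,
                 isocenter = c(0, 0, 0), gantry_angle = 0,
                 gantry_rotation_direction = "NONE", collimator_angle = 0,
                 couch_angle = 0, jaws = c(x1 = -50, x2 = 50, y1 = -50, y2 = 50),
                 control_points = list(), ssd = NULL, wedge = NULL,
                 bolus_linked = FALSE, applicator = NULL,
                 is_setup_beam = FALSE) {
  structure(list(
    beam_name = as.character(beam_name),
    radiation_type = radiation_type,
    energy = as.character(energy),
    mu = as.numeric(mu),
    isocenter = as.numeric(isocenter),
    gantry_angle = as.numeric(gantry_angle),
    gantry_rotation_direction = gantry_rotation_direction,
    collimator_angle = as.numeric(collimator_angle),
    couch_angle = as.numeric(couch_angle),
    jaws = setNames(as.numeric(jaws), .jaw_names),
    ssd = if (is.null(ssd)) NULL else as.numeric(ssd),
    wedge = if (is.null(wedge)) NULL else as.character(wedge),
    bolus_linked = isTRUE(bolus_linked),
    applicator = if (is.null(applicator)) NULL else as.character(applicator),
    is_setup_beam = isTRUE(is_setup_beam),
    control_points = control_points
  ), class = "beam")
}

#' Construct a prescription record
#'
#' Doses are centigray. `total_dose` and `dose_per_fraction * n_fractions`
#' are stored independently on purpose: their agreement is a rule check
#' ([check_fractionation()]), not a constructor invariant.
#'
#' @param total_dose Total prescribed dose, cGy (> 0).
#' @param dose_per_fraction Dose per fraction, cGy (> 0).
#' @param n_fractions Number of fractions (>= 1).
#' @param template_name Prescription template name.
#' @param approval Whether the prescription is approved.
#' @param site Treatment site label.
#' @param fractionation_pattern e.g. `"QD"`, `"BID"`.
#' @param image_technique Imaging technique ordered with the prescription,
#'   or `NULL`.
#' @param bolus_spec `NULL` or `list(thickness_mm=, type=, frequency=)`.
#' @return A `prescription` list.
#' @export
prescription <- function(total_dose, dose_per_fraction, n_fractions,
                         template_name = "Generic", approval = TRUE,
                         site = "PELVIS", fractionation_pattern = "QD",
                         image_technique = NULL, bolus_spec = NULL) {
  stopifnot(total_dose > 0, dose_per_fraction > 0, n_fractions >= 1)
  structure(list(
    total_dose = as.numeric(total_dose),
    dose_per_fraction = as.numeric(dose_per_fraction),
    n_fractions = as.integer(n_fractions),
    template_name = as.character(template_name),
    approval = isTRUE(approval),
    site = as.character(site),
    fractionation_pattern = as.character(fractionation_pattern),
    image_technique = if (is.null(image_technique)) NULL else as.character(image_technique),
    bolus_spec = bolus_spec
  ), class = "prescription")
}

#' Construct a plan snapshot
#'
#' The comparable content of one RT plan as exported by one system — the
#' planning system (TPS) or the record-and-verify system (OIS). Two
#' snapshots of the same plan from the two systems are the inputs to
#' [compare_plans()].
#'
#' @param system `"TPS"` or `"OIS"`.
#' @param patient_id Patient identifier.
#' @param plan_name,plan_label Plan identifiers.
#' @param approval_status Plan approval status string.
#' @param course_name Course identifier in the OIS.
#' @param patient_position Patient position code (e.g. `"HFS"`).
#' @param technique One of `IMRT_VMAT, THREE_D, SIMPLE_2D, SRS, SBRT,
#'   ELECTRON`.
#' @param machine_name Treatment machine identifier.
#' @param tolerance_table_name Machine tolerance table assigned to the plan.
#' @param prescription A [prescription()].
#' @param beams List of [beam()]s (at least one for comparison).
#' @param user_origin User origin, mm, DICOM patient coordinates.
#' @param localization_point BB/localization point, mm, or `NULL`.
#' @param couch_delta Stored couch shift (cm, 3-vector) or `NULL` when
#'   cleared.
#' @param attestations Named logical vector of workflow attestations
#'   recorded in the OIS (e.g. `c(peer_review = TRUE)`).
#' @return A `plan_snapshot` list.
#' @export
plan_snapshot <- function(system, patient_id, plan_name, plan_label = plan_name,
                          approval_status = "Approved", course_name = "C1",
                          patient_position = "HFS", technique = "IMRT_VMAT",
                          machine_name = "TB1",
                          tolerance_table_name = "T1", prescription,
                          beams, user_origin = c(0, 0, 0),
                          localization_point = NULL, couch_delta = NULL,
                          attestations = logical(0)) {
  structure(list(
    system = system,
    patient_id = as.character(patient_id),
    plan_name = as.character(plan_name),
    plan_label = as.character(plan_label),
    approval_status = as.character(approval_status),
    course_name = as.character(course_name),
    patient_position = as.character(patient_position),
    technique = technique,
    machine_name = as.character(machine_name),
    tolerance_table_name = as.character(tolerance_table_name),
    prescription = prescription,
    beams = beams,
    user_origin = as.numeric(user_origin),
    localization_point = if (is.null(localization_point)) NULL else
      as.numeric(localization_point),
    couch_delta = if (is.null(couch_delta)) NULL else as.numeric(couch_delta),
    attestations = attestations
  ), class = "plan_snapshot")
}

#' @export
print.plan_snapshot <- function(x, ...) {
  cat("<plan_snapshot>", x$system, "patient", x$patient_id, "plan",
      x$plan_name, "-", length(x$beams), "beam(s),", x$technique, "\n")
  invisible(x)
}

# --- validation ------------------------------------------------------------

fail_at <- function(pointer, msg) {
  stop(sprintf("snapshot validation error at %s: %s", pointer, msg),
       call. = FALSE)
}

check_num <- function(x, pointer, len = 1L, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    fail_at(pointer, "required numeric field missing")
  }
  if (!is.numeric(x)) fail_at(pointer, paste0("expected number, got ", class(x)[1]))
  if (!is.null(len) && length(x) != len)
    fail_at(pointer, sprintf("expected length %d, got %d", len, length(x)))
  if (any(!is.finite(x))) fail_at(pointer, "non-finite value")
  invisible(NULL)
}

check_str <- function(x, pointer, allow_null = FALSE, oneof = NULL) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    fail_at(pointer, "required string field missing")
  }
  if (!is.character(x) || length(x) != 1L)
    fail_at(pointer, "expected a single string")
  if (!is.null(oneof) && !(x %in% oneof))
    fail_at(pointer, paste0("'", x, "' not one of {", paste(oneof, collapse = ", "), "}"))
  invisible(NULL)
}

#' Validate a plan snapshot
#'
#' Checks required fields, enumerations, coordinate finiteness, control
#' point monotonicity and MLC bank consistency. Errors carry a JSON-pointer
#' style path to the offending field.
#'
#' @param snapshot A `plan_snapshot`.
#' @return `snapshot`, invisibly, if valid; otherwise an error.
#' @export
validate_snapshot <- function(snapshot) {
  s <- snapshot
  if (!is.list(s)) fail_at("/", "snapshot is not an object")
  check_str(s$system, "/system", oneof = .systems)
  check_str(s$patient_id, "/patient_id")
  check_str(s$plan_name, "/plan_name")
  check_str(s$plan_label, "/plan_label")
  check_str(s$approval_status, "/approval_status")
  check_str(s$course_name, "/course_name")
  check_str(s$patient_position, "/patient_position")
  check_str(s$technique, "/technique", oneof = .techniques)
  check_str(s$machine_name, "/machine_name")
  check_str(s$tolerance_table_name, "/tolerance_table_name")
  check_num(s$user_origin, "/user_origin", len = 3L)
  check_num(s$localization_point, "/localization_point", len = 3L, allow_null = TRUE)
  check_num(s$couch_delta, "/couch_delta", len = 3L, allow_null = TRUE)

  rx <- s$prescription
  if (is.null(rx)) fail_at("/prescription", "required field missing")
  check_num(rx$total_dose, "/prescription/total_dose")
  check_num(rx$dose_per_fraction, "/prescription/dose_per_fraction")
  check_num(rx$n_fractions, "/prescription/n_fractions")
  if (rx$total_dose <= 0) fail_at("/prescription/total_dose", "must be > 0")
  if (rx$dose_per_fraction <= 0) fail_at("/prescription/dose_per_fraction", "must be > 0")
  if (rx$n_fractions < 1) fail_at("/prescription/n_fractions", "must be >= 1")
  check_str(rx$template_name, "/prescription/template_name")
  if (!is.logical(rx$approval)) fail_at("/prescription/approval", "expected boolean")
  check_str(rx$site, "/prescription/site")
  check_str(rx$fractionation_pattern, "/prescription/fractionation_pattern")
  check_str(rx$image_technique, "/prescription/image_technique", allow_null = TRUE)
  if (!is.null(rx$bolus_spec)) {
    check_num(rx$bolus_spec$thickness_mm, "/prescription/bolus_spec/thickness_mm")
    check_str(rx$bolus_spec$type, "/prescription/bolus_spec/type")
    check_str(rx$bolus_spec$frequency, "/prescription/bolus_spec/frequency")
  }

  if (is.null(s$beams) || length(s$beams) == 0L)
    fail_at("/beams", "at least one beam required")
  for (i in seq_along(s$beams)) {
    b <- s$beams[[i]]
    bp <- sprintf("/beams/%d", i - 1L)
    check_str(b$beam_name, paste0(bp, "/beam_name"))
    check_str(b$radiation_type, paste0(bp, "/radiation_type"), oneof = .radiation_types)
    check_str(b$energy, paste0(bp, "/energy"))
    check_num(b$mu, paste0(bp, "/mu"))
    if (b$mu < 0) fail_at(paste0(bp, "/mu"), "must be >= 0")
    check_num(b$isocenter, paste0(bp, "/isocenter"), len = 3L)
    check_num(b$gantry_angle, paste0(bp, "/gantry_angle"))
    if (b$gantry_angle < 0 || b$gantry_angle >= 360)
      fail_at(paste0(bp, "/gantry_angle"), "must be in [0, 360)")
    check_str(b$gantry_rotation_direction, paste0(bp, "/gantry_rotation_direction"),
              oneof = .rotation_directions)
    check_num(b$collimator_angle, paste0(bp, "/collimator_angle"))
    check_num(b$couch_angle, paste0(bp, "/couch_angle"))
    check_num(b$jaws, paste0(bp, "/jaws"), len = 4L)
    check_num(b$ssd, paste0(bp, "/ssd"), allow_null = TRUE)
    check_str(b$wedge, paste0(bp, "/wedge"), allow_null = TRUE)
    if (!is.logical(b$bolus_linked)) fail_at(paste0(bp, "/bolus_linked"), "expected boolean")
    check_str(b$applicator, paste0(bp, "/applicator"), allow_null = TRUE)
    if (!is.logical(b$is_setup_beam)) fail_at(paste0(bp, "/is_setup_beam"), "expected boolean")
    if (!b$is_setup_beam && length(b$control_points) == 0L)
      fail_at(paste0(bp, "/control_points"), "treatment beam needs control points")
    prev_w <- -Inf
    for (j in seq_along(b$control_points)) {
      cp <- b$control_points[[j]]
      cpp <- sprintf("%s/control_points/%d", bp, j - 1L)
      check_num(cp$cumulative_weight, paste0(cpp, "/cumulative_weight"))
      if (cp$cumulative_weight < 0 || cp$cumulative_weight > 1)
        fail_at(paste0(cpp, "/cumulative_weight"), "must be in [0, 1]")
      if (cp$cumulative_weight < prev_w)
        fail_at(paste0(cpp, "/cumulative_weight"), "cumulative weights must be nondecreasing")
      prev_w <- cp$cumulative_weight
      check_num(cp$gantry_angle, paste0(cpp, "/gantry_angle"))
      check_num(cp$mlc_bank_A, paste0(cpp, "/mlc_bank_A"), len = NULL)
      check_num(cp$mlc_bank_B, paste0(cpp, "/mlc_bank_B"), len = NULL)
      if (length(cp$mlc_bank_A) != length(cp$mlc_bank_B))
        fail_at(paste0(cpp, "/mlc_bank_B"), "bank A and bank B leaf counts differ")
      if (any(cp$mlc_bank_A > cp$mlc_bank_B + 1e-9))
        fail_at(paste0(cpp, "/mlc_bank_A"), "leaf banks cross (A > B)")
      check_num(cp$jaw_positions, paste0(cpp, "/jaw_positions"), len = 4L,
                allow_null = TRUE)
    }
  }
  invisible(snapshot)
}

# --- JSON dialect ----------------------------------------------------------

ub <- jsonlite::unbox

snapshot_to_jsonable <- function(s) {
  cp_j <- function(cp) {
    out <- list(
      index = ub(cp$index),
      cumulative_weight = ub(cp$cumulative_weight),
      gantry_angle = ub(cp$gantry_angle),
      mlc_bank_A = cp$mlc_bank_A,
      mlc_bank_B = cp$mlc_bank_B
    )
    if (!is.null(cp$jaw_positions)) out$jaw_positions <- unname(cp$jaw_positions)
    out
  }
  beam_j <- function(b) {
    out <- list(
      beam_name = ub(b$beam_name), radiation_type = ub(b$radiation_type),
      energy = ub(b$energy), mu = ub(b$mu), isocenter = b$isocenter,
      gantry_angle = ub(b$gantry_angle),
      gantry_rotation_direction = ub(b$gantry_rotation_direction),
      collimator_angle = ub(b$collimator_angle),
      couch_angle = ub(b$couch_angle), jaws = unname(b$jaws),
      bolus_linked = ub(b$bolus_linked), is_setup_beam = ub(b$is_setup_beam),
      control_points = lapply(b$control_points, cp_j)
    )
    if (!is.null(b$ssd)) out$ssd <- ub(b$ssd)
    if (!is.null(b$wedge)) out$wedge <- ub(b$wedge)
    if (!is.null(b$applicator)) out$applicator <- ub(b$applicator)
    out
  }
  rx <- s$prescription
  rx_j <- list(
    total_dose = ub(rx$total_dose), dose_per_fraction = ub(rx$dose_per_fraction),
    n_fractions = ub(rx$n_fractions), template_name = ub(rx$template_name),
    approval = ub(rx$approval), site = ub(rx$site),
    fractionation_pattern = ub(rx$fractionation_pattern)
  )
  if (!is.null(rx$image_technique)) rx_j$image_technique <- ub(rx$image_technique)
  if (!is.null(rx$bolus_spec)) {
    rx_j$bolus_spec <- list(thickness_mm = ub(rx$bolus_spec$thickness_mm),
                            type = ub(rx$bolus_spec$type),
                            frequency = ub(rx$bolus_spec$frequency))
  }
  out <- list(
    format = ub("chartcheckr-plan-snapshot"), format_version = ub(1L),
    system = ub(s$system), patient_id = ub(s$patient_id),
    plan_name = ub(s$plan_name), plan_label = ub(s$plan_label),
    approval_status = ub(s$approval_status), course_name = ub(s$course_name),
    patient_position = ub(s$patient_position), technique = ub(s$technique),
    machine_name = ub(s$machine_name),
    tolerance_table_name = ub(s$tolerance_table_name),
    prescription = rx_j, beams = lapply(s$beams, beam_j),
    user_origin = s$user_origin
  )
  if (!is.null(s$localization_point)) out$localization_point <- s$localization_point
  if (!is.null(s$couch_delta)) out$couch_delta <- s$couch_delta
  if (length(s$attestations) > 0L)
    out$attestations <- lapply(as.list(s$attestations), ub)
  out
}

#' Write a plan snapshot as JSON
#'
#' Serializes a snapshot to the package's JSON plan-snapshot dialect. The
#' round trip through [read_snapshot_json()] is lossless for all fields.
#'
#' @param snapshot A validated `plan_snapshot`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snapshot_json <- function(snapshot, path) {
  validate_snapshot(snapshot)
  json <- jsonlite::toJSON(snapshot_to_jsonable(snapshot), digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

num_or_fail <- function(x, pointer, n = 1L) {
  if (is.list(x)) x <- unlist(x, use.names = FALSE)
  if (!is.numeric(x) && !is.integer(x))
    fail_at(pointer, paste0("expected number, got ", class(x)[1]))
  as.numeric(x)
}

#' Read a plan snapshot from JSON
#'
#' Parses and validates the package's JSON plan-snapshot dialect. Schema
#' violations raise errors that point at the offending field.
#'
#' @param path Path to a snapshot JSON file.
#' @return A validated `plan_snapshot`.
#' @export
read_snapshot_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(j$format, "chartcheckr-plan-snapshot"))
    fail_at("/format", "not a chartcheckr plan snapshot")
  cp_r <- function(cj, cpp) {
    control_point(
      index = num_or_fail(cj$index, paste0(cpp, "/index")),
      cumulative_weight = num_or_fail(cj$cumulative_weight, paste0(cpp, "/cumulative_weight")),
      gantry_angle = num_or_fail(cj$gantry_angle, paste0(cpp, "/gantry_angle")),
      mlc_bank_A = num_or_fail(cj$mlc_bank_A, paste0(cpp, "/mlc_bank_A")),
      mlc_bank_B = num_or_fail(cj$mlc_bank_B, paste0(cpp, "/mlc_bank_B")),
      jaw_positions = if (is.null(cj$jaw_positions)) NULL else
        num_or_fail(cj$jaw_positions, paste0(cpp, "/jaw_positions"))
    )
  }
  beam_r <- function(bj, bp) {
    beam(
      beam_name = bj$beam_name, radiation_type = bj$radiation_type,
      energy = bj$energy, mu = num_or_fail(bj$mu, paste0(bp, "/mu")),
      isocenter = num_or_fail(bj$isocenter, paste0(bp, "/isocenter")),
      gantry_angle = num_or_fail(bj$gantry_angle, paste0(bp, "/gantry_angle")),
      gantry_rotation_direction = bj$gantry_rotation_direction,
      collimator_angle = num_or_fail(bj$collimator_angle, paste0(bp, "/collimator_angle")),
      couch_angle = num_or_fail(bj$couch_angle, paste0(bp, "/couch_angle")),
      jaws = num_or_fail(bj$jaws, paste0(bp, "/jaws")),
      ssd = if (is.null(bj$ssd)) NULL else num_or_fail(bj$ssd, paste0(bp, "/ssd")),
      wedge = bj$wedge, bolus_linked = isTRUE(bj$bolus_linked),
      applicator = bj$applicator, is_setup_beam = isTRUE(bj$is_setup_beam),
      control_points = lapply(seq_along(bj$control_points), function(j)
        cp_r(bj$control_points[[j]], sprintf("%s/control_points/%d", bp, j - 1L)))
    )
  }
  if (is.null(j$prescription)) fail_at("/prescription", "required field missing")
  rxj <- j$prescription
  rx <- prescription(
    total_dose = num_or_fail(rxj$total_dose, "/prescription/total_dose"),
    dose_per_fraction = num_or_fail(rxj$dose_per_fraction, "/prescription/dose_per_fraction"),
    n_fractions = num_or_fail(rxj$n_fractions, "/prescription/n_fractions"),
    template_name = rxj$template_name, approval = isTRUE(rxj$approval),
    site = rxj$site, fractionation_pattern = rxj$fractionation_pattern,
    image_technique = rxj$image_technique,
    bolus_spec = if (is.null(rxj$bolus_spec)) NULL else list(
      thickness_mm = num_or_fail(rxj$bolus_spec$thickness_mm,
                                 "/prescription/bolus_spec/thickness_mm"),
      type = rxj$bolus_spec$type, frequency = rxj$bolus_spec$frequency)
  )
  att <- logical(0)
  if (!is.null(j$attestations)) {
    att <- vapply(j$attestations, isTRUE, logical(1))
  }
  s <- plan_snapshot(
    system = j$system, patient_id = j$patient_id, plan_name = j$plan_name,
    plan_label = j$plan_label, approval_status = j$approval_status,
    course_name = j$course_name, patient_position = j$patient_position,
    technique = j$technique, machine_name = j$machine_name,
    tolerance_table_name = j$tolerance_table_name, prescription = rx,
    beams = lapply(seq_along(j$beams), function(i)
      beam_r(j$beams[[i]], sprintf("/beams/%d", i - 1L))),
    user_origin = num_or_fail(j$user_origin, "/user_origin"),
    localization_point = if (is.null(j$localization_point)) NULL else
      num_or_fail(j$localization_point, "/localization_point"),
    couch_delta = if (is.null(j$couch_delta)) NULL else
      num_or_fail(j$couch_delta, "/couch_delta"),
    attestations = att
  )
  validate_snapshot(s)
}
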