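#' Injected-error taxonomy
#'
#' The error types the synthetic fixture generator can inject into the OIS
#' copy of a plan pair. All but `hotspot_injected` mutate the plan snapshot
#' and are recorded in the manifest with the exact field paths they touch;
#' `hotspot_injected` targets the dose grid (see [generate_dose_grid()]).
#'
#' @return Character vector of error type names.
#' @export
error_types <- function() {
  c("mu_delta", "energy_swap", "gantry_delta", "collimator_delta",
    "couch_delta_angle", "isocenter_shift", "mlc_leaf_shift", "jaw_shift",
    "fractionation_mismatch", "bolus_removed", "wedge_removed",
    "plan_name_change", "patient_position_change", "machine_change",
    "approval_cleared", "couch_shift_injected", "hotspot_injected",
    "localization_offset")
}

#' Specify one error to inject
#'
#' @param error_type One of [error_types()].
#' @param magnitude Numeric magnitude in the field's units, where
#'   applicable (MU, degrees, mm, cGy); `NULL` uses a type-specific default.
#' @param beam 1-based index of the target beam, or `NULL` to pick one
#'   deterministically under the generator seed.
#' @param control_point,leaf,bank,jaw,axis Finer-grained target selectors
#'   (1-based; `bank` is `"A"` or `"B"`, `jaw` one of `x1,x2,y1,y2`,
#'   `axis` 1..3); `NULL` means seeded random choice.
#' @return An `error_spec` list.
#' @export
error_spec <- function(error_type, magnitude = NULL, beam = NULL,
                       control_point = NULL, leaf = NULL, bank = NULL,
                       jaw = NULL, axis = NULL) {
  error_type <- match.arg(error_type, error_types())
  structure(list(error_type = error_type, magnitude = magnitude, beam = beam,
                 control_point = control_point, leaf = leaf, bank = bank,
                 jaw = jaw, axis = axis),
            class = "error_spec")
}

# run code under a private RNG stream without touching global RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.default_magnitude <- c(
  mu_delta = 1.0, energy_swap = NA, gantry_delta = 1.0,
  collimator_delta = 1.0, couch_delta_angle = 1.0, isocenter_shift = 2.0,
  mlc_leaf_shift = 2.0, jaw_shift = 2.0, fractionation_mismatch = -40,
  bolus_removed = NA, wedge_removed = NA, plan_name_change = NA,
  patient_position_change = NA, machine_change = NA, approval_cleared = NA,
  couch_shift_injected = 1.0, localization_offset = 3.0
)

# build the clean (TPS-side) snapshot; all values rounded so that the
# decimal-string DICOM encoding round trips exactly
synth_base_snapshot <- function(technique, n_beams, n_leaves = 60L,
                                n_control_points = NULL) {
  if (is.null(n_control_points)) {
    n_control_points <- if (technique %in% c("IMRT_VMAT", "SRS", "SBRT")) 10L else 2L
  }
  dpf <- sample(c(180, 200, 250, 300, 800), 1L)
  nfx <- if (dpf >= 800) sample(3:5, 1L) else sample(10:35, 1L)
  rx <- prescription(
    total_dose = dpf * nfx, dose_per_fraction = dpf, n_fractions = nfx,
    template_name = sample(c("Prostate", "Lung", "Breast", "Brain"), 1L),
    site = sample(c("PROSTATE", "LUNG", "BREAST", "BRAIN"), 1L),
    image_technique = "kV_CBCT"
  )
  iso <- round(stats::runif(3, -20, 20), 1)
  mk_beam <- function(i) {
    ga0 <- round((360 / n_beams) * (i - 1), 1)
    cps <- lapply(seq_len(n_control_points), function(j) {
      frac <- (j - 1) / max(1L, n_control_points - 1L)
      half <- round(stats::runif(n_leaves, 5, 60), 1)
      control_point(
        index = j - 1L,
        cumulative_weight = round(frac, 4),
        gantry_angle = if (technique == "IMRT_VMAT")
          round((ga0 + 30 * frac) %% 360, 1) else ga0,
        mlc_bank_A = -half, mlc_bank_B = half
      )
    })
    beam(
      beam_name = sprintf("B%02d", i),
      radiation_type = if (technique == "ELECTRON") "electron" else "photon",
      energy = if (technique == "ELECTRON") "9E" else "6X",
      mu = round(stats::runif(1, 50, 300), 1),
      isocenter = iso,
      gantry_angle = ga0,
      gantry_rotation_direction = if (technique == "IMRT_VMAT") "CW" else "NONE",
      collimator_angle = round(stats::runif(1, 0, 90), 1),
      couch_angle = 0,
      jaws = c(x1 = -70, x2 = 70, y1 = -70, y2 = 70),
      ssd = round(stats::runif(1, 850, 1000), 1),
      applicator = if (technique == "ELECTRON") "A10" else NULL,
      control_points = cps
    )
  }
  plan_snapshot(
    system = "TPS",
    patient_id = sprintf("PT%06d", sample.int(999999L, 1L)),
    plan_name = paste0("PLAN_", technique),
    plan_label = paste0("PL_", technique),
    approval_status = "Approved",
    course_name = rx$template_name,  # keeps the course-name rule check clean
    patient_position = "HFS",
    technique = technique,
    machine_name = "TB1",
    tolerance_table_name = if (technique %in% c("SRS", "SBRT")) "SRS" else "T1",
    prescription = rx,
    beams = lapply(seq_len(n_beams), mk_beam),
    user_origin = round(stats::runif(3, -5, 5), 1),
    localization_point = NULL,
    couch_delta = if (technique %in% c("SRS", "SBRT")) c(0.5, -0.3, 1.2) else NULL,
    attestations = c(peer_review = TRUE, billing_approval = TRUE,
                     consent_present = TRUE)
  )
}

pick <- function(given, n) if (is.null(given)) sample.int(n, 1L) else as.integer(given)

# applies one error to the OIS copy; may also adjust the base (both copies)
# to make the error applicable (e.g. attach the wedge that gets dropped).
# Returns list(base=, ois=, record=).
apply_error <- function(base, ois, spec) {
  nb <- length(base$beams)
  if (!is.null(spec$beam) && (spec$beam < 1 || spec$beam > nb)) {
    stop("error_spec targets beam ", spec$beam, " but plan has ", nb, " beams",
         call. = FALSE)
  }
  mag <- spec$magnitude
  if (is.null(mag)) mag <- unname(.default_magnitude[spec$error_type])
  rec <- list(error_type = spec$error_type, magnitude = mag)
  i <- pick(spec$beam, nb)
  bpath <- sprintf("beams[%d]", i)

  set_both <- function(fun) { base <<- fun(base); ois <<- fun(ois) }

  switch(spec$error_type,
    mu_delta = {
      before <- ois$beams[[i]]$mu
      ois$beams[[i]]$mu <- round(before + mag, 2)
      rec$field_paths <- paste0(bpath, ".mu")
      rec$before <- before; rec$after <- ois$beams[[i]]$mu
    },
    energy_swap = {
      before <- ois$beams[[i]]$energy
      ois$beams[[i]]$energy <- if (before == "6X") "10X" else "6X"
      rec$field_paths <- paste0(bpath, ".energy")
      rec$before <- before; rec$after <- ois$beams[[i]]$energy
    },
    gantry_delta = {
      before <- ois$beams[[i]]$gantry_angle
      ois$beams[[i]]$gantry_angle <- round((before + mag) %% 360, 2)
      rec$field_paths <- paste0(bpath, ".gantry_angle")
      rec$before <- before; rec$after <- ois$beams[[i]]$gantry_angle
    },
    collimator_delta = {
      before <- ois$beams[[i]]$collimator_angle
      ois$beams[[i]]$collimator_angle <- round((before + mag) %% 360, 2)
      rec$field_paths <- paste0(bpath, ".collimator_angle")
      rec$before <- before; rec$after <- ois$beams[[i]]$collimator_angle
    },
    couch_delta_angle = {
      before <- ois$beams[[i]]$couch_angle
      ois$beams[[i]]$couch_angle <- round((before + mag) %% 360, 2)
      rec$field_paths <- paste0(bpath, ".couch_angle")
      rec$before <- before; rec$after <- ois$beams[[i]]$couch_angle
    },
    isocenter_shift = {
      ax <- pick(spec$axis, 3L)
      before <- ois$beams[[i]]$isocenter[ax]
      ois$beams[[i]]$isocenter[ax] <- round(before + mag, 2)
      rec$field_paths <- sprintf("%s.isocenter[%d]", bpath, ax)
      rec$before <- before; rec$after <- ois$beams[[i]]$isocenter[ax]
    },
    mlc_leaf_shift = {
      j <- pick(spec$control_point, length(ois$beams[[i]]$control_points))
      bank <- if (is.null(spec$bank)) sample(c("A", "B"), 1L) else spec$bank
      field <- paste0("mlc_bank_", bank)
      k <- pick(spec$leaf, length(ois$beams[[i]]$control_points[[j]][[field]]))
      before <- ois$beams[[i]]$control_points[[j]][[field]][k]
      # shift away from the opposing bank so leaves never cross
      delta <- if (bank == "A") -abs(mag) else abs(mag)
      ois$beams[[i]]$control_points[[j]][[field]][k] <- round(before + delta, 2)
      rec$field_paths <- sprintf("%s.control_points[%d].%s[%d]", bpath, j, field, k)
      rec$before <- before
      rec$after <- ois$beams[[i]]$control_points[[j]][[field]][k]
    },
    jaw_shift = {
      jw <- if (is.null(spec$jaw)) sample(.jaw_names, 1L) else spec$jaw
      before <- ois$beams[[i]]$jaws[[jw]]
      delta <- if (jw %in% c("x1", "y1")) -abs(mag) else abs(mag)
      ois$beams[[i]]$jaws[[jw]] <- round(before + delta, 2)
      rec$field_paths <- sprintf("%s.jaws.%s", bpath, jw)
      rec$before <- before; rec$after <- ois$beams[[i]]$jaws[[jw]]
    },
    fractionation_mismatch = {
      before <- ois$prescription$total_dose
      ois$prescription$total_dose <- round(before + mag, 1)
      if (ois$prescription$total_dose <= 0)
        ois$prescription$total_dose <- round(before + abs(mag), 1)
      rec$field_paths <- "prescription.total_dose"
      rec$before <- before; rec$after <- ois$prescription$total_dose
    },
    bolus_removed = {
      set_both(function(s) { s$beams[[i]]$bolus_linked <- TRUE; s })
      ois$beams[[i]]$bolus_linked <- FALSE
      rec$field_paths <- paste0(bpath, ".bolus_linked")
      rec$before <- TRUE; rec$after <- FALSE
    },
    wedge_removed = {
      set_both(function(s) { s$beams[[i]]$wedge <- "W30"; s })
      ois$beams[[i]]["wedge"] <- list(NULL)  # keep the field, clear the value
      rec$field_paths <- paste0(bpath, ".wedge")
      rec$before <- "W30"; rec$after <- NA
    },
    plan_name_change = {
      before <- ois$plan_name
      ois$plan_name <- paste0(before, "_REV")
      rec$field_paths <- "plan_name"
      rec$before <- before; rec$after <- ois$plan_name
    },
    patient_position_change = {
      before <- ois$patient_position
      ois$patient_position <- if (before == "HFS") "FFS" else "HFS"
      rec$field_paths <- "patient_position"
      rec$before <- before; rec$after <- ois$patient_position
    },
    machine_change = {
      before <- ois$machine_name
      ois$machine_name <- if (before == "TB1") "TB2" else "TB1"
      rec$field_paths <- "machine_name"
      rec$before <- before; rec$after <- ois$machine_name
    },
    approval_cleared = {
      before <- ois$approval_status
      ois$approval_status <- "Unapproved"
      rec$field_paths <- "approval_status"
      rec$before <- before; rec$after <- "Unapproved"
    },
    couch_shift_injected = {
      set_both(function(s) { s["couch_delta"] <- list(NULL); s })
      ois$couch_delta <- c(abs(mag), 0, 0)
      rec$field_paths <- "couch_delta"
      rec$before <- NA; rec$after <- ois$couch_delta
    },
    localization_offset = {
      lp <- base$user_origin
      set_both(function(s) { s$localization_point <- lp; s })
      ax <- pick(spec$axis, 3L)
      before <- ois$localization_point[ax]
      ois$localization_point[ax] <- round(before + mag, 2)
      rec$field_paths <- sprintf("localization_point[%d]", ax)
      rec$before <- before; rec$after <- ois$localization_point[ax]
    },
    hotspot_injected = {
      stop("hotspot_injected targets the dose grid, not the plan snapshot; ",
           "use generate_dose_grid(hotspot_fraction > 0)", call. = FALSE)
    }
  )
  list(base = base, ois = ois, record = rec)
}

#' Generate a paired TPS/OIS plan snapshot fixture
#'
#' Builds one plausible clean plan and exports it twice, as the TPS copy and
#' the OIS copy. With no errors the copies are identical except for the
#' `system` tag; each requested [error_spec()] mutates the OIS copy at
#' exactly the field paths recorded in the returned manifest. Everything is
#' deterministic given `seed`; the global RNG state is left untouched.
#'
#' @param seed Integer seed for the generator's private random stream.
#' @param technique Plan technique (see [plan_snapshot()]).
#' @param n_beams Number of treatment beams (>= 1).
#' @param errors List of [error_spec()]s to inject into the OIS copy.
#' @param n_leaves MLC leaf pairs per bank (default 60, 5 mm leaves).
#' @param n_control_points Control points per beam; default 10 for
#'   dynamic techniques, 2 for static.
#' @return List with `tps`, `ois` (validated `plan_snapshot`s) and
#'   `manifest` (seed, plan descriptor, applied errors with resolved field
#'   paths and before/after values).
#' @export
#' @examples
#' pair <- generate_plan_pair(7, "IMRT_VMAT", 3,
#'                            errors = list(error_spec("mu_delta")))
#' pair$manifest$errors[[1]]$field_paths
generate_plan_pair <- function(seed, technique = "IMRT_VMAT", n_beams = 2L,
                               errors = list(), n_leaves = 60L,
                               n_control_points = NULL) {
  stopifnot(n_beams >= 1)
  technique <- match.arg(technique, .techniques)
  with_seed(seed, {
    base <- synth_base_snapshot(technique, n_beams, n_leaves, n_control_points)
    ois <- base
    ois$system <- "OIS"
    records <- vector("list", length(errors))
    for (e in seq_along(errors)) {
      res <- apply_error(base, ois, errors[[e]])
      base <- res$base; ois <- res$ois
      records[[e]] <- res$record
    }
    base$system <- "TPS"
    validate_snapshot(base)
    validate_snapshot(ois)
    manifest <- structure(list(
      seed = seed,
      base_plan = list(technique = technique, n_beams = n_beams,
                       patient_id = base$patient_id, plan_name = base$plan_name),
      errors = records
    ), class = "fixture_manifest")
    list(tps = base, ois = ois, manifest = manifest)
  })
}

#' Field paths recorded in a fixture manifest
#'
#' @param manifest A `fixture_manifest` from [generate_plan_pair()].
#' @return Character vector of all mutated field paths.
#' @export
manifest_paths <- function(manifest) {
  stopifnot(inherits(manifest, "fixture_manifest"))
  unlist(lapply(manifest$errors, `[[`, "field_paths"))
}

#' Write a fixture manifest as JSON
#'
#' @param manifest A `fixture_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(manifest, path) {
  writeLines(jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, null = "null",
                              na = "null"),
             path)
  invisible(path)
}

#' Generate a cylindrical CT phantom with an External contour
#'
#' A water cylinder (0 HU) centered in an air background (-1000 HU), with
#' optional inserts of arbitrary HU at stated voxels. Per-slice circular
#' polygons delineate the External (body) structure. The phantom exercises
#' the HU statistics, slice-thickness and high-Z rule checks with known
#' ground truth.
#'
#' @param seed Integer seed (reserved; the phantom itself is deterministic
#'   in its arguments).
#' @param shape Integer 3-vector `(nx, ny, nz)` of the voxel grid.
#' @param external_radius_mm Radius of the water cylinder, mm.
#' @param inserts List of `list(hu =, voxel = c(i, j, k))` high-density
#'   inserts (1-based voxel indices).
#' @param spacing Voxel spacing `(dx, dy, dz)` mm; `dz` is the slice
#'   thickness.
#' @param n_poly_vertices Vertices of each circular contour polygon.
#' @return List: `volume` (3D HU array), `origin` (mm position of voxel
#'   `(1,1,1)` center), `spacing`, `series_description`,
#'   `density_table_name`, `contrast_flag`, and `external` (a structure:
#'   name, role, approval, per-slice `contours` with `$z` and `$xy`).
#' @export
generate_ct_phantom <- function(seed = 0, shape = c(32L, 32L, 8L),
                                external_radius_mm = 50,
                                inserts = list(),
                                spacing = c(4, 4, 2.5),
                                n_poly_vertices = 48L) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  origin <- -spacing * (shape - 1) / 2  # grid centered on (0,0,0)
  vol <- array(-1000, dim = shape)
  xs <- origin[1] + (seq_len(nx) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(ny) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(nz) - 1) * spacing[3]
  r2 <- outer(xs^2, ys^2, `+`)
  inside <- r2 <= external_radius_mm^2
  for (k in seq_len(nz)) vol[, , k][inside] <- 0
  for (ins in inserts) {
    v <- ins$voxel
    vol[v[1], v[2], v[3]] <- ins$hu
  }
  ang <- seq(0, 2 * pi, length.out = n_poly_vertices + 1L)[-(n_poly_vertices + 1L)]
  circle <- cbind(external_radius_mm * cos(ang), external_radius_mm * sin(ang))
  contours <- lapply(zs, function(z) list(z = z, xy = circle))
  list(
    volume = vol, origin = origin, spacing = spacing,
    series_description = "SYNTH CT PHANTOM",
    density_table_name = "CT_2020", contrast_flag = FALSE,
    external = list(name = "External", role = "External", approval = TRUE,
                    contours = contours)
  )
}

#' Generate a synthetic dose grid with a controlled hotspot burden
#'
#' Fills a grid at exactly the prescription dose and raises
#' `round(hotspot_fraction * n_voxels)` voxels (chosen deterministically
#' under `seed`) to 115% of prescription, i.e. strictly above the 110%
#' hotspot threshold used by [check_hotspot()].
#'
#' @param seed Integer seed for hotspot placement.
#' @param shape Integer 3-vector of grid dimensions.
#' @param rx_total_cGy Prescription total dose, cGy.
#' @param hotspot_fraction Fraction of voxels to raise above threshold,
#'   in `[0, 1]`.
#' @param spacing,origin Grid geometry (mm), as for the CT phantom.
#' @return List: `values` (3D cGy array), `origin`, `spacing`,
#'   `n_hot` (number of raised voxels).
#' @export
generate_dose_grid <- function(seed = 0, shape = c(10L, 10L, 10L),
                               rx_total_cGy = 5000, hotspot_fraction = 0,
                               spacing = c(4, 4, 2.5),
                               origin = -spacing * (shape - 1) / 2) {
  stopifnot(hotspot_fraction >= 0, hotspot_fraction <= 1)
  nvox <- prod(shape)
  n_hot <- round(hotspot_fraction * nvox)
  vals <- array(rx_total_cGy, dim = shape)
  if (n_hot > 0) {
    idx <- with_seed(seed, sample.int(nvox, n_hot))
    vals[idx] <- 1.15 * rx_total_cGy
  }
  list(values = vals, origin = origin, spacing = spacing, n_hot = n_hot)
}
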