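# Minimal DICOM RT Plan I/O: explicit VR little endian, defined-length
# sequences on write, defined or undefined lengths accepted on read.
# Scope is exactly the PlanSnapshot model; attributes with no standard RT
# Plan home travel in one private element as compact JSON.

.uid_rtplan <- "1.2.840.10008.5.1.4.1.1.481.5"
.uid_explicit_le <- "1.2.840.10008.1.2.1"
.uid_impl_class <- "1.2.826.0.1.3680043.10.1341.1"
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) {
  # avoid 32-bit signed overflow for lengths >= 2^31 (never hit in practice)
  lo <- x %% 65536; hi <- x %/% 65536
  c(u16le(lo), u16le(hi))
}

pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

enc_value <- function(vr, value) {
  switch(vr,
    UI = pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0)),
    SH = , LO = , CS = , PN = , DA = , TM = , ST = , LT = , UT =
      pad_even(charToRaw(paste(value, collapse = "\\"))),
    IS = pad_even(charToRaw(paste(format(as.integer(value), scientific = FALSE,
                                         trim = TRUE), collapse = "\\"))),
    DS = pad_even(charToRaw(paste(vapply(value, function(v) sprintf("%.10g", v), ""),
                                  collapse = "\\"))),
    FD = writeBin(as.numeric(value), raw(), size = 8, endian = "little"),
    UL = u32le(value),
    US = u16le(value),
    OB = pad_even(as.raw(value), as.raw(0)),
    stop("unsupported VR for encoding: ", vr)
  )
}

dcm_elem <- function(group, elem, vr, value, raw_payload = NULL) {
  payload <- if (is.null(raw_payload)) enc_value(vr, value) else raw_payload
  head <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(head, as.raw(c(0, 0)), u32le(length(payload)), payload)
  } else {
    if (length(payload) > 65535) stop("value too long for short VR ", vr)
    c(head, u16le(length(payload)), payload)
  }
}

dcm_item <- function(content) {
  c(u16le(0xFFFE), u16le(0xE000), u32le(length(content)), content)
}

dcm_sq <- function(group, elem, items) {
  dcm_elem(group, elem, "SQ", raw_payload = do.call(c, c(list(raw(0)), items)))
}

snapshot_extras_json <- function(s) {
  rx <- s$prescription
  extras <- list(
    system = ub(s$system),
    dose_per_fraction = ub(rx$dose_per_fraction),
    template_name = ub(rx$template_name),
    rx_approval = ub(rx$approval),
    fractionation_pattern = ub(rx$fractionation_pattern),
    user_origin = s$user_origin,
    beam_gantry = vapply(s$beams, `[[`, 0, "gantry_angle")
  )
  if (!is.null(rx$image_technique)) extras$image_technique <- ub(rx$image_technique)
  if (!is.null(rx$bolus_spec))
    extras$bolus_spec <- list(thickness_mm = ub(rx$bolus_spec$thickness_mm),
                              type = ub(rx$bolus_spec$type),
                              frequency = ub(rx$bolus_spec$frequency))
  if (!is.null(s$localization_point)) extras$localization_point <- s$localization_point
  if (!is.null(s$couch_delta)) extras$couch_delta <- s$couch_delta
  if (length(s$attestations) > 0L)
    extras$attestations <- lapply(as.list(s$attestations), ub)
  as.character(jsonlite::toJSON(extras, digits = NA, null = "null"))
}

encode_control_point <- function(cp, b, first) {
  els <- list(dcm_elem(0x300A, 0x0112, "IS", cp$index))
  if (first) {
    energy_num <- suppressWarnings(as.numeric(sub("[^0-9.].*$", "", b$energy)))
    if (is.na(energy_num)) energy_num <- 0
    els <- c(els, list(dcm_elem(0x300A, 0x0114, "DS", energy_num)))
  }
  bld <- list()
  if (first) {
    if (!is.null(cp$jaw_positions) &&
        any(abs(cp$jaw_positions - b$jaws) > 1e-9)) {
      stop("first control point jaw positions conflict with beam jaws; ",
           "not representable in the RT Plan encoding", call. = FALSE)
    }
    bld <- c(bld,
      list(dcm_item(c(dcm_elem(0x300A, 0x00B8, "CS", "ASYMX"),
                      dcm_elem(0x300A, 0x011C, "DS", b$jaws[c("x1", "x2")])))),
      list(dcm_item(c(dcm_elem(0x300A, 0x00B8, "CS", "ASYMY"),
                      dcm_elem(0x300A, 0x011C, "DS", b$jaws[c("y1", "y2")])))))
  } else if (!is.null(cp$jaw_positions)) {
    bld <- c(bld,
      list(dcm_item(c(dcm_elem(0x300A, 0x00B8, "CS", "ASYMX"),
                      dcm_elem(0x300A, 0x011C, "DS", cp$jaw_positions[c("x1", "x2")])))),
      list(dcm_item(c(dcm_elem(0x300A, 0x00B8, "CS", "ASYMY"),
                      dcm_elem(0x300A, 0x011C, "DS", cp$jaw_positions[c("y1", "y2")])))))
  }
  bld <- c(bld, list(dcm_item(c(
    dcm_elem(0x300A, 0x00B8, "CS", "MLCX"),
    dcm_elem(0x300A, 0x011C, "DS", c(cp$mlc_bank_A, cp$mlc_bank_B))))))
  els <- c(els, list(dcm_sq(0x300A, 0x011A, bld)))
  els <- c(els, list(dcm_elem(0x300A, 0x011E, "DS", cp$gantry_angle)))
  if (first) {
    dir <- c(CW = "CW", CCW = "CC", NONE = "NONE")[[b$gantry_rotation_direction]]
    els <- c(els,
             list(dcm_elem(0x300A, 0x011F, "CS", dir)),
             list(dcm_elem(0x300A, 0x0120, "DS", b$collimator_angle)),
             list(dcm_elem(0x300A, 0x0122, "DS", b$couch_angle)),
             list(dcm_elem(0x300A, 0x012C, "DS", b$isocenter)))
    if (!is.null(b$ssd))
      els <- c(els, list(dcm_elem(0x300A, 0x0130, "DS", b$ssd)))
  }
  els <- c(els, list(dcm_elem(0x300A, 0x0134, "DS", cp$cumulative_weight)))
  dcm_item(do.call(c, els))
}

encode_beam <- function(b, number, n_leaves, machine) {
  bounds <- seq(-2.5 * n_leaves, 2.5 * n_leaves, by = 5)  # 5 mm leaves
  bld_defs <- list(
    dcm_item(c(dcm_elem(0x300A, 0x00B8, "CS", "ASYMX"),
               dcm_elem(0x300A, 0x00BC, "IS", 1L))),
    dcm_item(c(dcm_elem(0x300A, 0x00B8, "CS", "ASYMY"),
               dcm_elem(0x300A, 0x00BC, "IS", 1L))),
    dcm_item(c(dcm_elem(0x300A, 0x00B8, "CS", "MLCX"),
               dcm_elem(0x300A, 0x00BC, "IS", n_leaves),
               dcm_elem(0x300A, 0x00BE, "DS", bounds)))
  )
  els <- list(
    dcm_elem(0x300A, 0x00B2, "SH", machine),
    dcm_sq(0x300A, 0x00B6, bld_defs),
    dcm_elem(0x300A, 0x00C0, "IS", number),
    dcm_elem(0x300A, 0x00C2, "LO", b$beam_name),
    dcm_elem(0x300A, 0x00C3, "ST", b$energy),
    dcm_elem(0x300A, 0x00C4, "CS",
             if (length(b$control_points) > 2L) "DYNAMIC" else "STATIC"),
    dcm_elem(0x300A, 0x00C6, "CS", toupper(b$radiation_type)),
    dcm_elem(0x300A, 0x00CE, "CS", if (b$is_setup_beam) "SETUP" else "TREATMENT"),
    dcm_elem(0x300A, 0x00D0, "IS", if (is.null(b$wedge)) 0L else 1L)
  )
  if (!is.null(b$wedge)) {
    els <- c(els, list(dcm_sq(0x300A, 0x00D1, list(dcm_item(c(
      dcm_elem(0x300A, 0x00D2, "IS", 1L),
      dcm_elem(0x300A, 0x00D3, "CS", "STANDARD"),
      dcm_elem(0x300A, 0x00D4, "SH", b$wedge)))))))
  }
  els <- c(els, list(dcm_elem(0x300A, 0x00ED, "IS",
                              if (b$bolus_linked) 1L else 0L)))
  if (!is.null(b$applicator)) {
    els <- c(els, list(dcm_sq(0x300A, 0x0107, list(dcm_item(c(
      dcm_elem(0x300A, 0x0108, "SH", b$applicator),
      dcm_elem(0x300A, 0x0109, "CS", "ELECTRON_SQUARE")))))))
  }
  cw <- if (length(b$control_points) > 0L)
    b$control_points[[length(b$control_points)]]$cumulative_weight else 1
  cps <- lapply(seq_along(b$control_points), function(j)
    encode_control_point(b$control_points[[j]], b, first = (j == 1L)))
  els <- c(els,
           list(dcm_elem(0x300A, 0x010E, "DS", cw)),
           list(dcm_elem(0x300A, 0x0110, "IS", length(b$control_points))),
           list(dcm_sq(0x300A, 0x0111, cps)))
  dcm_item(do.call(c, els))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a plan snapshot as a DICOM RT Plan file
#'
#' Emits a minimal but standard-conforming RT Plan object (explicit VR
#' little endian) carrying the full snapshot: beam geometry, control
#' points, MLC banks and metersets in their standard attributes, and
#' snapshot fields with no standard RT Plan home (user origin, couch delta,
#' prescription details, attestations) in one private element as JSON.
#' [read_rtplan_dicom()] restores an identical snapshot. One restriction:
#' per-control-point jaw positions on the first control point must agree
#' with the beam-level jaws.
#'
#' @param snapshot A validated `plan_snapshot`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rtplan_dicom <- function(snapshot, path) {
  s <- validate_snapshot(snapshot)
  n_leaves <- length(s$beams[[1]]$control_points[[1]]$mlc_bank_A)
  digits <- gsub("[^0-9]", "", s$patient_id)
  if (!nzchar(digits)) digits <- "0"
  sop_uid <- paste0("1.2.826.0.1.3680043.10.1341.2.", digits, ".",
                    if (s$system == "TPS") "1" else "2")

  dose_ref <- dcm_sq(0x300A, 0x0010, list(dcm_item(c(
    dcm_elem(0x300A, 0x0012, "IS", 1L),
    dcm_elem(0x300A, 0x0014, "CS", "SITE"),
    dcm_elem(0x300A, 0x0016, "LO", s$prescription$site),
    dcm_elem(0x300A, 0x0020, "CS", "TARGET"),
    dcm_elem(0x300A, 0x0026, "DS", s$prescription$total_dose / 100)))))

  ref_beams <- lapply(seq_along(s$beams), function(i) dcm_item(c(
    dcm_elem(0x300A, 0x0086, "DS", s$beams[[i]]$mu),
    dcm_elem(0x300C, 0x0006, "IS", i))))
  fx_group <- dcm_sq(0x300A, 0x0070, list(dcm_item(c(
    dcm_elem(0x300A, 0x0071, "IS", 1L),
    dcm_elem(0x300A, 0x0078, "IS", s$prescription$n_fractions),
    dcm_elem(0x300A, 0x0080, "IS", length(s$beams)),
    dcm_sq(0x300C, 0x0004, ref_beams)))))

  beams <- dcm_sq(0x300A, 0x00B0,
                  lapply(seq_along(s$beams), function(i)
                    encode_beam(s$beams[[i]], i, n_leaves, s$machine_name)))

  setup <- dcm_sq(0x300A, 0x0180, list(dcm_item(c(
    dcm_elem(0x0018, 0x5100, "CS", s$patient_position),
    dcm_elem(0x300A, 0x0182, "IS", 1L)))))

  tol_table <- dcm_sq(0x300A, 0x0040, list(dcm_item(c(
    dcm_elem(0x300A, 0x0042, "IS", 1L),
    dcm_elem(0x300A, 0x0043, "SH", s$tolerance_table_name)))))

  dataset <- c(
    dcm_elem(0x0008, 0x0016, "UI", .uid_rtplan),
    dcm_elem(0x0008, 0x0018, "UI", sop_uid),
    dcm_elem(0x0008, 0x0020, "DA", "20200101"),
    dcm_elem(0x0008, 0x0030, "TM", "000000"),
    dcm_elem(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_elem(0x0008, 0x1030, "LO", s$course_name),
    dcm_elem(0x0008, 0x103E, "LO", s$technique),
    dcm_elem(0x0009, 0x0010, "LO", "CHARTCHECKR"),
    dcm_elem(0x0009, 0x1001, "UT", snapshot_extras_json(s)),
    dcm_elem(0x0010, 0x0010, "PN", s$patient_id),
    dcm_elem(0x0010, 0x0020, "LO", s$patient_id),
    dcm_elem(0x300A, 0x0002, "SH", s$plan_label),
    dcm_elem(0x300A, 0x0003, "LO", s$plan_name),
    dose_ref, tol_table, fx_group, beams, setup,
    dcm_elem(0x300E, 0x0002, "CS", s$approval_status)
  )

  meta_body <- c(
    dcm_elem(0x0002, 0x0001, "OB", c(0L, 1L)),
    dcm_elem(0x0002, 0x0002, "UI", .uid_rtplan),
    dcm_elem(0x0002, 0x0003, "UI", sop_uid),
    dcm_elem(0x0002, 0x0010, "UI", .uid_explicit_le),
    dcm_elem(0x0002, 0x0012, "UI", .uid_impl_class)
  )
  meta <- c(dcm_elem(0x0002, 0x0000, "UL", length(meta_body)), meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

# --- reading ---------------------------------------------------------------

dcm_format_error <- function(msg) stop("DICOM format error: ", msg, call. = FALSE)

r_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
r_u32 <- function(raw, pos) {
  r_u16(raw, pos) + 65536 * r_u16(raw, pos + 2L)
}

decode_value <- function(vr, payload) {
  txt <- function() {
    s <- rawToChar(payload[payload != as.raw(0)])  # drop NUL padding
    sub(" +$", "", s)
  }
  switch(vr,
    UI = , SH = , LO = , CS = , PN = , DA = , TM = , ST = , LT = , UT = txt(),
    IS = as.integer(strsplit(txt(), "\\", fixed = TRUE)[[1]]),
    DS = as.numeric(strsplit(txt(), "\\", fixed = TRUE)[[1]]),
    UL = r_u32(payload, 1L),
    US = r_u16(payload, 1L),
    FD = readBin(payload, numeric(), n = length(payload) / 8, size = 8,
                 endian = "little"),
    payload
  )
}

# parse one dataset (sequence of elements) in raw[pos..end]; returns
# list(elements = named list, pos = next position)
parse_dataset <- function(raw, pos, end) {
  els <- list()
  while (pos <= end - 7L) {
    group <- r_u16(raw, pos); elem <- r_u16(raw, pos + 2L)
    if (group == 0xFFFE) break  # item/sequence delimiter handled by caller
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .long_vrs) {
      len <- r_u32(raw, pos + 8L)
      body_start <- pos + 12L
    } else {
      len <- r_u16(raw, pos + 6L)
      body_start <- pos + 8L
    }
    key <- sprintf("%04X%04X", group, elem)
    if (vr == "SQ") {
      parsed <- parse_sq(raw, body_start, len)
      els[[key]] <- parsed$items
      pos <- parsed$pos
    } else {
      if (len == 0xFFFFFFFF) dcm_format_error("undefined length on non-SQ element")
      els[[key]] <- decode_value(vr, if (len > 0) raw[body_start:(body_start + len - 1L)] else raw(0))
      pos <- body_start + len
    }
  }
  list(elements = els, pos = pos)
}

parse_sq <- function(raw, pos, len) {
  undefined <- len == 0xFFFFFFFF
  end <- if (undefined) length(raw) else pos + len - 1L
  items <- list()
  while (pos <= end - 7L) {
    group <- r_u16(raw, pos); elem <- r_u16(raw, pos + 2L)
    ilen <- r_u32(raw, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && elem == 0xE0DD) break  # sequence delimiter
    if (!(group == 0xFFFE && elem == 0xE000)) dcm_format_error("expected item tag in sequence")
    if (ilen == 0xFFFFFFFF) {
      res <- parse_dataset(raw, pos, end)
      items[[length(items) + 1L]] <- res$elements
      pos <- res$pos
      # expect item delimiter
      if (r_u16(raw, pos) == 0xFFFE && r_u16(raw, pos + 2L) == 0xE00D) pos <- pos + 8L
    } else {
      res <- parse_dataset(raw, pos, pos + ilen - 1L)
      items[[length(items) + 1L]] <- res$elements
      pos <- pos + ilen
    }
    if (!undefined && pos > end) break
  }
  if (undefined && pos <= length(raw) - 7L &&
      r_u16(raw, pos - 8L) != 0xFFFE) {
    # delimiter consumption handled in loop; nothing to do
  }
  list(items = items, pos = if (undefined) pos else pos)
}

get1 <- function(els, key, default = NULL) {
  if (is.null(els[[key]])) default else els[[key]]
}

decode_bld <- function(bld_items) {
  out <- list()
  for (it in bld_items) {
    out[[get1(it, "300A00B8")]] <- get1(it, "300A011C")
  }
  out
}

#' Read a DICOM RT Plan file into a plan snapshot
#'
#' Counterpart of [write_rtplan_dicom()]. Rejects files that are not DICOM
#' or whose SOP class is not RT Plan, and RT Plans without a beam sequence.
#' Optional attributes absent from the file stay absent in the snapshot
#' (`NULL`), never defaulted to zero.
#'
#' @param path Path to a DICOM RT Plan file.
#' @return A validated `plan_snapshot`.
#' @export
read_rtplan_dicom <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readBin(path, raw(), n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    dcm_format_error("missing DICM magic; not a DICOM part-10 file")
  ds <- parse_dataset(raw, 133L, length(raw))$elements
  sop <- get1(ds, "00080016")
  if (is.null(sop) || sop != .uid_rtplan)
    dcm_format_error(paste0("SOP class '", sop %||% "<missing>",
                            "' is not an RT Plan"))
  beam_items <- get1(ds, "300A00B0")
  if (is.null(beam_items) || length(beam_items) == 0L)
    dcm_format_error("RT Plan has no beam sequence")

  extras_json <- get1(ds, "00091001")
  if (is.null(extras_json)) dcm_format_error("missing plan snapshot extras element")
  extras <- jsonlite::fromJSON(extras_json, simplifyVector = TRUE)

  # beam MU from the fraction group
  fx <- get1(ds, "300A0070")
  if (is.null(fx) || length(fx) == 0L) dcm_format_error("missing fraction group sequence")
  fx <- fx[[1]]
  mu_by_number <- list()
  for (rb in get1(fx, "300C0004", list())) {
    mu_by_number[[as.character(get1(rb, "300C0006"))]] <- get1(rb, "300A0086")
  }

  read_beam <- function(bi, idx) {
    cps_items <- get1(bi, "300A0111", list())
    if (length(cps_items) == 0L) dcm_format_error("beam without control points")
    first <- cps_items[[1]]
    bld1 <- decode_bld(get1(first, "300A011A", list()))
    if (is.null(bld1$ASYMX) || is.null(bld1$ASYMY))
      dcm_format_error("first control point lacks jaw positions")
    n_leaves <- length(bld1$MLCX) / 2L
    dirmap <- c(CW = "CW", CC = "CCW", NONE = "NONE")
    wedge <- NULL
    if (identical(get1(bi, "300A00D0"), 1L)) {
      ws <- get1(bi, "300A00D1", list())
      if (length(ws) > 0L) wedge <- get1(ws[[1]], "300A00D4")
    }
    applicator <- NULL
    ap <- get1(bi, "300A0107", list())
    if (length(ap) > 0L) applicator <- get1(ap[[1]], "300A0108")
    cps <- lapply(seq_along(cps_items), function(j) {
      it <- cps_items[[j]]
      bld <- decode_bld(get1(it, "300A011A", list()))
      jaw_pos <- NULL
      if (j > 1L && !is.null(bld$ASYMX) && !is.null(bld$ASYMY)) {
        jaw_pos <- c(bld$ASYMX, bld$ASYMY)
      }
      mlc <- bld$MLCX
      control_point(
        index = get1(it, "300A0112"),
        cumulative_weight = get1(it, "300A0134"),
        gantry_angle = get1(it, "300A011E"),
        mlc_bank_A = mlc[seq_len(n_leaves)],
        mlc_bank_B = mlc[n_leaves + seq_len(n_leaves)],
        jaw_positions = jaw_pos
      )
    })
    beam_number <- get1(bi, "300A00C0", idx)
    beam(
      beam_name = get1(bi, "300A00C2"),
      radiation_type = tolower(get1(bi, "300A00C6")),
      energy = get1(bi, "300A00C3"),
      mu = mu_by_number[[as.character(beam_number)]] %||% 0,
      isocenter = get1(first, "300A012C"),
      gantry_angle = extras$beam_gantry[idx],
      gantry_rotation_direction = dirmap[[get1(first, "300A011F", "NONE")]],
      collimator_angle = get1(first, "300A0120", 0),
      couch_angle = get1(first, "300A0122", 0),
      jaws = c(bld1$ASYMX, bld1$ASYMY),
      ssd = get1(first, "300A0130"),
      wedge = wedge,
      bolus_linked = identical(get1(bi, "300A00ED"), 1L),
      applicator = applicator,
      is_setup_beam = identical(get1(bi, "300A00CE"), "SETUP"),
      control_points = cps
    )
  }
  beams <- lapply(seq_along(beam_items), function(i) read_beam(beam_items[[i]], i))

  dose_ref <- get1(ds, "300A0010", list())
  total_dose <- NULL; site <- "UNKNOWN"
  if (length(dose_ref) > 0L) {
    total_dose <- get1(dose_ref[[1]], "300A0026") * 100
    site <- get1(dose_ref[[1]], "300A0016", "UNKNOWN")
  }
  if (is.null(total_dose)) dcm_format_error("missing target prescription dose")

  rx <- prescription(
    total_dose = total_dose,
    dose_per_fraction = extras$dose_per_fraction,
    n_fractions = get1(fx, "300A0078"),
    template_name = extras$template_name,
    approval = isTRUE(extras$rx_approval),
    site = site,
    fractionation_pattern = extras$fractionation_pattern,
    image_technique = extras$image_technique,
    bolus_spec = if (is.null(extras$bolus_spec)) NULL else
      list(thickness_mm = extras$bolus_spec$thickness_mm,
           type = extras$bolus_spec$type,
           frequency = extras$bolus_spec$frequency)
  )

  tol_name <- "T1"
  tt <- get1(ds, "300A0040", list())
  if (length(tt) > 0L) tol_name <- get1(tt[[1]], "300A0043", "T1")
  pos_code <- "HFS"
  psu <- get1(ds, "300A0180", list())
  if (length(psu) > 0L) pos_code <- get1(psu[[1]], "00185100", "HFS")
  machine <- get1(beam_items[[1]], "300A00B2", "UNKNOWN")

  att <- logical(0)
  if (!is.null(extras$attestations)) {
    att <- vapply(extras$attestations, isTRUE, logical(1))
  }

  validate_snapshot(plan_snapshot(
    system = extras$system,
    patient_id = get1(ds, "00100020"),
    plan_name = get1(ds, "300A0003"),
    plan_label = get1(ds, "300A0002"),
    approval_status = get1(ds, "300E0002", "Unknown"),
    course_name = get1(ds, "00081030", "C1"),
    patient_position = pos_code,
    technique = get1(ds, "0008103E", "IMRT_VMAT"),
    machine_name = machine,
    tolerance_table_name = tol_name,
    prescription = rx,
    beams = beams,
    user_origin = extras$user_origin,
    localization_point = extras$localization_point,
    couch_delta = extras$couch_delta,
    attestations = att
  ))
}
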