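test_that("JSON snapshot round trip is the identity", {
  for (seed in c(1, 11)) {
    pair <- generate_plan_pair(seed, "IMRT_VMAT", 2,
                               errors = list(error_spec("wedge_removed"),
                                             error_spec("localization_offset")))
    for (s in list(pair$tps, pair$ois)) {
      p <- withr::local_tempfile(fileext = ".json")
      write_snapshot_json(s, p)
      expect_equal(read_snapshot_json(p), s)
    }
  }
})

test_that("snapshot schema violations point at the offending field", {
  s <- tiny_snapshot()
  p <- withr::local_tempfile(fileext = ".json")
  write_snapshot_json(s, p)
  j <- jsonlite::fromJSON(p, simplifyVector = FALSE)

  j1 <- j; j1$prescription <- NULL
  writeLines(jsonlite::toJSON(j1, auto_unbox = TRUE, digits = NA), p)
  expect_error(read_snapshot_json(p), "/prescription")

  j2 <- j; j2$beams[[1]]$mu <- "200"
  writeLines(jsonlite::toJSON(j2, auto_unbox = TRUE, digits = NA), p)
  expect_error(read_snapshot_json(p), "/beams/0/mu")

  writeLines("{\"format\": \"something-else\"}", p)
  expect_error(read_snapshot_json(p), "/format")
})

test_that("snapshot validation enforces machine-state invariants", {
  s <- tiny_snapshot()
  bad <- s
  bad$beams[[1]]$control_points[[1]]$mlc_bank_A <- rep(20, 4)  # crosses bank B
  expect_error(validate_snapshot(bad), "cross")

  bad <- s
  bad$beams[[1]]$control_points[[2]]$cumulative_weight <- -0.5
  expect_error(validate_snapshot(bad), "cumulative_weight")

  bad <- s
  bad$beams[[1]]$gantry_angle <- 380
  expect_error(validate_snapshot(bad), "gantry_angle")

  bad <- s
  bad$beams <- list()
  expect_error(validate_snapshot(bad), "at least one beam")
})

test_that("DICOM RT Plan round trip restores the snapshot exactly", {
  # photon dynamic plan with wedge and injected extras
  pair <- generate_plan_pair(5, "IMRT_VMAT", 3,
                             errors = list(error_spec("wedge_removed", beam = 2),
                                           error_spec("localization_offset")))
  # electron plan exercises applicator and electron energy labels
  el <- generate_plan_pair(6, "ELECTRON", 1)
  for (s in list(pair$tps, pair$ois, el$tps)) {
    p <- withr::local_tempfile(fileext = ".dcm")
    write_rtplan_dicom(s, p)
    expect_equal(read_rtplan_dicom(p), s)
  }
})

test_that("DICOM and JSON dialects of one manifest yield equal snapshots", {
  pair <- generate_plan_pair(9, "THREE_D", 2)
  d <- withr::local_tempdir()
  write_case(d, pair, dicom = TRUE)
  expect_equal(read_rtplan_dicom(file.path(d, "tps.dcm")),
               read_snapshot_json(file.path(d, "tps.json")))
  expect_equal(read_rtplan_dicom(file.path(d, "ois.dcm")),
               read_snapshot_json(file.path(d, "ois.json")))
})

test_that("the DICOM reader rejects non-RT-Plan inputs", {
  p <- withr::local_tempfile(fileext = ".dcm")
  writeBin(as.raw(rep(0, 200)), p)
  expect_error(read_rtplan_dicom(p), "DICM magic")

  # a syntactically valid DICOM file of the wrong SOP class (CT image)
  ct_uid <- "1.2.840.10008.5.1.4.1.1.2"
  ds <- c(chartcheckr:::dcm_elem(0x0008, 0x0016, "UI", ct_uid),
          chartcheckr:::dcm_elem(0x0008, 0x0060, "CS", "CT"))
  meta_body <- c(chartcheckr:::dcm_elem(0x0002, 0x0002, "UI", ct_uid),
                 chartcheckr:::dcm_elem(0x0002, 0x0010, "UI",
                                        "1.2.840.10008.1.2.1"))
  meta <- c(chartcheckr:::dcm_elem(0x0002, 0x0000, "UL", length(meta_body)),
            meta_body)
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), p)
  expect_error(read_rtplan_dicom(p), "not an RT Plan")
})

test_that("generated DICOM is readable by an independent DICOM implementation", {
  pair <- generate_plan_pair(21, "IMRT_VMAT", 2)
  p <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan_dicom(pair$tps, p)
  script <- paste(
    "import pydicom, sys",
    sprintf("d = pydicom.dcmread(r'%s')", p),
    "print(d.SOPClassUID)",
    "print('|'.join(b.BeamName for b in d.BeamSequence))",
    "print(d.FractionGroupSequence[0].ReferencedBeamSequence[0].BeamMeterset)",
    "print(len(d.BeamSequence[0].ControlPointSequence))",
    sep = "\n")
  out <- system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  expect_equal(out[1], "1.2.840.10008.5.1.4.1.1.481.5")
  expect_equal(out[2], paste(vapply(pair$tps$beams, `[[`, "", "beam_name"),
                             collapse = "|"))
  expect_equal(as.numeric(out[3]), pair$tps$beams[[1]]$mu)
  expect_equal(as.integer(out[4]), length(pair$tps$beams[[1]]$control_points))
})

test_that("structure summaries compute weighted centroids and bounding boxes", {
  square <- function(h, z) list(z = z, xy = cbind(c(-h, h, h, -h), c(-h, -h, h, h)))
  cube <- list(name = "CUBE", role = "Other", approval = TRUE,
               contours = lapply(seq(-20, 20, by = 5), function(z) square(20, z)))
  s <- summarize_structures(list(cube))
  expect_equal(unlist(s[1, c("centroid_x", "centroid_y", "centroid_z")]),
               c(centroid_x = 0, centroid_y = 0, centroid_z = 0))
  expect_equal(unlist(s[1, c("bbox_min_x", "bbox_min_y", "bbox_min_z")]),
               c(bbox_min_x = -20, bbox_min_y = -20, bbox_min_z = -20))
  expect_equal(unlist(s[1, c("bbox_max_x", "bbox_max_y", "bbox_max_z")]),
               c(bbox_max_x = 20, bbox_max_y = 20, bbox_max_z = 20))

  # two equal disjoint cubes at z = +/-30 average to z = 0
  twin <- list(name = "TWIN", role = "Target", approval = TRUE,
               contours = c(lapply(seq(25, 35, by = 5), function(z) square(10, z)),
                            lapply(seq(-35, -25, by = 5), function(z) square(10, z))))
  s2 <- summarize_structures(list(twin))
  expect_equal(s2$centroid_z, 0)

  degen <- list(name = "EMPTY", role = "OAR", approval = FALSE, contours = list())
  s3 <- summarize_structures(list(degen))
  expect_true(s3$degenerate)
  expect_true(is.na(s3$centroid_x))
})

test_that("HU statistics match the phantom's constructed ground truth", {
  ph <- generate_ct_phantom()
  expect_equal(compute_hu_stats(ph, ph$external),
               list(max_hu_inside = 0, max_hu_outside = -1000))

  # insert inside the External cylinder (grid center)
  ph2 <- generate_ct_phantom(inserts = list(list(hu = 3000, voxel = c(16, 16, 4))))
  expect_equal(compute_hu_stats(ph2, ph2$external),
               list(max_hu_inside = 3000, max_hu_outside = -1000))

  # insert in the air corner, outside the External cylinder
  ph3 <- generate_ct_phantom(inserts = list(list(hu = 3000, voxel = c(1, 1, 1))))
  expect_equal(compute_hu_stats(ph3, ph3$external),
               list(max_hu_inside = 0, max_hu_outside = 3000))

  # External covering the whole grid leaves no outside region
  ph4 <- generate_ct_phantom(external_radius_mm = 500)
  st <- compute_hu_stats(ph4, ph4$external)
  expect_true(is.na(st$max_hu_outside))
  expect_equal(st$max_hu_inside, 0)

  expect_error(compute_hu_stats(ph, NULL), "no External contour")
})

test_that("voxel labeling agrees with an independent point-in-polygon oracle", {
  ph <- generate_ct_phantom(shape = c(16L, 16L, 4L), external_radius_mm = 40,
                            spacing = c(6, 6, 2.5),
                            inserts = list(list(hu = 2500, voxel = c(8, 8, 2)),
                                           list(hu = 4000, voxel = c(1, 2, 3))))
  got <- compute_hu_stats(ph, ph$external)

  dims <- dim(ph$volume)
  xs <- ph$origin[1] + (seq_len(dims[1]) - 1) * ph$spacing[1]
  ys <- ph$origin[2] + (seq_len(dims[2]) - 1) * ph$spacing[2]
  inside_vals <- c(); outside_vals <- c()
  poly <- ph$external$contours[[1]]$xy
  for (k in seq_len(dims[3])) {
    for (j in seq_len(dims[2])) {
      for (i in seq_len(dims[1])) {
        inn <- mgcv::in.out(rbind(poly, poly[1, ]), matrix(c(xs[i], ys[j]), 1))
        if (inn) inside_vals <- c(inside_vals, ph$volume[i, j, k])
        else outside_vals <- c(outside_vals, ph$volume[i, j, k])
      }
    }
  }
  expect_equal(got$max_hu_inside, max(inside_vals))
  expect_equal(got$max_hu_outside, max(outside_vals))
})
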