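test_that("fractionation arithmetic check", {
  expect_equal(check_fractionation(prescription(5040, 180, 28))$verdict, "pass")
  r <- check_fractionation(prescription(5000, 180, 28))
  expect_equal(r$verdict, "fail")
  expect_match(r$detail, "5040")  # reports the product
  expect_match(r$detail, "tol")
  expect_equal(check_fractionation(prescription(200, 200, 1))$verdict, "pass")
  expect_equal(check_fractionation(prescription(5000, 180, 28), tol_cGy = 50)$verdict,
               "pass")
})

test_that("localization point vs user origin", {
  expect_equal(check_localization_consistency(c(0, 0, 0), c(0, 0, 0), 0.01)$verdict,
               "pass")
  r <- check_localization_consistency(c(0, 0, 0), c(0, 3, 0), 1)
  expect_equal(r$verdict, "fail")
  expect_match(r$detail, "3.00 mm")
  expect_equal(check_localization_consistency(c(0, 0, 0), NULL)$verdict,
               "not_applicable")
})

test_that("mono-isocenter spread", {
  b <- tiny_snapshot()$beams[[1]]
  b2 <- b; b2$beam_name <- "B02"
  expect_equal(check_mono_isocenter(list(b, b2))$verdict, "pass")
  b3 <- b2; b3$isocenter <- b$isocenter + c(5, 0, 0)
  r <- check_mono_isocenter(list(b, b3), tol_mm = 0.1)
  expect_equal(r$verdict, "fail")
  expect_match(r$detail, "5.000 mm")
  expect_equal(check_mono_isocenter(list(b))$verdict, "pass")
  # setup beams are exempt
  setup <- b3; setup$is_setup_beam <- TRUE
  expect_equal(check_mono_isocenter(list(b, setup))$verdict, "pass")
})

test_that("isocenter-to-target offset uses Euclidean distance", {
  target <- data.frame(degenerate = FALSE, centroid_x = 0, centroid_y = 0,
                       centroid_z = 0)
  expect_equal(check_isocenter_target_offset(c(0, 0, 0), target)$verdict, "pass")
  r <- check_isocenter_target_offset(c(0, 30, 40), target, max_mm = 49)
  expect_equal(r$verdict, "fail")
  expect_match(r$detail, "50.0 mm")  # 3-4-5 triangle
  expect_equal(check_isocenter_target_offset(c(0, 0, 0), NULL)$verdict,
               "not_applicable")
})

test_that("dose grid must cover the External bounding box", {
  box <- list(min = c(-10, -10, -10), max = c(10, 10, 10))
  expect_equal(check_dose_grid_covers_external(box, box)$verdict, "pass")
  shrunk <- list(min = c(-10, -10, -10), max = c(9, 10, 10))
  r <- check_dose_grid_covers_external(shrunk, box)
  expect_equal(r$verdict, "fail")
  expect_match(r$detail, "x axis")
  expect_equal(check_dose_grid_covers_external(NULL, box)$verdict,
               "not_applicable")
})

test_that("HU screening flags high-Z material inside the External", {
  cfg <- policy_config()
  ok <- check_hu_limits(list(max_hu_inside = 0, max_hu_outside = -1000), cfg)
  expect_equal(ok$verdict, "pass")
  expect_match(ok$detail, "-1000")
  bad <- check_hu_limits(list(max_hu_inside = 3000, max_hu_outside = -1000), cfg)
  expect_equal(bad$verdict, "fail")
  noout <- check_hu_limits(list(max_hu_inside = 100, max_hu_outside = NA), cfg)
  expect_equal(noout$verdict, "pass")
})

test_that("slice thickness limits are technique-specific", {
  cfg <- policy_config()
  expect_equal(check_slice_thickness("SRS", 1.0, cfg)$verdict, "pass")
  expect_equal(check_slice_thickness("SRS", 3.0, cfg)$verdict, "fail")
  expect_equal(check_slice_thickness("IMRT_VMAT", 3.0, cfg)$verdict, "pass")
  expect_error(check_slice_thickness("PROTON", 1.0, cfg), "no slice thickness limit")
})

test_that("delta couch policy differs for stereotactic and conventional plans", {
  expect_equal(check_delta_couch("SRS", NULL)$verdict, "fail")
  expect_equal(check_delta_couch("SRS", c(0.5, 0, 1))$verdict, "pass")
  expect_equal(check_delta_couch("THREE_D", c(0, 0, 0))$verdict, "pass")
  expect_equal(check_delta_couch("THREE_D", NULL)$verdict, "pass")
  expect_equal(check_delta_couch("THREE_D", c(1.0, 0, 0))$verdict, "fail")
})

test_that("jaw-to-MLC-leaf gap for stereotactic fields", {
  cfg <- policy_config()
  mk <- function(x1, x2, a, b) {
    beam("B01", jaws = c(x1 = x1, x2 = x2, y1 = -50, y2 = 50),
         control_points = list(control_point(0L, 0, a, b), control_point(1L, 1, a, b)))
  }
  # jaws exactly at the open leaf tips: gap 0, allowed band starts at 0
  tight <- mk(-30, 30, rep(-30, 10), rep(30, 10))
  expect_equal(check_jaw_mlc_gap_srs(tight, "SRS", cfg)$verdict, "pass")
  # jaw 20 mm beyond the leaf tips with a 5 mm cap
  wide <- mk(-50, 30, rep(-30, 10), rep(30, 10))
  r <- check_jaw_mlc_gap_srs(wide, "SRS", cfg)
  expect_equal(r$verdict, "fail")
  expect_match(r$detail, "20.0 mm")
  expect_equal(check_jaw_mlc_gap_srs(wide, "IMRT_VMAT", cfg)$verdict,
               "not_applicable")
  # fully closed MLC: nothing to measure
  closed <- mk(-30, 30, rep(0, 10), rep(0, 10))
  expect_equal(check_jaw_mlc_gap_srs(closed, "SRS", cfg)$verdict,
               "not_applicable")
})

test_that("hotspot detection counts voxels strictly above 110% of prescription", {
  rx <- prescription(5000, 200, 25)
  uniform <- list(values = array(5000, dim = c(10, 10, 10)))
  r <- check_hotspot(uniform, rx)
  expect_equal(r$verdict, "pass")
  expect_equal(attr(r, "hotspot_fraction"), 0)

  seven <- uniform
  seven$values[c(1, 5, 100, 200, 500, 999, 1000)] <- 5800  # 116% of Rx
  r7 <- check_hotspot(seven, rx)
  expect_equal(r7$verdict, "fail")
  expect_equal(attr(r7, "hotspot_fraction"), 0.007)
  expect_match(r7$detail, "7/1000")

  border <- uniform
  border$values[42] <- 5500  # exactly 110%: not a hotspot
  expect_equal(check_hotspot(border, rx)$verdict, "pass")
})

test_that("course name is compared after trimming and case folding", {
  expect_equal(check_course_name("Prostate", "Prostate")$verdict, "pass")
  expect_equal(check_course_name("Prostate ", "prostate")$verdict, "pass")
  expect_equal(check_course_name("Pelvis", "Prostate")$verdict, "fail")
})

test_that("policy YAML round trips into a policy_config", {
  cfg <- read_policy_yaml(system.file("extdata", "policy_default.yaml",
                                      package = "chartcheckr"))
  expect_s3_class(cfg, "policy_config")
  expect_equal(cfg$hu_high_z_threshold, 2000)
  expect_equal(cfg$slice_thickness_max_mm[["SRS"]], 1.25)
  expect_equal(cfg$srs_jaw_mlc_gap_mm, c(0, 5))
  expect_equal(cfg$hotspot_threshold_fraction, 1.10)
})

test_that("the orchestrated battery isolates the injected failure", {
  cl <- fixture_checklist()
  mk_case <- function(errors = list()) {
    pair <- generate_plan_pair(31, "THREE_D", 2, errors = errors)
    ct <- generate_ct_phantom(31)
    target <- list(name = "PTV", role = "Target", approval = TRUE,
                   contours = lapply(ct$external$contours, function(c)
                     list(z = c$z, xy = c$xy * 0.3)))
    dose <- generate_dose_grid(31, c(16L, 16L, 8L),
                               pair$tps$prescription$total_dose, 0,
                               spacing = c(8, 8, 2.5))
    run_all(pair$tps, pair$ois, structures = list(ct$external, target),
            ct = ct, dose_grid = dose, checklist = cl)
  }
  clean <- mk_case()
  verdicts <- vapply(clean$checks, `[[`, "", "verdict")
  expect_true(clean$report$clean)
  expect_false(any(verdicts == "fail"))
  expect_true(all(verdicts[c("fractionation", "hu_limits", "hotspot",
                             "slice_thickness", "course_name")] == "pass"))
  # linked checklist item ids come from the packaged fixture
  expect_true("PA-01" %in% clean$checks$fractionation$linked_items)

  broken <- mk_case(list(error_spec("fractionation_mismatch")))
  v2 <- vapply(broken$checks, `[[`, "", "verdict")
  expect_equal(v2[["fractionation"]], "fail")
  expect_equal(v2[names(v2) != "fractionation"],
               verdicts[names(verdicts) != "fractionation"])
  expect_false(broken$report$clean)

  # no CT: the CT-dependent checks degrade to not_applicable, rest unchanged
  pair <- generate_plan_pair(31, "THREE_D", 2)
  noct <- run_all(pair$tps, pair$ois, checklist = cl)
  v3 <- vapply(noct$checks, `[[`, "", "verdict")
  expect_equal(v3[["hu_limits"]], "not_applicable")
  expect_equal(v3[["slice_thickness"]], "not_applicable")
  expect_equal(v3[["hotspot"]], "not_applicable")
  expect_equal(v3[["fractionation"]], "pass")
})
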