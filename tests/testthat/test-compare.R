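test_that("a snapshot compared with itself is clean under any tolerance profile", {
  set.seed(7)
  for (tech in c("IMRT_VMAT", "THREE_D", "ELECTRON")) {
    pair <- generate_plan_pair(sample.int(1e6, 1), tech, 2)
    for (tol in list(tolerance_profile(),
                     tolerance_profile(default = 5),
                     tolerance_profile(overrides = c("beams[*].mu" = 0.01)))) {
      r <- compare_plans(pair$tps, pair$tps, tol)
      expect_true(r$clean)
      expect_length(r$discrepancies, 0)
    }
  }
})

test_that("numeric fields are flagged iff the difference exceeds the tolerance", {
  a <- tiny_snapshot(mu = 200.0)
  b <- tiny_snapshot(system = "OIS", mu = 201.0)
  r <- compare_plans(a, b)
  df <- discrepancies_df(r)
  expect_equal(nrow(df), 1L)
  expect_equal(df$field_path, "beams[1].mu")
  expect_equal(df$abs_difference, 1.0)

  a2 <- tiny_snapshot(mu = 100.0)
  b2 <- tiny_snapshot(system = "OIS", mu = 100.4)
  tol <- tolerance_profile(overrides = c("beams[*].mu" = 0.5))
  expect_true(compare_plans(a2, b2, tol)$clean)  # 0.4 <= 0.5 passes
  expect_false(compare_plans(a2, b2)$clean)      # zero tolerance flags it
})

test_that("angle differences wrap on the circle", {
  expect_equal(angle_difference(359.8, 0.1), 0.3, tolerance = 1e-9)
  expect_equal(angle_difference(42, 42), 0)
  expect_equal(angle_difference(0, 180), 180)
  expect_equal(angle_difference(350, 10), 20)
})

test_that("MLC comparison reports per-leaf deviations and structural mismatches", {
  b1 <- tiny_snapshot()$beams[[1]]
  expect_equal(compare_mlc(b1, b1)$max_leaf_deviation, 0)
  expect_length(compare_mlc(b1, b1)$discrepancies, 0)

  b2 <- b1
  b2$control_points[[2]]$mlc_bank_B[3] <- b2$control_points[[2]]$mlc_bank_B[3] + 2.0
  res <- compare_mlc(b1, b2)
  expect_equal(res$max_leaf_deviation, 2.0)
  expect_length(res$discrepancies, 1L)
  expect_match(res$discrepancies[[1]]$field_path, "control_points\\[2\\].mlc_bank_B\\[3\\]")

  b3 <- b1
  b3$control_points <- b3$control_points[1]  # 1 CP vs 2 CPs
  res3 <- compare_mlc(b1, b3)
  expect_length(res3$discrepancies, 1L)
  expect_equal(res3$discrepancies[[1]]$severity, "structural")
  expect_equal(res3$max_leaf_deviation, 0)
})

test_that("detection is symmetric in the two systems", {
  for (seed in c(3, 4)) {
    types <- sample(snapshot_error_types(), 4)
    pair <- generate_plan_pair(seed, "IMRT_VMAT", 2,
                               errors = lapply(types, error_spec))
    fwd <- sort(flagged_paths(compare_plans(pair$tps, pair$ois)))
    rev <- sort(flagged_paths(compare_plans(pair$ois, pair$tps)))
    expect_equal(fwd, rev)
  }
})

test_that("raising tolerances never increases the discrepancy count", {
  pair <- generate_plan_pair(13, "IMRT_VMAT", 2,
                             errors = list(error_spec("mu_delta", magnitude = 0.3),
                                           error_spec("mlc_leaf_shift", magnitude = 0.05),
                                           error_spec("gantry_delta", magnitude = 2)))
  tols <- list(tolerance_profile(0),
               tolerance_profile(overrides = c("beams[*].control_points[*].mlc_bank_A[*]" = 0.1,
                                               "beams[*].control_points[*].mlc_bank_B[*]" = 0.1)),
               tolerance_profile(0.5),
               tolerance_profile(5))
  counts <- vapply(tols, function(tl)
    length(compare_plans(pair$tps, pair$ois, tl)$discrepancies), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_true(counts[1] >= 3L)
})

test_that("unmatched and duplicated beam names are structural findings", {
  a <- tiny_snapshot()
  b <- tiny_snapshot(system = "OIS")
  b$beams[[1]]$beam_name <- "B99"
  r <- compare_plans(a, b)
  paths <- flagged_paths(r)
  expect_setequal(paths, c("beams[name=B01]", "beams[name=B99]"))
  expect_true(all(vapply(r$discrepancies, `[[`, "", "severity") == "structural"))

  dup <- a
  dup$beams <- list(a$beams[[1]], a$beams[[1]])
  r2 <- compare_plans(dup, b)
  expect_true(any(grepl("beams\\[name=B01\\]", flagged_paths(r2))))
})

test_that("tolerance YAML profiles load and apply by glob", {
  p <- system.file("extdata", "tolerances_example.yaml", package = "chartcheckr")
  tol <- read_tolerance_yaml(p)
  expect_equal(tol$default, 0)
  expect_equal(chartcheckr:::tolerance_for(tol, "beams[2].mu"), 0.01)
  expect_equal(chartcheckr:::tolerance_for(tol, "beams[1].control_points[4].mlc_bank_B[17]"), 0.1)
  expect_equal(chartcheckr:::tolerance_for(tol, "plan_name"), 0)
  expect_error(tolerance_profile(default = -1), ">= 0")
})
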