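test_that("the packaged 60-item checklist loads with the published class tallies", {
  cl <- fixture_checklist()
  expect_s3_class(cl, "checklist")
  expect_equal(length(cl), 60L)
  tal <- tally_classes(cl, "auto_umms_exp")
  expect_equal(tal, c(Full = 35L, `Full/Partial` = 17L, Partial = 6L, No = 2L))
  expect_equal(sum(tal), 60L)
  # the TG-275 survey column only uses Partial/No on these items
  tal275 <- tally_classes(cl, "auto_tg275")
  expect_equal(unname(tal275["Full"]), 0L)
  expect_equal(sum(tal275), 60L)
})

test_that("tally counts always sum to the item count, across scenarios", {
  cl <- fixture_checklist()
  for (sc in c("none", "auto_tg275", "auto_umms_exp")) {
    expect_equal(sum(tally_classes(cl, sc)), length(cl))
  }
  single <- toy_checklist("Full")
  expect_equal(tally_classes(single, "auto_umms_exp"),
               c(Full = 1L, `Full/Partial` = 0L, Partial = 0L, No = 0L))
  expect_equal(tally_classes(single, "none"),
               c(Full = 0L, `Full/Partial` = 0L, Partial = 0L, No = 1L))
})

test_that("automation weights follow the manual-burden scale", {
  expect_identical(automation_weight("Full"), 0)
  expect_identical(automation_weight("Partial"), 0.5)
  expect_identical(automation_weight("No"), 1)
  expect_identical(automation_weight("Full/Partial"), 0.25)
  w <- automation_weight(automation_classes())
  expect_true(all(diff(w) > 0))  # Full < Full/Partial < Partial < No
  expect_error(automation_weight("Maybe"), "unknown automation class")
})

test_that("priority filtering applies both strict thresholds and preserves order", {
  cl <- toy_checklist(c("Full", "Full", "Full"),
                      rpn = c(150L, 90L, 120L),
                      use_frequency = c(0.7, 0.8, 0.5))
  kept <- filter_priority(cl, 100, 0.60)
  expect_equal(length(kept), 1L)
  expect_equal(kept$items$item_id, "X-01")
  expect_true(all(kept$items$item_id %in% cl$items$item_id))

  # boundary: rpn == threshold is excluded (strict inequality)
  bd <- toy_checklist("Full", rpn = 100L, use_frequency = 0.99)
  expect_equal(length(filter_priority(bd, 100, 0.60)), 0L)

  empty <- filter_priority(cl, 1000, 0.99)
  expect_equal(length(filter_priority(empty, 100, 0.60)), 0L)

  # an item without risk attributes aborts the run instead of being dropped
  bad <- toy_checklist(c("Full", "Full"), rpn = c(150L, NA),
                       use_frequency = c(0.7, 0.7))
  expect_error(filter_priority(bad, 100, 0.60), "without rpn/use_frequency")
})

test_that("priority filter result is a subset for random inputs", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    cl <- toy_checklist(rep("Full", n),
                        rpn = sample(0:300, n, replace = TRUE),
                        use_frequency = round(stats::runif(n), 2))
    thr_r <- sample(0:200, 1); thr_u <- stats::runif(1)
    kept <- filter_priority(cl, thr_r, thr_u)
    expect_true(all(kept$items$item_id %in% cl$items$item_id))
    expect_true(all(kept$items$rpn > thr_r))
    expect_true(all(kept$items$use_frequency > thr_u))
  }
})

test_that("checklist CSV loader rejects malformed inputs", {
  hdr <- paste(chartcheckr:::.checklist_columns, collapse = ",")
  p <- withr::local_tempfile(fileext = ".csv")

  writeLines(hdr, p)
  expect_error(load_checklist(p), "no items")

  writeLines(c(hdr,
               "A-1,TG275,Simulation,x,,,,No,,Maybe"), p)
  expect_error(load_checklist(p), "unknown automation class")

  writeLines(c(hdr,
               "A-1,TG275,Simulation,x,,,,No,,Full",
               "A-1,TG275,Simulation,y,,,,No,,Full"), p)
  expect_error(load_checklist(p), "duplicate item_id")

  writeLines(c(hdr,
               "A-1,TG275,Elsewhere,x,,,,No,,Full"), p)
  expect_error(load_checklist(p), "unknown category")

  writeLines(c(hdr,
               "A-1,TG275,Simulation,x,,1.7,,No,,Full"), p)
  expect_error(load_checklist(p), "use_frequency")
})

test_that("write/load round trip reproduces items exactly", {
  cl <- fixture_checklist()
  p <- withr::local_tempfile(fileext = ".csv")
  write_checklist(cl, p)
  cl2 <- load_checklist(p, name = cl$name)
  expect_identical(cl$items, cl2$items)
})

test_that("the TG-315 skeleton fixture carries 36 recommended + 8 optional rows", {
  cl <- load_checklist(system.file("extdata", "tg315_skeleton.csv",
                                   package = "chartcheckr"))
  expect_equal(length(cl), 44L)
  expect_equal(sum(cl$items$recommended), 36L)
  expect_equal(sum(!cl$items$recommended), 8L)
  # no stored automation classes: only the fully-manual scenario applies
  expect_equal(unname(tally_classes(cl, "none")["No"]), 44L)
  expect_error(tally_classes(cl, "auto_umms_exp"), "no class for item")
})
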