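test_that("residual time is the weight-scaled sum of item times", {
  cl <- toy_checklist(c("Full", "Full/Partial", "Partial", "No"))
  per_item <- list(total_minutes = 40,
                   per_item_minutes = stats::setNames(rep(10, 4), cl$items$item_id))
  expect_equal(residual_time(cl, "auto_umms_exp", per_item), 17.5)  # 0+2.5+5+10
  # uniform allocation of the same total gives the same answer here
  expect_equal(residual_time(cl, "auto_umms_exp", 40), 17.5)
  expect_equal(residual_time(toy_checklist(rep("Full", 6)), "auto_umms_exp", 60), 0)
  expect_equal(residual_time(cl, "none", 40), 40)  # no automation keeps it all
  expect_error(residual_time(cl, "auto_umms_tool", 40), "no class")
})

test_that("time reduction percentage", {
  expect_equal(time_reduction_percent(40, 40), 0)
  expect_equal(time_reduction_percent(0, 40), 100)
  expect_equal(time_reduction_percent(17.5, 40), 56.25)
})

test_that("residual error percentages scale the baseline by the manual burden", {
  base <- c(PatientAssessment = 7.7, Simulation = 28.2, TreatmentPlanning = 49.2)
  cl_all_full <- toy_checklist(rep("Full", 9),
                               categories = rep(names(base), each = 3))
  expect_equal(residual_error_percent(cl_all_full, "auto_umms_exp", base),
               c(PatientAssessment = 0, Simulation = 0, TreatmentPlanning = 0))
  # no automation reproduces the baseline exactly
  expect_equal(residual_error_percent(cl_all_full, "none", base), base)

  two <- toy_checklist(c("No", "Full"), categories = rep("Simulation", 2))
  expect_equal(residual_error_percent(two, "auto_umms_exp", base)[["Simulation"]],
               14.1)  # burden 0.5 of 28.2
  # steps without items are absent from the result
  expect_named(residual_error_percent(two, "auto_umms_exp", base), "Simulation")

  # count mode treats any non-Full item as fully manual
  half <- toy_checklist(c("Partial", "Full"), categories = rep("Simulation", 2))
  expect_equal(residual_error_percent(half, "auto_umms_exp", base,
                                      error_model = "count")[["Simulation"]],
               14.1)
  expect_equal(residual_error_percent(half, "auto_umms_exp", base)[["Simulation"]],
               28.2 * 0.25)
})

test_that("lowering any item's class weight never increases residual burden", {
  set.seed(99)
  base <- load_baseline_errors()
  classes <- automation_classes()
  for (rep in 1:15) {
    n <- sample(3:12, 1)
    cls <- sample(classes, n, replace = TRUE)
    cats <- sample(names(base), n, replace = TRUE)
    cl <- toy_checklist(cls, categories = cats)
    t0 <- residual_time(cl, "auto_umms_exp", 60)
    e0 <- residual_error_percent(cl, "auto_umms_exp", base)
    # improve one item to a strictly lower-weight class
    i <- sample(n, 1)
    pos <- match(cls[i], classes)
    if (pos == 1L) next
    cls2 <- cls; cls2[i] <- classes[sample.int(pos - 1L, 1)]
    cl2 <- toy_checklist(cls2, categories = cats)
    expect_lte(residual_time(cl2, "auto_umms_exp", 60), t0)
    e1 <- residual_error_percent(cl2, "auto_umms_exp", base)
    expect_true(all(e1 <= e0[names(e1)] + 1e-12))
  }
})

test_that("higher automation levels dominate on the packaged checklist", {
  cl <- fixture_checklist()
  total <- 72.8
  t_none <- residual_time(cl, "none", total)
  t_tg <- residual_time(cl, "auto_tg275", total)
  t_exp <- residual_time(cl, "auto_umms_exp", total)
  expect_true(t_none >= t_tg)
  expect_true(t_tg >= t_exp)
  expect_equal(t_none, total)
  base <- load_baseline_errors()
  e_none <- residual_error_percent(cl, "none", base)
  e_exp <- residual_error_percent(cl, "auto_umms_exp", base)
  expect_true(all(e_exp <= e_none))
  expect_equal(e_none, base)
})

test_that("the simulation grid emits one ordered row per combination", {
  cl <- fixture_checklist()
  profiles <- load_time_profiles()
  rep <- simulate_benefit(list(TG275_full = cl),
                          c("none", "auto_umms_exp"), profiles)
  expect_equal(nrow(rep), 6L)  # 2 scenarios x 3 techniques
  expect_equal(unique(rep$scenario), c("none", "auto_umms_exp"))
  expect_true(all(rep$residual_minutes >= 0))
  expect_true(all(rep$residual_minutes <= rep$total_minutes))
  none_rows <- rep[rep$scenario == "none", ]
  expect_equal(none_rows$residual_minutes, none_rows$total_minutes)
  expect_equal(none_rows$residual_err_Simulation, rep(28.2, 3))

  empty <- simulate_benefit(list(TG275_full = cl), character(0), profiles)
  expect_equal(nrow(empty), 0L)
  expect_error(simulate_benefit(list(nope = cl), "none", profiles),
               "no time profile rows")
})

test_that("packaged time profiles carry all four checklists and three techniques", {
  tp <- load_time_profiles()
  expect_equal(nrow(tp), 36L)
  expect_setequal(unique(tp$checklist_name),
                  c("TG315_full", "TG275_full", "TG315_recommended", "TG275_priority"))
  expect_setequal(unique(tp$technique), c("IMRT_VMAT", "THREE_D", "SIMPLE_2D"))
  expect_true(all(tp$total_minutes > 0))
  # full lists take at least as long as their derived lists, per statistic
  for (st in c("max", "median")) {
    for (te in unique(tp$technique)) {
      g <- function(cl) tp$total_minutes[tp$checklist_name == cl &
                                           tp$stat == st & tp$technique == te]
      expect_gte(g("TG275_full"), g("TG275_priority"))
      expect_gte(g("TG315_full"), g("TG315_recommended"))
    }
  }
})
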