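test_that("two-point interpolation reproduces the worked dose", {
  expect_equal(round(interpolate_dose(17, 75, 252, 552, 400), 1), 45.6)
  expect_identical(interpolate_dose(17, 75, 252, 552, 252), 17)
  expect_identical(interpolate_dose(17, 75, 252, 552, 552), 75)
})

test_that("interpolation validates its anchors", {
  expect_error(interpolate_dose(75, 17, 252, 552, 400), "cm_max")
  expect_error(interpolate_dose(17, 75, 400, 400, 400),
               "zero dose sensitivity")
  expect_error(interpolate_dose(17, 75, NA, 552, 400), "finite")
})

test_that("interpolated dose is monotone in the target", {
  targets <- seq(260, 540, by = 20)
  doses <- interpolate_dose(17, 75, 252, 552, targets)
  expect_true(all(diff(doses) > 0))
  # mirrored when the dose-response slope is negative
  doses_neg <- interpolate_dose(17, 75, 552, 252, targets)
  expect_true(all(diff(doses_neg) < 0))
})

test_that("plan_dose fills a complete plan and re-prediction is exact", {
  m <- table3_model()
  pat <- example_patient()
  plan <- plan_dose(pat, m)
  expect_identical(plan$cm_min, 17)
  expect_identical(plan$cm_max, 75)
  expect_identical(plan$target_cta, 400)
  expect_identical(
    plan$cm_expect,
    interpolate_dose(17, 75, plan$v8_at_cm_min, plan$v8_at_cm_max, 400))
  if (plan$achievable && !plan$clipped) {
    pat$cm <- plan$cm_expect
    expect_lt(abs(predict_cta(pat, m) - 400), 1e-6)
  }
  # target set exactly at an extreme prediction returns that extreme dose
  plan_hi <- plan_dose(pat, m, target = plan$v8_at_cm_max)
  expect_equal(plan_hi$cm_expect, 75, tolerance = 1e-9)
})

test_that("unachievable targets are flagged and clipped into the dose range", {
  m <- table3_model()
  pat <- example_patient()
  base <- plan_dose(pat, m)
  far <- max(base$v8_at_cm_min, base$v8_at_cm_max) + 500
  plan <- plan_dose(pat, m, target = far)
  expect_false(plan$achievable)
  expect_true(plan$clipped)
  expect_true(plan$cm_expect >= 17 && plan$cm_expect <= 75)
  plan_free <- plan_dose(pat, m, target = far, clip = FALSE)
  expect_false(plan_free$clipped)
  expect_false(plan_free$cm_expect >= 17 && plan_free$cm_expect <= 75)
})

test_that("closed-loop planning over a testified cohort hits the target", {
  m <- table3_model()
  cohort <- suppressWarnings(
    simulate_cohort(table4_cohort_spec(n = 65, seed = 40)))
  plans <- suppressMessages(suppressWarnings(plan_cohort(cohort, m)))
  expect_identical(nrow(plans), 65L)
  ok <- plans$achievable & !plans$clipped & is.na(plans$error)
  expect_gt(sum(ok), 30)  # most plans are directly attainable
  replanned <- cohort[ok, ]
  replanned$cm <- plans$cm_expect[ok]
  achieved <- suppressWarnings(predict_cta(replanned, m))
  expect_lt(max(abs(achieved - 400)), 1e-6)
})

test_that("dosing to target then rescanning with noise centres near 400", {
  # structural analog of an in-vivo verification: plan each dose, then
  # regenerate the observed CTA number at the planned dose with the
  # generator's residual noise
  m <- table3_model()
  spec <- table4_cohort_spec(n = 65, seed = 41)
  cohort <- suppressWarnings(simulate_cohort(spec))
  plans <- suppressMessages(suppressWarnings(plan_cohort(cohort, m)))
  ok <- plans$achievable & !plans$clipped & is.na(plans$error)
  dosed <- cohort[ok, ]
  dosed$cm <- plans$cm_expect[ok]
  dosed$cta_la <- NULL
  set.seed(41)
  observed <- suppressWarnings(attach_responses(dosed, spec))$cta_la
  expect_lt(abs(mean(observed) - 400), 15)
  # spread driven by the residual noise scale: same order as a few
  # tens of raw CTA units
  expect_true(sd(observed) > 5 && sd(observed) < 60)
})

test_that("cohort planning is deterministic and rejects empty input", {
  m <- table3_model()
  cohort <- rbind(example_patient(), example_patient())
  cohort$patient_id <- c("A", "B")
  plans <- suppressMessages(plan_cohort(cohort, m))
  expect_identical(plans$cm_expect[1], plans$cm_expect[2])
  expect_error(plan_cohort(cohort[0, ], m), "empty")
})
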