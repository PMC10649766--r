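test_that("normalization maps the documented worked readings correctly", {
  expect_equal(round(normalize_reading(60, 24, 90), 4), 0.0909)
  expect_equal(round(normalize_reading(33, 24, 90), 4), -0.7273)
  expect_identical(normalize_reading(90, 24, 90), 1)
  expect_identical(normalize_reading(24, 24, 90), -1)
  expect_identical(normalize_reading(57, 24, 90), 0)
})

test_that("denormalization is the exact inverse and hits the bounds", {
  expect_equal(denormalize_reading(1, 24, 90), 90)
  expect_equal(denormalize_reading(-0.7273, 24, 90), 33, tolerance = 1e-3)
  expect_equal(denormalize_reading(normalize_reading(41.7, 24, 90), 24, 90),
               41.7)
})

test_that("round trip and affinity hold over random readings", {
  set.seed(101)
  spec <- table1_cohort_spec()
  for (id in factor_ids()) {
    f <- spec$factors[[id]]
    x <- runif(1000, f$min, f$max)
    back <- denormalize_reading(normalize_reading(x, f$min, f$max),
                                f$min, f$max)
    expect_lt(max(abs(back - x)), 1e-9 * (f$max - f$min))
  }
  # normalize is affine: convex combinations commute with the map
  alpha <- runif(200)
  x1 <- runif(200, 24, 90); x2 <- runif(200, 24, 90)
  lhs <- normalize_reading(alpha * x1 + (1 - alpha) * x2, 24, 90)
  rhs <- alpha * normalize_reading(x1, 24, 90) +
    (1 - alpha) * normalize_reading(x2, 24, 90)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("degenerate and non-finite inputs are rejected", {
  expect_error(normalize_reading(5, 10, 10), "degenerate")
  expect_error(normalize_reading(5, 10, 4), "degenerate")
  expect_error(normalize_reading(NaN, 0, 1), "finite")
  expect_error(denormalize_reading(0.5, 3, 3), "degenerate")
})

test_that("derive_bounds reproduces cohort extremes and flags constants", {
  cohort <- simulate_cohort(table1_cohort_spec(n = 80, seed = 2))
  b <- derive_bounds(cohort)
  expect_s3_class(b, "cta_bounds")
  expect_identical(b$factor, c(factor_ids(), response_id()))
  for (id in factor_ids()) {
    i <- match(id, b$factor)
    expect_identical(b$min[i], min(cohort[[id]]))
    expect_identical(b$max[i], max(cohort[[id]]))
  }
  i <- match(response_id(), b$factor)
  expect_equal(b$max[i], max(cohort$cta_la) / 400)
  # normalizing the derivation cohort itself hits -1/+1 exactly
  V <- normalize_cohort(cohort, b)
  expect_equal(unname(apply(V, 2, min)), rep(-1, 7))
  expect_equal(unname(apply(V, 2, max)), rep(1, 7))

  cohort$hr <- 70
  expect_error(derive_bounds(cohort), "hr")
})

test_that("out-of-range policy warns by default and rejects in strict mode", {
  cohort <- simulate_cohort(table1_cohort_spec(n = 10, seed = 3))
  b <- derive_bounds(cohort)
  stranger <- example_patient()
  stranger$age <- max(cohort$age) + 5
  expect_warning(V <- normalize_cohort(stranger, b), "extrapolated")
  expect_gt(V[1, "age"], 1)
  expect_identical(attr(V, "n_out_of_range"), 1L)
  expect_error(normalize_cohort(stranger, b, policy = "strict"), "age")
})

test_that("bounds tables require all eight entries and strict ordering", {
  b <- table3_model()$bounds
  expect_silent(cta_bounds(b))
  expect_error(cta_bounds(b[-3, ]), "exactly one row")
  b_bad <- b
  b_bad$max[2] <- b_bad$min[2]
  expect_error(cta_bounds(b_bad), "kvp")
})

test_that("response scale round-trips through /400 and its bounds", {
  b <- table3_model()$bounds
  expect_equal(denormalize_response(1, b), 2.17 * 400)
  expect_equal(denormalize_response(-1, b), 0.61 * 400)
  expect_equal(denormalize_response(0, b), 1.39 * 400)
  cta <- c(244, 400, 868, 515.3)
  expect_equal(denormalize_response(normalize_response(cta, b), b), cta)
})
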