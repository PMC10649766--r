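test_that("design expansion has the canonical 29-term structure", {
  row0 <- expand_design(rep(0, 7))
  expect_length(row0, 29)
  expect_identical(names(row0), term_labels())
  expect_equal(unname(row0), c(rep(0, 28), 1))

  expect_equal(unname(expand_design(rep(1, 7))), rep(1, 29))

  set.seed(7)
  v <- runif(7, -1, 1)
  row <- expand_design(v)
  # every interaction is exactly the product of its two main effects
  pairs <- combn(7, 2)
  for (k in seq_len(ncol(pairs))) {
    expect_identical(unname(row[7 + k]), v[pairs[1, k]] * v[pairs[2, k]])
  }
  expect_identical(unname(row[29]), 1)
  expect_error(expand_design(rep(0, 6)), "7")
})

test_that("design_matrix agrees with row-wise expansion", {
  set.seed(8)
  V <- matrix(runif(5 * 7, -1, 1), 5, 7)
  X <- design_matrix(V)
  expect_identical(dim(X), c(5L, 29L))
  for (i in 1:5) expect_equal(X[i, ], expand_design(V[i, ]))
})

test_that("QR solver matches the explicit normal-equations oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(c(40, 450), 1)
    prob <- random_problem(n)
    got <- ipa_fit(prob$X, prob$y)$coefficients
    want <- normal_equations_fit(prob$X, prob$y)
    expect_equal(unname(got), want, tolerance = 1e-6)
  }
})

test_that("noiseless fits recover the generating coefficients", {
  set.seed(9)
  prob <- random_problem(120, noise_sd = 0)
  fit <- ipa_fit(prob$X, prob$y)
  expect_equal(unname(fit$coefficients), prob$a_true, tolerance = 1e-8)
  expect_lt(fit$diagnostics$loss_phi, 1e-16 * 120)
})

test_that("least squares is invariant to patient order", {
  set.seed(10)
  prob <- random_problem(80)
  perm <- sample(80)
  a1 <- ipa_fit(prob$X, prob$y)$coefficients
  a2 <- ipa_fit(prob$X[perm, ], prob$y[perm])$coefficients
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("diagnostics are internally consistent", {
  set.seed(11)
  for (rep in 1:5) {
    prob <- random_problem(200, noise_sd = 0.3)
    fit <- ipa_fit(prob$X, prob$y)
    d <- fit$diagnostics
    expect_gte(d$loss_phi, 0)
    expect_true(d$variance >= 0 && d$variance <= 1)
    # with an intercept column, R^2 equals the obs-pred correlation squared
    expect_equal(d$variance, d$r^2, tolerance = 1e-9)
    # residuals orthogonal to every design column
    resid <- prob$y - drop(prob$X %*% fit$coefficients)
    expect_lt(max(abs(t(prob$X) %*% resid)), 1e-6 * 200)
  }
})

test_that("rank deficiency and underdetermined systems are errors", {
  set.seed(12)
  prob <- random_problem(100)
  X <- prob$X
  X[, "G"] <- X[, "A"]  # duplicate a main effect
  expect_error(ipa_fit(X, prob$y), "rank-deficient")
  expect_error(ipa_fit(prob$X[1:20, ], prob$y[1:20]), "underdetermined")
})

test_that("prediction at the zero vector returns the constant", {
  m <- table3_model()
  expect_identical(predict_normalized(rep(0, 7), m$coefficients),
                   -0.419399)
  expect_identical(predict_normalized(runif(7, -1, 1), rep(0, 29)), 0)
})

test_that("the model is affine in each single factor", {
  m <- table3_model()
  set.seed(13)
  for (j in 1:7) {
    v <- runif(7, -1, 1)
    v_hi <- v; v_hi[j] <- 1
    v_lo <- v; v_lo[j] <- -1
    v_mid <- v; v_mid[j] <- 0
    mid <- (predict_normalized(v_hi, m$coefficients) +
              predict_normalized(v_lo, m$coefficients)) / 2
    expect_equal(predict_normalized(v_mid, m$coefficients), mid,
                 tolerance = 1e-12)
  }
})

test_that("raw-scale predictions map the response bounds correctly", {
  m <- table3_model()
  expect_equal(denormalize_response(c(-1, 0, 1), m$bounds),
               c(244, 556, 868))
})

test_that("fit_ipa on a simulated cohort recovers the ground truth", {
  spec <- table1_cohort_spec(n = 450, seed = 5, residual_sd = 0)
  cohort <- simulate_cohort(spec)
  fit <- fit_ipa(cohort, bounds = spec$bounds)
  expect_equal(fit$coefficients, spec$ground_truth, tolerance = 1e-8)
  expect_lt(fit$diagnostics$loss_phi, 1e-14)
})

test_that("coefficient RMSE shrinks as the cohort grows", {
  sizes <- c(100, 450, 4500)
  rmse <- vapply(seq_along(sizes), function(k) {
    errs <- vapply(1:8, function(r) {
      spec <- table1_cohort_spec(n = sizes[k], seed = 1000 * k + r)
      cohort <- simulate_cohort(spec)
      fit <- fit_ipa(cohort, bounds = spec$bounds)
      sqrt(mean((fit$coefficients - spec$ground_truth)^2))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(rmse[1] > rmse[2] && rmse[2] > rmse[3])
})
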