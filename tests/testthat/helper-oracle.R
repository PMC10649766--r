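# Independent least-squares oracle: the explicit dense-inverse
# normal-equations solve M = (V'V)^-1 V'Y. Deliberately naive; used
# only to cross-check the package's QR solver.
normal_equations_fit <- function(X, y) {
  unname(drop(solve(t(X) %*% X) %*% t(X) %*% y))
}

# random full-rank synthetic regression problem on the 29-term design
random_problem <- function(n, noise_sd = 0.1) {
  V <- matrix(runif(n * 7, -1, 1), n, 7)
  X <- design_matrix(V)
  a_true <- rnorm(29)
  y <- drop(X %*% a_true) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, a_true = a_true)
}

# one-row patient record with readings near cohort centres
example_patient <- function(cm = 40) {
  data.frame(patient_id = "P0001", age = 60, kvp = 100, bsa = 1.8,
             hr = 72, co = 6.3, cm = cm, dtt = 3.1,
             stringsAsFactors = FALSE)
}
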