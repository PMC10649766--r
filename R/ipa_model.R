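#' Canonical labels of the 29 model terms
#'
#' Seven main effects A..G (age, tube voltage, BSA, HR, CO, CM, DTT),
#' the 21 pairwise interactions in lexicographic order (AxB, AxC, ...,
#' FxG), and the constant. Coefficient files whose labels disagree with
#' this order are rejected at load.
#'
#' @return Character vector of length 29.
#' @export
term_labels <- function() {
  main <- LETTERS[1:7]
  pairs <- utils::combn(7, 2)
  inter <- paste0(main[pairs[1, ]], "x", main[pairs[2, ]])
  c(main, inter, "Constant")
}

#' Validate a 29-coefficient vector
#'
#' @param a Numeric vector of the 29 coefficients in [term_labels()]
#'   order (names, if present, must match).
#' @return Named numeric vector of length 29.
#' @export
coefficient_set <- function(a) {
  labels <- term_labels()
  if (!is.numeric(a) || length(a) != length(labels)) {
    stop("a coefficient set must hold exactly ", length(labels),
         " numeric values, got ", length(a), call. = FALSE)
  }
  if (!all(is.finite(a))) stop("coefficients must be finite", call. = FALSE)
  if (!is.null(names(a)) && !identical(names(a), labels)) {
    stop("coefficient labels do not match the canonical term order",
         call. = FALSE)
  }
  stats::setNames(as.numeric(a), labels)
}

#' Expand normalized factors into the 29-term design row
#'
#' Given the seven normalized risk factors v1..v7, builds the row
#' (v1, ..., v7, v1*v2, v1*v3, ..., v6*v7, 1) whose dot product with a
#' coefficient set is the model prediction.
#'
#' @param v Numeric vector of 7 normalized factor values.
#' @return Named numeric vector of length 29; last entry is the
#'   constant 1.
#' @examples
#' expand_design(rep(0, 7))  # all zero except the trailing 1
#' @export
expand_design <- function(v) {
  if (!is.numeric(v) || length(v) != 7) {
    stop("expected 7 normalized factor values, got ", length(v),
         call. = FALSE)
  }
  if (!all(is.finite(v))) stop("factor values must be finite", call. = FALSE)
  pairs <- utils::combn(7, 2)
  row <- c(v, v[pairs[1, ]] * v[pairs[2, ]], 1)
  stats::setNames(row, term_labels())
}

#' Build the n x 29 design matrix for a cohort of normalized factors
#'
#' @param V An n x 7 matrix of normalized factors (columns in
#'   [factor_ids()] order).
#' @return An n x 29 matrix with columns labelled by [term_labels()].
#' @export
design_matrix <- function(V) {
  V <- as.matrix(V)
  if (ncol(V) != 7) {
    stop("normalized factor matrix must have 7 columns", call. = FALSE)
  }
  pairs <- utils::combn(7, 2)
  X <- cbind(V, V[, pairs[1, ], drop = FALSE] * V[, pairs[2, ], drop = FALSE],
             1)
  colnames(X) <- term_labels()
  X
}

#' Least-squares fit of the 29-term design
#'
#' Solves min ||X a - y||^2 for the coefficient vector via a QR
#' factorization (numerically equivalent to the normal-equations
#' solution (X'X)^-1 X'y for full-rank designs, but better
#' conditioned). A rank-deficient design is an error, not silently
#' resolved with a pseudo-inverse: the model's interpretation assumes a
#' unique coefficient vector.
#'
#' @param X n x 29 design matrix ([design_matrix()]).
#' @param y Vector of n normalized responses.
#' @return A list with `coefficients` (named, length 29) and
#'   `diagnostics`, a `fit_diagnostics` list holding `loss_phi` (the
#'   residual sum of squares on the normalized scale), `variance` (the
#'   coefficient of determination), `r` (correlation between observed
#'   and predicted responses), `n` and `rank`.
#' @export
ipa_fit <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  p <- length(term_labels())
  if (ncol(X) != p) stop("design must have ", p, " columns", call. = FALSE)
  if (nrow(X) != length(y)) {
    stop("design and response dimensions disagree", call. = FALSE)
  }
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("design and response must be finite", call. = FALSE)
  }
  n <- nrow(X)
  if (n < p) {
    stop("underdetermined system: ", n, " patients for ", p,
         " coefficients", call. = FALSE)
  }
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    dropped <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, p)]]
    stop("rank-deficient design (rank ", qr_x$rank, " < ", p,
         "); collinear term(s): ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  a <- qr.coef(qr_x, y)
  pred <- drop(X %*% a)
  resid <- y - pred
  loss_phi <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  diagnostics <- structure(list(
    loss_phi = loss_phi,
    variance = 1 - loss_phi / tss,
    r = stats::cor(y, pred),
    n = n,
    rank = qr_x$rank
  ), class = "fit_diagnostics")
  list(coefficients = coefficient_set(a), diagnostics = diagnostics)
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("fit diagnostics: n = %d, rank = %d\n", x$n, x$rank))
  cat(sprintf("  loss Phi (sum sq. resid, normalized scale): %.6g\n",
              x$loss_phi))
  cat(sprintf("  variance explained (R^2): %.4f   correlation R: %.4f\n",
              x$variance, x$r))
  invisible(x)
}

#' Bundle coefficients, scaling bounds and target into a model object
#'
#' A fitted model is only meaningful together with the bounds it was
#' scaled with, so the two are always carried (and serialized) as one
#' artifact.
#'
#' @param coefficients 29 coefficients ([coefficient_set()]).
#' @param bounds A `cta_bounds` table.
#' @param target_cta Raw CTA number targeted by dose planning
#'   (default 400).
#' @param diagnostics Optional `fit_diagnostics`.
#' @param metadata Optional named list (seed, n, provenance, ...).
#' @return An object of class `ipa_model`.
#' @export
ipa_model <- function(coefficients, bounds, target_cta = 400,
                      diagnostics = NULL, metadata = list()) {
  if (!is.numeric(target_cta) || length(target_cta) != 1 ||
      !is.finite(target_cta) || target_cta <= 0) {
    stop("`target_cta` must be a single positive number", call. = FALSE)
  }
  target_cta <- as.numeric(target_cta)
  structure(list(
    coefficients = coefficient_set(coefficients),
    bounds = cta_bounds(bounds),
    target_cta = target_cta,
    diagnostics = diagnostics,
    metadata = metadata
  ), class = "ipa_model")
}

#' @export
print.ipa_model <- function(x, ...) {
  cat("29-term semi-empirical CTA model (ipa_model)\n")
  cat(sprintf("  target CTA number: %g\n", x$target_cta))
  top <- sort(abs(x$coefficients[-29]), decreasing = TRUE)[1:3]
  cat("  largest effects:",
      paste(sprintf("%s (%+.3f)", names(top),
                    x$coefficients[names(top)]), collapse = ", "), "\n")
  if (!is.null(x$diagnostics)) print(x$diagnostics)
  invisible(x)
}

#' Fit the semi-empirical CTA model to a cohort
#'
#' Derives (or accepts) scaling bounds, normalizes the seven factors
#' and the observed response (CTA/400), expands the 29-term design and
#' fits it by least squares.
#'
#' @param cohort Patient data.frame with the seven factor columns and
#'   observed `cta_la`.
#' @param bounds Optional `cta_bounds`; derived from the cohort with
#'   [derive_bounds()] when `NULL`.
#' @param target_cta Dose-planning target stored with the model.
#' @param policy Out-of-range normalization policy (see
#'   [normalize_cohort()]).
#' @return A fitted `ipa_model`.
#' @examples
#' cohort <- simulate_cohort(table1_cohort_spec(n = 60, seed = 42))
#' fit <- fit_ipa(cohort)
#' fit$diagnostics$variance
#' @export
fit_ipa <- function(cohort, bounds = NULL, target_cta = 400,
                    policy = "warn") {
  cohort <- validate_cohort(cohort, require_response = TRUE)
  if (is.null(bounds)) bounds <- derive_bounds(cohort)
  bounds <- cta_bounds(bounds)
  V <- normalize_cohort(cohort, bounds, policy)
  y <- normalize_response(cohort$cta_la, bounds)
  fit <- ipa_fit(design_matrix(V), y)
  ipa_model(fit$coefficients, bounds, target_cta = target_cta,
            diagnostics = fit$diagnostics,
            metadata = list(n = nrow(cohort)))
}

#' Predict the normalized response from normalized factors
#'
#' @param v Either a vector of 7 normalized factors or an n x 7 matrix.
#' @param coefficients 29 coefficients ([coefficient_set()]).
#' @return Normalized predicted response(s).
#' @examples
#' predict_normalized(rep(0, 7), table3_model()$coefficients)
#' @export
predict_normalized <- function(v, coefficients) {
  a <- coefficient_set(coefficients)
  if (is.matrix(v) || is.data.frame(v)) {
    drop(design_matrix(as.matrix(v)) %*% a)
  } else {
    sum(expand_design(v) * a)
  }
}

#' Predict raw CTA numbers for patient records
#'
#' Composition of the full stage-one pipeline: normalize the factors,
#' evaluate the 29-term formula, and map the normalized prediction back
#' onto the raw CTA scale (denormalize, then multiply by 400).
#'
#' @param cohort Patient data.frame (response column not required).
#' @param model An `ipa_model`.
#' @param policy Out-of-range normalization policy.
#' @return Vector of predicted raw CTA numbers of the left artery.
#' @export
predict_cta <- function(cohort, model, policy = "warn") {
  stopifnot(inherits(model, "ipa_model"))
  V <- normalize_cohort(cohort, model$bounds, policy)
  z <- predict_normalized(V, model$coefficients)
  denormalize_response(z, model$bounds)
}

#' @export
predict.ipa_model <- function(object, newdata,
                              type = c("cta", "normalized"),
                              policy = "warn", ...) {
  type <- match.arg(type)
  if (type == "cta") return(predict_cta(newdata, object, policy))
  V <- normalize_cohort(newdata, object$bounds, policy)
  predict_normalized(V, object$coefficients)
}
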