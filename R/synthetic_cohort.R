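#' Body surface area from height and weight
#'
#' Mosteller estimate `sqrt(height * weight / 3600)` with height in cm
#' and weight in kg.
#'
#' @param height Height in cm, positive.
#' @param weight Weight in kg, positive.
#' @return BSA in m^2.
#' @examples
#' bsa_from_height_weight(170, 70)  # ~1.82 m^2
#' @export
bsa_from_height_weight <- function(height, weight) {
  if (!all(is.finite(height)) || !all(is.finite(weight)) ||
      any(height <= 0) || any(weight <= 0)) {
    stop("height and weight must be positive and finite", call. = FALSE)
  }
  sqrt(height * weight / 3600)
}

# truncated-normal draws by inverse-CDF; clamped to guard against
# floating rounding at the tails
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  if (p_hi - p_lo < 1e-10) {
    stop("infeasible truncation: the [", lo, ", ", hi,
         "] window carries almost no mass under Normal(", mean, ", ", sd,
         ")", call. = FALSE)
  }
  x <- stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Specify a synthetic patient cohort
#'
#' A cohort spec holds everything needed to simulate patients: per-factor
#' truncated-normal marginal parameters (independent by default), the
#' ground-truth 29-term coefficient set that generates responses, the
#' residual noise SD on the normalized response scale, and the scaling
#' bounds used to map normalized responses back to raw CTA numbers.
#'
#' @param n Number of patients.
#' @param factors Named list over [factor_ids()]; each entry a list
#'   with `mean`, `sd`, `min`, `max` in raw units and optionally
#'   `levels`, a vector of discrete settings the draw is snapped to
#'   (used for tube voltage, which clinically takes a small step set).
#' @param ground_truth 29 coefficients generating the true responses.
#' @param bounds `cta_bounds` used to normalize factors and to
#'   denormalize responses during generation.
#' @param residual_sd Gaussian noise SD added to the true normalized
#'   response (default 0.084, i.e. a residual sum of squares near
#'   3.18 at n = 450).
#' @param seed Default RNG seed used by [simulate_cohort()]; may be
#'   overridden there.
#' @return An object of class `cohort_spec`.
#' @seealso [table1_cohort_spec()], [table4_cohort_spec()] for the
#'   packaged derivation- and verification-cohort parameter sets.
#' @export
cohort_spec <- function(n, factors, ground_truth, bounds,
                        residual_sd = 0.084, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  ids <- factor_ids()
  if (!is.list(factors) || !setequal(names(factors), ids)) {
    stop("`factors` must be a named list over: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  for (id in ids) {
    f <- factors[[id]]
    need <- c("mean", "sd", "min", "max")
    if (!all(need %in% names(f))) {
      stop("factor '", id, "' must define mean, sd, min, max",
           call. = FALSE)
    }
    if (!all(vapply(f[need], function(v) is.numeric(v) && is.finite(v),
                    logical(1)))) {
      stop("factor '", id, "' has non-numeric marginal parameters",
           call. = FALSE)
    }
    if (f$sd <= 0) stop("factor '", id, "': sd must be > 0", call. = FALSE)
    if (!(f$min < f$mean && f$mean < f$max)) {
      stop("factor '", id, "': need min < mean < max", call. = FALSE)
    }
    if (!is.null(f$levels)) {
      if (any(f$levels < f$min | f$levels > f$max)) {
        stop("factor '", id, "': levels must lie within [min, max]",
             call. = FALSE)
      }
    }
  }
  if (!is.numeric(residual_sd) || residual_sd < 0) {
    stop("`residual_sd` must be >= 0", call. = FALSE)
  }
  structure(list(
    n = as.integer(n),
    factors = factors[ids],
    ground_truth = coefficient_set(ground_truth),
    bounds = cta_bounds(bounds),
    residual_sd = residual_sd,
    seed = seed
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("synthetic cohort spec: n = %d, residual_sd = %g\n",
              x$n, x$residual_sd))
  for (id in factor_ids()) {
    f <- x$factors[[id]]
    cat(sprintf("  %-4s mean %-6g sd %-5g range [%g, %g]%s\n", id,
                f$mean, f$sd, f$min, f$max,
                if (is.null(f$levels)) "" else
                  paste0(" levels {", paste(f$levels, collapse = ","), "}")))
  }
  invisible(x)
}

#' Draw the raw factor readings for a cohort
#'
#' Each factor is sampled independently from a normal distribution
#' truncated to its `[min, max]` window; factors with a `levels` set
#' (tube voltage) are snapped to the nearest level after the draw.
#'
#' @param spec A `cohort_spec`.
#' @param seed RNG seed; defaults to the spec's own. `NULL` leaves the
#'   RNG state untouched.
#' @return Patient data.frame with `patient_id` and the seven factor
#'   columns (no responses yet).
#' @export
sample_factors <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  draw_factors(spec, spec$n)
}

draw_factors <- function(spec, k) {
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(k)),
                    stringsAsFactors = FALSE)
  for (id in factor_ids()) {
    f <- spec$factors[[id]]
    x <- rtruncnorm(k, f$mean, f$sd, f$min, f$max)
    if (!is.null(f$levels)) {
      lv <- sort(f$levels)
      x <- vapply(x, function(xi) lv[which.min(abs(lv - xi))], numeric(1))
    }
    out[[id]] <- x
  }
  out
}

#' Attach simulated CTA responses to a cohort
#'
#' The true normalized response is the 29-term formula evaluated at the
#' record's normalized factors (using the spec's bounds); Gaussian noise
#' with SD `residual_sd` is added, and the observed raw CTA number is
#' recovered by denormalizing and multiplying by 400. Noise draws that
#' would produce a non-positive CTA number are resampled.
#'
#' @param records Patient data.frame from [sample_factors()].
#' @param spec The `cohort_spec` that generated it.
#' @param seed Optional RNG seed for the noise draws; `NULL` (default)
#'   continues the current RNG stream.
#' @return The records with a `cta_la` column appended.
#' @export
attach_responses <- function(records, spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  records <- validate_cohort(records, require_response = FALSE)
  if (!is.null(seed)) set.seed(seed)
  V <- normalize_cohort(records, spec$bounds, policy = "warn")
  z_true <- predict_normalized(V, spec$ground_truth)
  n <- length(z_true)
  noise <- stats::rnorm(n, 0, spec$residual_sd)
  cta <- denormalize_response(z_true + noise, spec$bounds)
  for (tries in seq_len(100)) {
    bad <- which(cta <= 0)
    if (length(bad) == 0) break
    noise[bad] <- stats::rnorm(length(bad), 0, spec$residual_sd)
    cta[bad] <- denormalize_response(z_true[bad] + noise[bad], spec$bounds)
  }
  if (any(cta <= 0)) {
    stop("could not generate positive CTA numbers; check the spec's ",
         "ground truth and bounds", call. = FALSE)
  }
  records$cta_la <- cta
  records
}

#' Simulate a complete synthetic cohort
#'
#' Draws factor readings and attaches responses under a single seeded
#' RNG stream: identical spec and seed give byte-identical cohorts.
#' Patients whose *true* normalized response falls outside [-1, +1]
#' are rejected and redrawn, so the simulated cohort respects the
#' response scale's empirical range the way an observed cohort does by
#' construction; independent marginals would otherwise occasionally
#' combine into physically implausible CTA numbers.
#'
#' @inheritParams sample_factors
#' @param responses Set `FALSE` to skip response generation (and the
#'   response-range rejection step).
#' @return Patient data.frame with factor columns and (unless
#'   `responses = FALSE`) observed `cta_la`.
#' @examples
#' cohort <- simulate_cohort(table1_cohort_spec(n = 100, seed = 7))
#' range(cohort$age)  # within [24, 90]
#' @export
simulate_cohort <- function(spec, seed = spec$seed, responses = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (!responses) return(draw_factors(spec, spec$n))
  accepted <- NULL
  for (tries in seq_len(100)) {
    k <- spec$n - if (is.null(accepted)) 0L else nrow(accepted)
    if (k == 0L) break
    cand <- draw_factors(spec, k)
    V <- suppressWarnings(normalize_cohort(cand, spec$bounds))
    z <- predict_normalized(V, spec$ground_truth)
    keep <- cand[z >= -1 & z <= 1, , drop = FALSE]
    accepted <- if (is.null(accepted)) keep else rbind(accepted, keep)
  }
  if (is.null(accepted) || nrow(accepted) < spec$n) {
    stop("rejection sampling failed: the ground-truth model maps almost ",
         "all factor draws outside the response scale", call. = FALSE)
  }
  accepted$patient_id <- sprintf("P%04d", seq_len(nrow(accepted)))
  rownames(accepted) <- NULL
  attach_responses(accepted, spec, seed = NULL)
}
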