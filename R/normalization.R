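#' Canonical risk-factor identifiers
#'
#' The seven risk factors of the semi-empirical CTA model, in the fixed
#' order used everywhere in the package: `age` (yr), `kvp` (CT tube
#' voltage, kVp), `bsa` (body surface area, m^2), `hr` (heart rate,
#' beats/min), `co` (cardiac output, L/min), `cm` (injected contrast
#' media, c.c.), `dtt` (delayed trigger timing, s).
#'
#' @return Character vector of length 7.
#' @export
factor_ids <- function() {
  c("age", "kvp", "bsa", "hr", "co", "cm", "dtt")
}

#' Identifier of the response scale
#'
#' The model response is the CTA number of the left artery divided by
#' 400 (the clinical target), then min-max normalized like the factors.
#'
#' @return The string `"cta_la_over_400"`.
#' @export
response_id <- function() "cta_la_over_400"

bounds_ids <- function() c(factor_ids(), response_id())

#' Bounds table for min-max normalization
#'
#' Validates and canonicalizes a table of per-factor scaling bounds: one
#' row per risk factor plus one for the response scale (CTA number of
#' LA / 400). Each reading x is mapped onto [-1, +1] by
#' \deqn{x^* = \frac{x - (x_{max}+x_{min})/2}{(x_{max}-x_{min})/2}}
#' so `min` maps to -1 and `max` to +1 exactly.
#'
#' @param bounds A data.frame with columns `factor`, `min`, `max`
#'   containing exactly the seven factors of [factor_ids()] plus
#'   [response_id()].
#' @return A data.frame of class `cta_bounds`, rows in canonical order.
#' @examples
#' derive_bounds(simulate_cohort(table1_cohort_spec(n = 50, seed = 1)))
#' @export
cta_bounds <- function(bounds) {
  if (!is.data.frame(bounds)) {
    stop("`bounds` must be a data.frame with columns factor, min, max",
         call. = FALSE)
  }
  need <- c("factor", "min", "max")
  missing_cols <- setdiff(need, names(bounds))
  if (length(missing_cols) > 0) {
    stop("bounds table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- bounds_ids()
  if (!setequal(bounds$factor, ids) || nrow(bounds) != length(ids)) {
    stop("bounds table must contain exactly one row for each of: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  bounds <- bounds[match(ids, bounds$factor), need, drop = FALSE]
  rownames(bounds) <- NULL
  if (!all(is.finite(bounds$min)) || !all(is.finite(bounds$max))) {
    stop("bounds must be finite", call. = FALSE)
  }
  bad <- bounds$max <= bounds$min
  if (any(bad)) {
    stop("degenerate bounds (max <= min) for factor(s): ",
         paste(bounds$factor[bad], collapse = ", "), call. = FALSE)
  }
  class(bounds) <- c("cta_bounds", "data.frame")
  bounds
}

check_bounds_pair <- function(x_min, x_max) {
  if (!all(is.finite(x_min)) || !all(is.finite(x_max))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(x_max <= x_min)) {
    stop("degenerate bounds: x_max must be strictly greater than x_min",
         call. = FALSE)
  }
}

#' Min-max normalization of a raw reading onto [-1, +1]
#'
#' @param x Raw reading(s), finite numeric.
#' @param x_min,x_max Minimal and maximal readings of the factor
#'   (`x_max > x_min` strictly).
#' @return `(x - (x_max + x_min)/2) / ((x_max - x_min)/2)`; lies in
#'   [-1, +1] whenever `x` is within the bounds.
#' @examples
#' normalize_reading(60, 24, 90)  # +0.0909
#' normalize_reading(33, 24, 90)  # -0.7273
#' @seealso [denormalize_reading()] for the exact inverse.
#' @export
normalize_reading <- function(x, x_min, x_max) {
  check_bounds_pair(x_min, x_max)
  if (!all(is.finite(x))) stop("readings must be finite", call. = FALSE)
  (x - (x_max + x_min) / 2) / ((x_max - x_min) / 2)
}

#' Inverse of the min-max normalization
#'
#' @param x_star Normalized value(s).
#' @inheritParams normalize_reading
#' @return `x_star * (x_max - x_min)/2 + (x_max + x_min)/2`, the exact
#'   inverse of [normalize_reading()].
#' @export
denormalize_reading <- function(x_star, x_min, x_max) {
  check_bounds_pair(x_min, x_max)
  if (!all(is.finite(x_star))) stop("values must be finite", call. = FALSE)
  x_star * (x_max - x_min) / 2 + (x_max + x_min) / 2
}

bounds_row <- function(bounds, id) {
  i <- match(id, bounds$factor)
  if (is.na(i)) stop("no bounds for factor '", id, "'", call. = FALSE)
  list(min = bounds$min[i], max = bounds$max[i])
}

#' Derive scaling bounds from an observed cohort
#'
#' Computes the per-factor minimum and maximum over a cohort, and the
#' response bounds over the observed CTA numbers divided by 400. These
#' are the bounds under which the cohort itself normalizes exactly onto
#' [-1, +1].
#'
#' @param cohort A patient data.frame with the seven factor columns and
#'   an observed `cta_la` column (see [read_patient_csv()]).
#' @return A `cta_bounds` table.
#' @export
derive_bounds <- function(cohort) {
  cohort <- validate_cohort(cohort, require_response = TRUE)
  ids <- factor_ids()
  lo <- numeric(length(ids) + 1)
  hi <- numeric(length(ids) + 1)
  for (k in seq_along(ids)) {
    v <- cohort[[ids[k]]]
    lo[k] <- min(v)
    hi[k] <- max(v)
    if (hi[k] <= lo[k]) {
      stop("degenerate bounds: factor '", ids[k],
           "' is constant across the cohort", call. = FALSE)
    }
  }
  y <- cohort$cta_la / 400
  lo[length(lo)] <- min(y)
  hi[length(hi)] <- max(y)
  if (hi[length(hi)] <= lo[length(lo)]) {
    stop("degenerate bounds: observed CTA number is constant across the cohort",
         call. = FALSE)
  }
  cta_bounds(data.frame(factor = bounds_ids(), min = lo, max = hi,
                        stringsAsFactors = FALSE))
}

#' Normalize the factor columns of a cohort
#'
#' Maps each of the seven factor columns through [normalize_reading()]
#' with the matching bounds. New patients may fall outside the bounds
#' the model was trained with; by default such readings are extrapolated
#' beyond +/-1 with a warning (`policy = "warn"`), while
#' `policy = "strict"` rejects them.
#'
#' @param cohort Patient data.frame (response column not required).
#' @param bounds A `cta_bounds` table.
#' @param policy Out-of-range policy, `"warn"` (default) or `"strict"`.
#' @return An n x 7 numeric matrix of normalized factors with columns
#'   in [factor_ids()] order and attribute `n_out_of_range`, the count
#'   of readings outside their bounds.
#' @export
normalize_cohort <- function(cohort, bounds, policy = c("warn", "strict")) {
  policy <- match.arg(policy)
  cohort <- validate_cohort(cohort, require_response = FALSE)
  bounds <- cta_bounds(bounds)
  ids <- factor_ids()
  out <- matrix(NA_real_, nrow(cohort), length(ids),
                dimnames = list(NULL, ids))
  n_oob <- 0L
  for (id in ids) {
    b <- bounds_row(bounds, id)
    x <- cohort[[id]]
    oob <- x < b$min | x > b$max
    n_oob <- n_oob + sum(oob)
    if (any(oob) && policy == "strict") {
      stop(sum(oob), " reading(s) of factor '", id,
           "' outside bounds [", b$min, ", ", b$max, "]", call. = FALSE)
    }
    out[, id] <- normalize_reading(x, b$min, b$max)
  }
  if (n_oob > 0 && policy == "warn") {
    warning(n_oob, " reading(s) outside scaling bounds; normalized values ",
            "extrapolated beyond [-1, +1]", call. = FALSE)
  }
  attr(out, "n_out_of_range") <- n_oob
  out
}

#' Normalize observed CTA numbers onto the model response scale
#'
#' Divides raw CTA numbers by 400 and applies the response row of the
#' bounds table.
#'
#' @param cta_la Raw CTA numbers of the left artery.
#' @param bounds A `cta_bounds` table.
#' @return Normalized responses (may exceed +/-1 for readings outside
#'   the bounds; the response scale is never strict).
#' @export
normalize_response <- function(cta_la, bounds) {
  bounds <- cta_bounds(bounds)
  b <- bounds_row(bounds, response_id())
  normalize_reading(cta_la / 400, b$min, b$max)
}

#' Map normalized predictions back to raw CTA numbers
#'
#' @param z Normalized predicted response(s).
#' @param bounds A `cta_bounds` table.
#' @return Raw CTA numbers: `denormalize_reading(z) * 400`.
#' @export
denormalize_response <- function(z, bounds) {
  bounds <- cta_bounds(bounds)
  b <- bounds_row(bounds, response_id())
  denormalize_reading(z, b$min, b$max) * 400
}
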