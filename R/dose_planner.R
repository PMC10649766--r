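#' Two-point dose interpolation
#'
#' Solves the linear interpolation
#' `(cm - cm_min)/(cm_max - cm_min) = (target - v8_min)/(v8_max - v8_min)`
#' for the contrast-media volume `cm` whose predicted CTA number equals
#' the target. Exact, not approximate: the 29-term model is affine in
#' the contrast-media factor once the other six factors are fixed, so
#' the straight line through the two extreme predictions *is* the
#' model's dose response.
#'
#' @param cm_min,cm_max Dose extremes in c.c. (`cm_max > cm_min`); for
#'   a fitted model these are the training cohort's extremes, i.e. the
#'   doses mapping to normalized -1 and +1.
#' @param v8_min,v8_max Predicted raw CTA numbers at `cm_min` and
#'   `cm_max`; must differ.
#' @param target Raw CTA number to attain (default 400).
#' @return Recommended dose in c.c. (unclipped; may fall outside
#'   `[cm_min, cm_max]` when the target is not between the two
#'   predictions).
#' @examples
#' interpolate_dose(17, 75, 252, 552, 400)  # 45.6 c.c.
#' @export
interpolate_dose <- function(cm_min, cm_max, v8_min, v8_max, target = 400) {
  if (!all(is.finite(c(cm_min, cm_max, v8_min, v8_max, target)))) {
    stop("all dose-interpolation inputs must be finite", call. = FALSE)
  }
  if (any(cm_max <= cm_min)) {
    stop("`cm_max` must be strictly greater than `cm_min`", call. = FALSE)
  }
  if (any(v8_max == v8_min)) {
    stop("zero dose sensitivity: predicted CTA number does not depend ",
         "on the contrast-media volume for this patient", call. = FALSE)
  }
  cm_min + (target - v8_min) / (v8_max - v8_min) * (cm_max - cm_min)
}

#' Plan the contrast-media dose for one patient
#'
#' Stage two of the pipeline: with the patient's six non-dose factors
#' fixed, evaluates the model at the normalized dose extremes (+1 and
#' -1), interpolates the dose at which the predicted CTA number equals
#' the target, and applies the clipping policy.
#'
#' @param record One-row patient data.frame; the `cm` column is not
#'   required (it is the unknown being planned).
#' @param model A fitted or packaged `ipa_model`.
#' @param target Raw CTA target; defaults to the model's `target_cta`.
#' @param clip When `TRUE` (default), a recommended dose falling
#'   outside the model's dose bounds is clamped into them and flagged;
#'   the model's linearity in dose is only trusted inside the range it
#'   was trained on. Set `FALSE` to allow extrapolated doses.
#' @param policy Out-of-range normalization policy for the six fixed
#'   factors.
#' @return One-row data.frame: `patient_id`, `cm_min`, `cm_max`,
#'   `v8_at_cm_min`, `v8_at_cm_max`, `target_cta`, `cm_expect`,
#'   `achievable` (is the target between the two extreme predictions?),
#'   `clipped`.
#' @examples
#' pat <- simulate_cohort(table4_cohort_spec(n = 1, seed = 3))
#' plan_dose(pat, table3_model())
#' @export
plan_dose <- function(record, model, target = NULL, clip = TRUE,
                      policy = "warn") {
  stopifnot(inherits(model, "ipa_model"))
  if (is.null(target)) target <- model$target_cta
  record <- validate_cohort(record, require_response = FALSE,
                            require_cm = FALSE)
  if (nrow(record) != 1) {
    stop("`record` must be a single patient; use plan_cohort() for a batch",
         call. = FALSE)
  }
  cm_b <- bounds_row(model$bounds, "cm")
  ids <- factor_ids()
  v <- numeric(7)
  names(v) <- ids
  n_oob <- 0L
  for (id in setdiff(ids, "cm")) {
    b <- bounds_row(model$bounds, id)
    x <- record[[id]]
    oob <- x < b$min || x > b$max
    n_oob <- n_oob + oob
    if (oob && policy == "strict") {
      stop("reading of factor '", id, "' outside bounds [", b$min, ", ",
           b$max, "]", call. = FALSE)
    }
    v[id] <- normalize_reading(x, b$min, b$max)
  }
  if (n_oob > 0 && policy == "warn") {
    warning(n_oob, " reading(s) outside scaling bounds; normalized values ",
            "extrapolated beyond [-1, +1]", call. = FALSE)
  }
  v_hi <- v; v_hi["cm"] <- 1
  v_lo <- v; v_lo["cm"] <- -1
  v8_max <- denormalize_response(predict_normalized(v_hi, model$coefficients),
                                 model$bounds)
  v8_min <- denormalize_response(predict_normalized(v_lo, model$coefficients),
                                 model$bounds)
  if (abs(v8_max - v8_min) < 1e-9) {
    stop("zero dose sensitivity: predicted CTA number does not depend ",
         "on the contrast-media volume for this patient", call. = FALSE)
  }
  cm_expect <- interpolate_dose(cm_b$min, cm_b$max, v8_min, v8_max, target)
  achievable <- target >= min(v8_min, v8_max) - 1e-9 &&
    target <= max(v8_min, v8_max) + 1e-9
  clipped <- FALSE
  if (clip && (cm_expect < cm_b$min || cm_expect > cm_b$max)) {
    cm_expect <- min(max(cm_expect, cm_b$min), cm_b$max)
    clipped <- TRUE
  }
  pid <- if (!is.null(record$patient_id)) as.character(record$patient_id)
         else NA_character_
  data.frame(patient_id = pid, cm_min = cm_b$min, cm_max = cm_b$max,
             v8_at_cm_min = v8_min, v8_at_cm_max = v8_max,
             target_cta = target, cm_expect = cm_expect,
             achievable = achievable, clipped = clipped,
             stringsAsFactors = FALSE)
}

#' Plan contrast-media doses for a whole cohort
#'
#' Applies [plan_dose()] to every patient. Per-patient failures (e.g.
#' zero dose sensitivity) are collected into the `error` column rather
#' than aborting the batch; a summary of the planned dose range and the
#' counts of clipped and unachievable plans is emitted as a message.
#'
#' @inheritParams plan_dose
#' @param cohort Patient data.frame, one row per patient.
#' @return Data.frame with one row per patient: the [plan_dose()]
#'   columns plus `error` (`NA` for successful plans).
#' @export
plan_cohort <- function(cohort, model, target = NULL, clip = TRUE,
                        policy = "warn") {
  stopifnot(inherits(model, "ipa_model"))
  if (is.null(target)) target <- model$target_cta
  cohort <- validate_cohort(cohort, require_response = FALSE,
                            require_cm = FALSE)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  plans <- lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, , drop = FALSE]
    tryCatch({
      p <- plan_dose(row, model, target = target, clip = clip,
                     policy = policy)
      p$error <- NA_character_
      p
    }, error = function(e) {
      data.frame(patient_id = if (!is.null(row$patient_id))
                   as.character(row$patient_id) else NA_character_,
                 cm_min = NA_real_, cm_max = NA_real_,
                 v8_at_cm_min = NA_real_, v8_at_cm_max = NA_real_,
                 target_cta = target, cm_expect = NA_real_,
                 achievable = NA, clipped = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, plans)
  rownames(out) <- NULL
  ok <- is.na(out$error)
  message(sprintf(
    "planned %d/%d patients; cm_expect range %.1f-%.1f c.c.; %d clipped, %d unachievable",
    sum(ok), nrow(out),
    if (any(ok)) min(out$cm_expect[ok]) else NA_real_,
    if (any(ok)) max(out$cm_expect[ok]) else NA_real_,
    sum(out$clipped[ok]), sum(!out$achievable[ok])))
  out
}
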