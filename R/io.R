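#' Validate a patient table
#'
#' Checks the column schema and per-row values of a patient cohort:
#' the seven factor columns must be numeric, finite and strictly
#' positive; `cta_la`, when present, strictly positive. Offending rows
#' are reported by number.
#'
#' @param cohort Data.frame to validate.
#' @param require_response Require the observed `cta_la` column.
#' @param require_cm Require the `cm` column (dose planning treats the
#'   dose as unknown, so plans may omit it).
#' @return The validated data.frame (with a `patient_id` column added
#'   when absent).
#' @export
validate_cohort <- function(cohort, require_response = FALSE,
                            require_cm = TRUE) {
  if (!is.data.frame(cohort)) {
    stop("a cohort must be a data.frame", call. = FALSE)
  }
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  need <- factor_ids()
  if (!require_cm) need <- setdiff(need, "cm")
  missing_cols <- setdiff(need, names(cohort))
  if (require_response && !"cta_la" %in% names(cohort)) {
    missing_cols <- c(missing_cols, "cta_la")
  }
  if (length(missing_cols) > 0) {
    stop("patient table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check <- intersect(c(factor_ids(), "cta_la"), names(cohort))
  for (col in check) {
    x <- cohort[[col]]
    if (!is.numeric(x)) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
    bad <- which(!is.finite(x) | x <= 0)
    if (length(bad) > 0) {
      stop("column '", col, "' has non-finite or non-positive value(s) ",
           "in row(s): ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(cohort$patient_id)) {
    cohort$patient_id <- sprintf("P%04d", seq_len(nrow(cohort)))
  }
  cohort
}

#' Read a patient table from CSV
#'
#' Expects a header with the seven factor columns (`age, kvp, bsa, hr,
#' co, cm, dtt`); `patient_id` and `cta_la` are optional. Non-numeric
#' cells and invalid readings are reported with their row numbers.
#'
#' @param path CSV file path.
#' @param require_response Require the `cta_la` column (e.g. before
#'   fitting or verification).
#' @return Validated patient data.frame.
#' @export
read_patient_csv <- function(path, require_response = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- factor_ids()
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("patient CSV '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check <- intersect(c(need, "cta_la"), names(raw))
  for (col in check) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "', row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- x
  }
  validate_cohort(raw, require_response = require_response)
}

#' Write a patient table to CSV
#'
#' @param cohort Patient data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a model to JSON
#'
#' The artifact bundles the 29 coefficients with their term labels, the
#' scaling bounds, the dose-planning target, and optional diagnostics
#' and provenance metadata, so a model can never be applied with
#' mismatched scaling. Floats are written with full round-trip
#' precision.
#'
#' @param model An `ipa_model`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ipa_model"))
  obj <- list(
    term_labels = term_labels(),
    coefficients = unname(model$coefficients),
    bounds = list(factor = model$bounds$factor,
                  min = model$bounds$min,
                  max = model$bounds$max),
    target_cta = model$target_cta,
    diagnostics = if (is.null(model$diagnostics)) NULL else
      unclass(model$diagnostics),
    metadata = model$metadata
  )
  # I(17) = 17 *significant* digits, enough for exact double round trips
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a model artifact from JSON
#'
#' Validates the term-label order against the canonical 29-term order
#' and the bounds against the canonical factor set; files that disagree
#' are rejected as incompatible rather than silently reordered.
#'
#' @param path JSON path written by [write_model()] (or the packaged
#'   fixture, see [table3_model()]).
#' @return An `ipa_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse model JSON '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  for (field in c("term_labels", "coefficients", "bounds", "target_cta")) {
    if (is.null(obj[[field]])) {
      stop("model file is missing field '", field, "'", call. = FALSE)
    }
  }
  if (!identical(as.character(obj$term_labels), term_labels())) {
    stop("incompatible model: term labels do not match the canonical ",
         "29-term order", call. = FALSE)
  }
  if (length(obj$coefficients) != 29) {
    stop("incompatible model: expected 29 coefficients, found ",
         length(obj$coefficients), call. = FALSE)
  }
  bounds <- cta_bounds(data.frame(factor = obj$bounds$factor,
                                  min = obj$bounds$min,
                                  max = obj$bounds$max,
                                  stringsAsFactors = FALSE))
  diagnostics <- NULL
  if (!is.null(obj$diagnostics) && length(obj$diagnostics) > 0) {
    diagnostics <- structure(obj$diagnostics, class = "fit_diagnostics")
  }
  ipa_model(as.numeric(obj$coefficients), bounds,
            target_cta = obj$target_cta, diagnostics = diagnostics,
            metadata = if (is.null(obj$metadata)) list() else obj$metadata)
}

#' The packaged 29-coefficient reference model
#'
#' Loads the model artifact shipped with the package: the published
#' 29-term coefficient set for the head-and-neck CTA formula together
#' with the derivation cohort's scaling bounds (age 24-90 yr, tube
#' voltage 70-140 kVp, BSA 1.27-2.70 m^2, HR 45-139 /min, CO
#' 4.18-11.11 L/min, CM 17-75 c.c., DTT 2.00-5.13 s, response scale
#' 0.61-2.17) and the clinical target of 400.
#'
#' @return An `ipa_model`.
#' @examples
#' m <- table3_model()
#' unname(m$coefficients["Constant"])  # -0.419399
#' @export
table3_model <- function() {
  read_model(system.file("extdata", "table3_model.json",
                         package = "ctadose", mustWork = TRUE))
}

parse_spec_yaml <- function(path, n = NULL, seed = NULL,
                            residual_sd = NULL) {
  cfg <- yaml::read_yaml(path)
  for (field in c("n", "factors", "scaling")) {
    if (is.null(cfg[[field]])) {
      stop("cohort spec '", path, "' is missing field '", field, "'",
           call. = FALSE)
    }
  }
  sc <- cfg$scaling
  bounds <- cta_bounds(data.frame(
    factor = bounds_ids(),
    min = vapply(bounds_ids(), function(id) as.numeric(sc[[id]]$min),
                 numeric(1)),
    max = vapply(bounds_ids(), function(id) as.numeric(sc[[id]]$max),
                 numeric(1)),
    stringsAsFactors = FALSE))
  gt <- cfg$ground_truth
  if (is.null(gt) || identical(gt, "table3")) {
    gt <- table3_model()$coefficients
  } else {
    gt <- as.numeric(gt)
  }
  cohort_spec(
    n = if (is.null(n)) cfg$n else n,
    factors = cfg$factors,
    ground_truth = gt,
    bounds = bounds,
    residual_sd = if (!is.null(residual_sd)) residual_sd
                  else if (!is.null(cfg$residual_sd)) cfg$residual_sd
                  else 0.084,
    seed = seed
  )
}

#' Read a cohort spec from a YAML config
#'
#' The config carries `n`, per-factor marginal parameters under
#' `factors`, the scaling bounds under `scaling`, and optionally
#' `residual_sd` and an explicit `ground_truth` coefficient list
#' (`ground_truth: table3` uses the packaged reference coefficients).
#'
#' @param path YAML config path.
#' @param n,seed,residual_sd Optional overrides.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path, n = NULL, seed = NULL,
                             residual_sd = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parse_spec_yaml(path, n = n, seed = seed, residual_sd = residual_sd)
}

#' Packaged derivation-cohort spec (450-patient marginals)
#'
#' Marginal parameters of the derivation cohort: per-factor mean, SD
#' and range (e.g. age 56 +/- 13.3 yr over 24-90; contrast media
#' 36.7 +/- 11.5 c.c. over 17-75), with tube voltage snapped to the
#' clinical step set \{70, 80, 100, 120, 140\} kVp. Responses are
#' generated from the packaged reference coefficients with residual SD
#' 0.084 on the normalized scale.
#'
#' @param n Cohort size (default 450).
#' @param seed Default simulation seed.
#' @param residual_sd Override the residual noise SD.
#' @return A `cohort_spec`.
#' @export
table1_cohort_spec <- function(n = 450, seed = NULL, residual_sd = NULL) {
  parse_spec_yaml(system.file("extdata", "table1_cohort.yaml",
                              package = "ctadose", mustWork = TRUE),
                  n = n, seed = seed, residual_sd = residual_sd)
}

#' Packaged verification-cohort spec (112-patient marginals)
#'
#' Marginal parameters of the verification cohort (age 55 +/- 13.9 yr
#' over 31-88, tube voltage 100/120 kVp, contrast media 54.4 +/- 8.9
#' c.c. over 32-68, ...). Scaling bounds are the derivation cohort's,
#' since verification patients are evaluated under the trained model's
#' scaling.
#'
#' @param n Cohort size (default 112).
#' @inheritParams table1_cohort_spec
#' @return A `cohort_spec`.
#' @export
table4_cohort_spec <- function(n = 112, seed = NULL, residual_sd = NULL) {
  parse_spec_yaml(system.file("extdata", "table4_cohort.yaml",
                              package = "ctadose", mustWork = TRUE),
                  n = n, seed = seed, residual_sd = residual_sd)
}

#' Write an agreement summary to CSV and/or JSON
#'
#' @param agreement A `cta_agreement` from [summarize_agreement()].
#' @param csv_path Optional path for the per-patient CSV
#'   (`patient_id, actual, predicted, at_percent`).
#' @param json_path Optional path for the JSON summary
#'   (`at_avg`, `at_sd`, `bins`).
#' @return Invisibly, the paths written.
#' @export
write_agreement <- function(agreement, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(agreement, "cta_agreement"))
  if (!is.null(csv_path)) {
    utils::write.csv(agreement$per_patient, csv_path, row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(n = nrow(agreement$per_patient),
                              at_avg = agreement$at_avg,
                              at_sd = agreement$at_sd,
                              bins = agreement$histogram),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(csv = csv_path, json = json_path))
}
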