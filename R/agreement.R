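#' Per-patient agreement statistic
#'
#' Agreement (AT) between an actual and a predicted CTA number: the
#' absolute difference divided by the actual value. Lower AT means
#' closer coincidence of prediction and observation.
#'
#' @param actual Observed raw CTA number(s); strictly positive.
#' @param predicted Predicted raw CTA number(s), same length.
#' @return AT as a fraction (multiply by 100 for percent).
#' @examples
#' at_statistic(400, 414)  # 0.035, i.e. 3.5%
#' @export
at_statistic <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have the same length", call. = FALSE)
  }
  if (!all(is.finite(actual)) || !all(is.finite(predicted))) {
    stop("CTA numbers must be finite", call. = FALSE)
  }
  if (any(actual <= 0)) {
    stop("actual CTA numbers must be strictly positive", call. = FALSE)
  }
  abs(actual - predicted) / actual
}

#' Cohort agreement summary
#'
#' Computes per-patient ATs in percent, their mean and sample standard
#' deviation (n - 1 denominator), and a binned histogram (2%-wide bins
#' anchored at 0 by default, lower edge inclusive).
#'
#' @param actual,predicted Paired raw CTA numbers, all actuals > 0.
#' @param patient_id Optional labels; defaults to `"P1"`, `"P2"`, ...
#' @param bin_width Histogram bin width in percent (default 2).
#' @return An object of class `cta_agreement`: a list with
#'   `per_patient` (data.frame of `patient_id`, `actual`, `predicted`,
#'   `at_percent`), `at_avg`, `at_sd` (both percent) and `histogram`
#'   (data.frame of `bin_lo`, `bin_hi`, `count`; counts sum to n).
#' @examples
#' summarize_agreement(c(400, 500), c(392, 480))
#' @export
summarize_agreement <- function(actual, predicted, patient_id = NULL,
                                bin_width = 2) {
  if (length(actual) == 0) stop("empty cohort", call. = FALSE)
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be positive", call. = FALSE)
  }
  at_pct <- 100 * at_statistic(actual, predicted)
  if (is.null(patient_id)) patient_id <- paste0("P", seq_along(at_pct))
  n_bins <- max(1L, ceiling(max(at_pct) / bin_width + 1e-12))
  breaks <- seq(0, by = bin_width, length.out = n_bins + 1L)
  # lower-inclusive bins [0, w), [w, 2w), ...; top edge closed so the
  # maximum AT is never dropped
  idx <- pmin(floor(at_pct / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(
    per_patient = data.frame(patient_id = patient_id, actual = actual,
                             predicted = predicted, at_percent = at_pct,
                             stringsAsFactors = FALSE),
    at_avg = mean(at_pct),
    at_sd = if (length(at_pct) > 1) stats::sd(at_pct) else 0,
    histogram = data.frame(bin_lo = breaks[-length(breaks)],
                           bin_hi = breaks[-1], count = counts)
  ), class = "cta_agreement")
}

#' @export
print.cta_agreement <- function(x, ...) {
  n <- nrow(x$per_patient)
  cat(sprintf("agreement over %d patients: AT_avg = %.2f%%, SD = %.2f%%\n",
              n, x$at_avg, x$at_sd))
  below <- sum(x$per_patient$at_percent < 2)
  cat(sprintf("  %d of %d ATs below 2%%\n", below, n))
  invisible(x)
}
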