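#' Mean squared difference between two baseline series
#'
#' The evaluation error: `sum((candidate_k - reference_k)^2) / n`.  Used both
#' for `error1` (raw extracted component vs the reference method's baseline)
#' and `error2` (adjusted baseline vs the same reference).  Set `rms = TRUE`
#' for the root form; the mean-square form is the default reading.
#'
#' @param candidate,reference Equal-length [ecg_signal()]s or numeric
#'   vectors.
#' @param rms Return the root mean square instead of the mean square.
#' @return A nonnegative scalar.
#' @export
baseline_error <- function(candidate, reference, rms = FALSE) {
  x <- if (inherits(candidate, "ecg_signal")) candidate$samples
       else as.numeric(candidate)
  y <- if (inherits(reference, "ecg_signal")) reference$samples
       else as.numeric(reference)
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch (%d vs %d)", length(x), length(y)),
         call. = FALSE)
  }
  if (length(x) < 1L) stop("empty input", call. = FALSE)
  mse <- sum((x - y)^2) / length(x)
  if (rms) sqrt(mse) else mse
}

#' Relative error reduction achieved by the adjustment
#'
#' `(error1 - error2) / error1`: the fraction by which aligning and rescaling
#' the extracted component reduced its disagreement with the reference
#' baseline.  1 means the adjusted baseline matches the reference exactly,
#' 0 means no improvement.
#'
#' @param error1 Error of the unadjusted component (> 0).
#' @param error2 Error of the adjusted baseline (>= 0).
#' @return A scalar (at most 1; negative would mean the adjustment hurt,
#'   which the shift search rules out when both errors target the same
#'   reference).
#' @export
error_reduction <- function(error1, error2) {
  if (!is.finite(error1) || error1 <= 0) {
    stop("`error1` must be positive; the reduction is undefined otherwise",
         call. = FALSE)
  }
  (error1 - error2) / error1
}

#' Bundle the two errors of one record into a report
#'
#' @param error1,error2 See [error_reduction()].
#' @param n_samples Number of samples the errors were computed over.
#' @return An `error_report`: list with `error1`, `error2`, `percentage`
#'   (the reduction as a fraction) and `n_samples`.
#' @export
error_report <- function(error1, error2, n_samples = NA_integer_) {
  structure(list(error1 = error1, error2 = error2,
                 percentage = error_reduction(error1, error2),
                 n_samples = as.integer(n_samples)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report: error1=%.4g error2=%.4g reduction=%.2f%%>\n",
              x$error1, x$error2, 100 * x$percentage))
  invisible(x)
}

#' Average error reduction over a set of records
#'
#' Arithmetic mean of the per-record reductions, reported as a fraction
#' (multiply by 100 for percent).
#'
#' @param reports Non-empty list of [error_report()] objects.
#' @return The mean reduction.
#' @export
average_error_reduction <- function(reports) {
  if (length(reports) == 0) stop("empty report list", call. = FALSE)
  mean(vapply(reports, function(r) {
    stopifnot(inherits(r, "error_report"))
    r$percentage
  }, numeric(1)))
}

#' Serialize error reports as JSON lines
#'
#' One JSON object per line per report, with fields `error1`, `error2`,
#' `percentage`, `n_samples`.
#'
#' @param reports List of [error_report()] objects.
#' @param path File to write (or `""` for stdout).
#' @return `path`, invisibly.
#' @export
write_error_reports <- function(reports, path) {
  lines <- vapply(reports, function(r) {
    jsonlite::toJSON(list(error1 = r$error1, error2 = r$error2,
                          percentage = r$percentage,
                          n_samples = r$n_samples),
                     auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
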