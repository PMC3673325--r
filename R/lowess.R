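#' Robust locally weighted regression configuration
#'
#' @param span Window size in samples (the number of nearest samples entering
#'   each local fit); default 1500, i.e. 3 s at 500 Hz.
#' @param degree Local polynomial degree, default 1.  Must satisfy
#'   `span >= degree + 2`.
#' @param robust_iters Bisquare robustness iterations, default 2.
#' @return A `lowess_config` object.
#' @export
lowess_config <- function(span = 1500L, degree = 1L, robust_iters = 2L) {
  span <- as.integer(span); degree <- as.integer(degree)
  robust_iters <- as.integer(robust_iters)
  if (is.na(degree) || degree < 0L) stop("`degree` must be >= 0",
                                         call. = FALSE)
  if (is.na(span) || span < degree + 2L) {
    stop("`span` must be at least degree + 2", call. = FALSE)
  }
  if (is.na(robust_iters) || robust_iters < 0L) {
    stop("`robust_iters` must be >= 0", call. = FALSE)
  }
  structure(list(span = span, degree = degree, robust_iters = robust_iters),
            class = "lowess_config")
}

#' Robust locally weighted regression baseline (reference method)
#'
#' The comparator baseline estimator: at every sample a degree-`degree`
#' polynomial is fitted by weighted least squares over the `span` nearest
#' samples with tricube distance weights; `robust_iters` rounds of bisquare
#' reweighting (residuals scaled by six times their median absolute value)
#' then downweight outliers such as QRS complexes.  Interior windows are
#' symmetric; at the record edges the window slides to stay in bounds, so no
#' data is fabricated.  The fitted trend has the same length as the input.
#'
#' @param signal An [ecg_signal()] at least `span` samples long.
#' @param cfg A [lowess_config()].
#' @return The fitted baseline as an [ecg_signal()].
#' @export
lowess_baseline <- function(signal, cfg = lowess_config()) {
  signal <- as_signal(signal)
  stopifnot(inherits(cfg, "lowess_config"))
  n <- length(signal$samples)
  if (n < cfg$span) {
    stop(sprintf("signal (%d samples) shorter than span (%d)", n, cfg$span),
         call. = FALSE)
  }
  fit <- .lowess_cpp(signal$samples, cfg$span, cfg$degree, cfg$robust_iters)
  ecg_signal(fit, signal$fs)
}

#' Baseline removal by the locally weighted regression reference method
#'
#' @param signal An [ecg_signal()].
#' @param cfg A [lowess_config()].
#' @return List with `clean` (`signal - baseline`, exact) and `baseline`.
#' @export
remove_baseline_reference <- function(signal, cfg = lowess_config()) {
  signal <- as_signal(signal)
  baseline <- lowess_baseline(signal, cfg)
  list(clean = ecg_signal(signal$samples - baseline$samples, signal$fs),
       baseline = baseline)
}
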