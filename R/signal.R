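#' Uniformly sampled single-channel signal
#'
#' The universal currency of the package: a numeric vector of samples together
#' with its sampling rate in Hz.  All filtering, embedding and evaluation
#' functions consume and produce `ecg_signal` objects.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units). Must be
#'   finite and non-empty.
#' @param fs Sampling rate in Hz (a single positive number). The sampling
#'   interval is `T = 1/fs` seconds.
#' @return An object of class `ecg_signal` with fields `samples` and `fs`.
#' @examples
#' s <- ecg_signal(sin(2 * pi * 1 * (0:999) / 500), fs = 500)
#' s
#' @export
ecg_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("signal must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("signal contains non-finite samples", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(list(samples = samples, fs = as.numeric(fs)),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' Coerce to an `ecg_signal`
#'
#' @param x An `ecg_signal` (returned unchanged) or a numeric vector.
#' @param fs Sampling rate in Hz, required when `x` is a bare vector.
#' @return An `ecg_signal`.
#' @export
as_signal <- function(x, fs = NULL) {
  if (inherits(x, "ecg_signal")) return(x)
  if (is.null(fs)) stop("`fs` is required to build a signal from a vector",
                        call. = FALSE)
  ecg_signal(x, fs)
}

# shared precondition: same length and rate
check_same_grid <- function(a, b) {
  if (length(a$samples) != length(b$samples)) {
    stop(sprintf("signals differ in length (%d vs %d)",
                 length(a$samples), length(b$samples)), call. = FALSE)
  }
  if (abs(a$fs - b$fs) > 1e-9 * a$fs) {
    stop(sprintf("signals differ in sampling rate (%g vs %g Hz)", a$fs, b$fs),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Time axis of a signal
#'
#' @param x An `ecg_signal`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
signal_time <- function(x) {
  (seq_along(x$samples) - 1) / x$fs
}
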