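#' Adaptive notch filter configuration
#'
#' Parameter set for the LMS adaptive notch filter: an `N`-stage tapped delay
#' line driven by a sinusoidal reference `C * cos(w_r * k * T + theta)` and
#' adapted with step size `step`.  Two presets match the design used for ECG:
#' a DC/high-pass filter (`w_r = 0`, `N = 10000`, `step = 1e-4`, `C = 0.1`)
#' and a 60 Hz powerline filter (`N = 2048`, `step = 1e-3`, `C = 0.1`).
#'
#' Stability requires `step` below the reciprocal of the largest eigenvalue of
#' the reference correlation matrix; [lms_cancel()] warns when the trace bound
#' `N * mean(x^2)` already rules this out and aborts if the weights diverge.
#'
#' @param N Tap count (positive integer).
#' @param step Adaptation constant (>= 0; 0 freezes adaptation, so the
#'   filter passes the primary input unchanged -- useful for analysis).
#' @param C Reference amplitude (>= 0).
#' @param w_r Reference angular frequency in rad/s (>= 0; 0 gives a constant
#'   reference, i.e. a DC notch / high-pass filter).
#' @param theta Reference phase in radians.
#' @return A `notch_config` object.
#' @seealso [notch_filter()] for the presets, [notch_bandwidth()] for the
#'   design bandwidth the parameters imply.
#' @export
notch_config <- function(N, step, C = 0.1, w_r = 0, theta = 0) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("`N` must be a positive integer", call. = FALSE)
  if (!is.finite(step) || step < 0) stop("`step` must be >= 0", call. = FALSE)
  if (!is.finite(C) || C < 0) stop("`C` must be >= 0", call. = FALSE)
  if (!is.finite(w_r) || w_r < 0) stop("`w_r` must be >= 0", call. = FALSE)
  structure(list(N = N, step = step, C = C, w_r = w_r, theta = theta),
            class = "notch_config")
}

#' @export
print.notch_config <- function(x, ...) {
  cat(sprintf(
    "<notch_config: N=%d step=%g C=%g f_r=%.4g Hz theta=%g>\n",
    x$N, x$step, x$C, x$w_r / (2 * pi), x$theta))
  invisible(x)
}

#' Sinusoidal reference signal for the adaptive notch filter
#'
#' Generates `samples[k] = C * cos(w_r * k * T + theta)` for `k = 0, ...,
#' n - 1` with `T = 1/fs`.  For `w_r = 0` this is the constant
#' `C * cos(theta)`, the reference of the DC notch.
#'
#' @param n Number of samples (>= 1).
#' @param fs Sampling rate in Hz.
#' @param cfg A [notch_config()].
#' @return An [ecg_signal()].
#' @export
make_reference <- function(n, fs, cfg) {
  stopifnot(inherits(cfg, "notch_config"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  k <- seq_len(n) - 1
  ecg_signal(cfg$C * cos(cfg$w_r * k / fs + cfg$theta), fs)
}

#' LMS adaptive noise cancellation
#'
#' Core recursion of the adaptive noise canceller: at each sample `k` the
#' filter output is `y_k = w_k' x_k` where `x_k` is the length-`N` tapped
#' delay line of the reference (most recent sample first, zero-padded before
#' the start), the error is `e_k = d_k - y_k`, and the weights adapt as
#' `w_{k+1} = w_k + step * e_k * x_k`.  Weights start at zero, so
#' `output + interference_estimate == primary` holds exactly from sample one.
#' By default the delay line is zero before the first sample; for an analytic
#' reference the pre-history (`x` at `k = -1, -2, ...`) can be supplied to
#' remove the line-filling transient, which matters when `N` is comparable to
#' the record length.
#'
#' @param primary The primary input `d` (signal plus interference), an
#'   [ecg_signal()].
#' @param reference The reference input correlated with the interference;
#'   same length and rate as `primary`.
#' @param N Tap count.
#' @param step Adaptation constant (> 0).
#' @param guard Divergence guard: if the weight norm exceeds this value the
#'   filter aborts with an error naming the sample index. Default `1e12`.
#' @param ref_prehistory Optional numeric vector of reference samples before
#'   the record starts, most recent first (`x[-1], x[-2], ...`), used to
#'   pre-fill the tapped delay line; missing taps start at zero.
#' @return A `notch_result`: list with `output` (the error sequence, i.e. the
#'   cleaned signal), `interference_estimate` (the filter output `y`) and
#'   `final_weights`.
#' @export
lms_cancel <- function(primary, reference, N, step, guard = 1e12,
                       ref_prehistory = NULL) {
  primary <- as_signal(primary)
  reference <- as_signal(reference)
  check_same_grid(primary, reference)
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("`N` must be >= 1", call. = FALSE)
  if (!is.finite(step) || step < 0) stop("`step` must be >= 0", call. = FALSE)
  # stability pre-check: lambda_max <= trace(R) = N * E[x^2]
  pow <- mean(reference$samples^2)
  if (pow > 0 && step > 0 && step >= 1 / (N * pow)) {
    warning(sprintf(paste0(
      "step %g is at or above the stability bound 1/lambda_max ",
      "(trace bound 1/(N*E[x^2]) = %g); the adaptation may diverge"),
      step, 1 / (N * pow)), call. = FALSE)
  }
  res <- .lms_cpp(primary$samples, reference$samples, N, step, guard,
                  if (is.null(ref_prehistory)) numeric(0)
                  else as.numeric(ref_prehistory))
  if (res$diverged_at > 0) {
    stop(sprintf(paste0(
      "adaptive filter diverged at sample %d (weight norm exceeded %g); ",
      "reduce `step` below 1/lambda_max of the reference correlation matrix"),
      res$diverged_at, guard), call. = FALSE)
  }
  structure(list(
    output = ecg_signal(res$output, primary$fs),
    interference_estimate = ecg_signal(res$interference, primary$fs),
    final_weights = res$weights
  ), class = "notch_result")
}

#' @export
print.notch_result <- function(x, ...) {
  cat(sprintf("<notch_result: %d samples, %d taps>\n",
              length(x$output$samples), length(x$final_weights)))
  invisible(x)
}

#' Apply an adaptive notch filter to a signal
#'
#' Convenience wrapper: builds the sinusoidal reference with
#' [make_reference()] and runs [lms_cancel()].  `mode` selects a preset
#' configuration: `"dc"` is the high-pass filter that removes frequencies
#' around 0 Hz (`N = 10000`, `step = 1e-4`, `C = 0.1`, `w_r = 0`, design
#' bandwidth about 2.5 rad/s, i.e. 0.4 Hz); `"powerline"` removes 60 Hz
#' interference (`N = 2048`, `step = 1e-3`, `C = 0.1`, `w_r = 2*pi*60`).
#'
#' @param signal An [ecg_signal()].
#' @param cfg A [notch_config()]; overrides `mode` when supplied.
#' @param mode `"dc"` or `"powerline"` preset (ignored when `cfg` is given).
#' @param guard Divergence guard passed to [lms_cancel()].
#' @return A `notch_result` (see [lms_cancel()]); `output` is the signal with
#'   the notched band removed, `interference_estimate` the removed band.
#' @export
notch_filter <- function(signal, cfg = NULL, mode = c("dc", "powerline"),
                         guard = 1e12) {
  signal <- as_signal(signal)
  if (is.null(cfg)) {
    mode <- match.arg(mode)
    cfg <- switch(mode,
      dc = notch_config(N = 10000L, step = 1e-4, C = 0.1, w_r = 0),
      powerline = notch_config(N = 2048L, step = 1e-3, C = 0.1,
                               w_r = 2 * pi * 60))
  }
  n <- length(signal$samples)
  if (n < cfg$N) {
    warning(sprintf(
      "signal (%d samples) is shorter than the filter length N = %d",
      n, cfg$N), call. = FALSE)
  }
  ref <- make_reference(n, signal$fs, cfg)
  # the sinusoidal reference is analytic, so the delay line can start fully
  # populated with its pre-history instead of zeros
  kpre <- -seq_len(cfg$N - 1L)
  pre <- cfg$C * cos(cfg$w_r * kpre / signal$fs + cfg$theta)
  lms_cancel(signal, ref, N = cfg$N, step = cfg$step, guard = guard,
             ref_prehistory = pre)
}

#' Analytic transfer-function magnitude of the converged notch filter
#'
#' Magnitude of
#' \deqn{H(z) = \frac{z^2 - 2 z \cos(w_r T) + 1}
#'  {z^2 - 2 (1 - N \partial C^2/4) z \cos(w_r T) + (1 - N \partial C^2/2)}}
#' evaluated at `z = exp(i 2 pi f T)`.  The numerator vanishes at the
#' reference frequency, so the response is exactly 0 there; when
#' `N * step * C^2 = 0` numerator and denominator coincide and the response
#' is 1 at every frequency.
#'
#' @param cfg A [notch_config()].
#' @param fs Sampling rate in Hz.
#' @param freq Frequency (Hz) at which to evaluate, in `[0, fs/2]`.
#'   Vectorized.
#' @return Nonnegative magnitude(s).
#' @export
notch_transfer <- function(cfg, fs, freq) {
  stopifnot(inherits(cfg, "notch_config"))
  if (any(freq < 0 | freq > fs / 2)) {
    stop("`freq` must lie in [0, fs/2]", call. = FALSE)
  }
  T <- 1 / fs
  k <- cfg$N * cfg$step * cfg$C^2
  if (k == 0) return(rep(1, length(freq)))  # numerator == denominator
  z <- exp(2i * pi * freq * T)
  cwt <- cos(cfg$w_r * T)
  num <- z^2 - 2 * z * cwt + 1
  den <- z^2 - 2 * (1 - k / 4) * z * cwt + (1 - k / 2)
  if (any(Mod(den) < 1e-15)) {
    stop("transfer function pole at the requested frequency", call. = FALSE)
  }
  Mod(num) / Mod(den)
}

#' Time-varying component gain of the LMS notch filter
#'
#' `beta = sin(N w_r T) / sin(w_r T)`, the factor controlling how strongly the
#' time-varying part of the adaptive filter's response contributes; the filter
#' behaves as time-invariant when `beta / N` is near zero, which larger `N`
#' achieves.  At `w_r * T -> 0` the limit `N` is returned.
#'
#' @param N Tap count.
#' @param w_r Reference angular frequency in rad/s.
#' @param T Sampling interval in seconds.
#' @return The value of `beta` (vectorized over `w_r`).
#' @export
notch_beta <- function(N, w_r, T) {
  x <- w_r * T
  s <- sin(x)
  out <- ifelse(abs(s) < 1e-12, N, sin(N * x) / s)
  as.numeric(out)
}

#' Design bandwidth of the adaptive notch filter
#'
#' Approximate notch bandwidth `BW = N * step * C^2 / (2 T)` in rad/s.  For
#' the 60 Hz preset (`N = 2048`, `step = 1e-3`, `C = 0.1` at 500 Hz) this is
#' 5.12 rad/s, about 0.81 Hz.
#'
#' @param cfg A [notch_config()].
#' @param T Sampling interval in seconds (> 0).
#' @return Bandwidth in rad/s.
#' @export
notch_bandwidth <- function(cfg, T) {
  stopifnot(inherits(cfg, "notch_config"))
  if (!is.finite(T) || T <= 0) stop("`T` must be > 0", call. = FALSE)
  cfg$N * cfg$step * cfg$C^2 / (2 * T)
}

#' Empirical steady-state frequency response of a filtering operation
#'
#' Least-squares transfer estimate between an input and an output record:
#' both are cut into non-overlapping segments of `seg_len` samples after
#' discarding `discard` start-up samples, and the gain at each FFT bin is
#' `|sum conj(IN) * OUT| / sum |IN|^2` across segments.  Used to verify the
#' adaptive filter against [notch_transfer()].
#'
#' @param input,output `ecg_signal`s on the same grid (e.g. the primary input
#'   and the `output` of [notch_filter()]).
#' @param seg_len Segment length in samples; the frequency resolution is
#'   `fs / seg_len`.
#' @param discard Samples dropped from the start before estimating (the LMS
#'   transient); default `max(N, 2 s)` is a good choice for an `N`-tap filter.
#' @return A data frame with columns `freq` (Hz) and `gain`.
#' @export
empirical_response <- function(input, output, seg_len = 5000L,
                               discard = 0L) {
  input <- as_signal(input); output <- as_signal(output)
  check_same_grid(input, output)
  xin <- input$samples; xout <- output$samples
  if (discard > 0) {
    xin <- xin[-seq_len(discard)]
    xout <- xout[-seq_len(discard)]
  }
  nseg <- length(xin) %/% seg_len
  if (nseg < 1) stop("record too short for the requested segment length",
                     call. = FALSE)
  cross <- complex(seg_len)
  power <- numeric(seg_len)
  for (s in seq_len(nseg)) {
    idx <- ((s - 1) * seg_len + 1):(s * seg_len)
    fin <- stats::fft(xin[idx])
    fout <- stats::fft(xout[idx])
    cross <- cross + Conj(fin) * fout
    power <- power + Mod(fin)^2
  }
  half <- seq_len(seg_len %/% 2 + 1)
  data.frame(freq = (half - 1) * input$fs / seg_len,
             gain = Mod(cross[half]) / pmax(power[half],
                                            .Machine$double.xmin))
}
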