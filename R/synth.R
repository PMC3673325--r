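#' Default five-wave beat template
#'
#' One heartbeat modelled as a sum of five Gaussian bumps (P, Q, R, S, T),
#' each with an amplitude (R-wave units), a center offset from the R peak in
#' seconds, and a width (Gaussian sigma) in seconds.  The values are typical
#' lead-II proportions with a unit R wave.
#'
#' @return A data frame with columns `wave`, `amplitude`, `center`, `width`.
#' @export
beat_template <- function() {
  data.frame(
    wave      = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.15, -0.10, 1.00, -0.12, 0.30),
    center    = c(-0.200, -0.030, 0.000, 0.030, 0.250),
    width     = c(0.025, 0.010, 0.012, 0.010, 0.050),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic ECG record
#'
#' Declarative description of a simulated single-lead ECG: template beats at
#' a given heart rate, additive band-limited baseline wander (a sparse sum of
#' sinusoids in the 0.05-0.5 Hz band, optionally amplitude-modulated by a
#' slow piecewise-linear envelope), optional 60 Hz powerline interference,
#' and white Gaussian noise.  All randomness (beat-to-beat jitter, noise) is
#' driven by `seed`.
#'
#' @param fs Sampling rate in Hz, default 500.
#' @param duration Record length in seconds.
#' @param heart_rate Mean heart rate in beats per minute, default 72.
#' @param hr_jitter Beat-to-beat RR jitter as a fraction of the mean RR
#'   interval (uniform), default 0.05.
#' @param template Beat template data frame, see [beat_template()].
#' @param wander Data frame with columns `freq` (Hz, each in `[0.05, 0.5]`),
#'   `amplitude` and `phase` describing the wander sinusoids.  The default
#'   mixes a slow electrode-drift component at 0.1 Hz with respiratory
#'   components at 0.21 and 0.33 Hz.
#' @param wander_envelope Optional slow amplitude modulation of the wander: a
#'   list with `times` (s) and `values`, linearly interpolated (and held at
#'   the ends).  `NULL` for a constant-amplitude wander.
#' @param powerline List with `amplitude`, `freq` (default 60 Hz) and
#'   `phase`; amplitude 0 disables it.
#' @param noise_sd Standard deviation of the additive white noise, default
#'   0.02 (2% of the R amplitude).
#' @param seed Integer seed.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(fs = 500, duration = 60, heart_rate = 72,
                       hr_jitter = 0.05, template = beat_template(),
                       wander = data.frame(
                         freq = c(0.10, 0.21, 0.33),
                         amplitude = c(0.70, 0.40, 0.20),
                         phase = c(0.4, 1.7, 2.9)),
                       wander_envelope = NULL,
                       powerline = list(amplitude = 0, freq = 60, phase = 0),
                       noise_sd = 0.02, seed = 1L) {
  if (!is.finite(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  if (!is.finite(duration) || duration <= 0) {
    stop("`duration` must be > 0", call. = FALSE)
  }
  if (nrow(wander) > 0) {
    if (any(wander$freq < 0.05 - 1e-12 | wander$freq > 0.5 + 1e-12)) {
      stop("wander frequencies must lie in [0.05, 0.5] Hz", call. = FALSE)
    }
  }
  if (any(template$width <= 0)) {
    stop("beat template widths must be positive", call. = FALSE)
  }
  structure(list(fs = fs, duration = duration, heart_rate = heart_rate,
                 hr_jitter = hr_jitter, template = template, wander = wander,
                 wander_envelope = wander_envelope, powerline = powerline,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' Generate a synthetic ECG record with ground truth
#'
#' Realizes a [synth_spec()]: beats are placed at jittered RR intervals,
#' each beat is the sum of the template's five Gaussian waves, and the four
#' additive components (clean ECG, wander, powerline, noise) are generated
#' independently, so `mixture == ecg_clean + wander_true + powerline_true +
#' noise` holds sample-exactly.  Deterministic per seed; the caller's RNG
#' state is untouched.
#'
#' @param spec A [synth_spec()].
#' @return A `synth_record`: list of [ecg_signal()]s `mixture`, `ecg_clean`,
#'   `wander_true`, `powerline_true`, `noise`, plus `r_peaks` (R-peak times
#'   in seconds) and the `spec`.
#' @export
synth_ecg <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- round(spec$duration * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  rr_mean <- 60 / spec$heart_rate
  out <- with_local_seed(spec$seed, {
    n_max <- ceiling(spec$duration / rr_mean) + 2L
    rr <- rr_mean * (1 + spec$hr_jitter * stats::runif(n_max, -1, 1))
    centers <- 0.5 * rr_mean + cumsum(c(0, rr[-n_max]))
    centers <- centers[centers < spec$duration]
    noise <- stats::rnorm(n, sd = spec$noise_sd)
    list(centers = centers, noise = noise)
  })
  ecg <- numeric(n)
  tpl <- spec$template
  for (ct in out$centers) {
    for (w in seq_len(nrow(tpl))) {
      mu <- ct + tpl$center[w]
      sg <- tpl$width[w]
      lo <- max(1L, floor((mu - 6 * sg) * spec$fs) + 1L)
      hi <- min(n, ceiling((mu + 6 * sg) * spec$fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      ecg[idx] <- ecg[idx] +
        tpl$amplitude[w] * exp(-(t[idx] - mu)^2 / (2 * sg^2))
    }
  }
  wander <- numeric(n)
  if (nrow(spec$wander) > 0) {
    for (w in seq_len(nrow(spec$wander))) {
      wander <- wander + spec$wander$amplitude[w] *
        sin(2 * pi * spec$wander$freq[w] * t + spec$wander$phase[w])
    }
    if (!is.null(spec$wander_envelope)) {
      env <- stats::approx(spec$wander_envelope$times,
                           spec$wander_envelope$values, xout = t,
                           rule = 2)$y
      wander <- wander * env
    }
  }
  pl <- spec$powerline
  powerline <- if (is.null(pl) || pl$amplitude == 0) numeric(n) else {
    pl$amplitude * sin(2 * pi * pl$freq * t + pl$phase)
  }
  mixture <- ecg + wander + powerline + out$noise
  structure(list(
    mixture = ecg_signal(mixture, spec$fs),
    ecg_clean = ecg_signal(ecg, spec$fs),
    wander_true = ecg_signal(wander, spec$fs),
    powerline_true = ecg_signal(powerline, spec$fs),
    noise = ecg_signal(out$noise, spec$fs),
    r_peaks = out$centers,
    spec = spec
  ), class = "synth_record")
}

#' @export
print.synth_record <- function(x, ...) {
  cat(sprintf("<synth_record: %.1f s @ %g Hz, %d beats, wander RMS %.3f>\n",
              x$spec$duration, x$spec$fs, length(x$r_peaks),
              sqrt(mean(x$wander_true$samples^2))))
  invisible(x)
}

#' Generate a cohort of synthetic records with varied wander severity
#'
#' Emulates a multi-subject experiment of the kind produced by lower body
#' negative pressure (LBNP) protocols, where progressive suction to the
#' lower body raises respiratory drive and with it the severity of
#' baseline drift: each record draws its own wander
#' frequencies (within 0.05-0.5 Hz), phases, peak amplitude (log-uniform
#' between `amp_range[1]` and `amp_range[2]` times the R amplitude) and, with
#' probability `envelope_prob`, a slowly drifting amplitude envelope (a ramp
#' between two random levels), covering both the moderate-wander and the
#' strong-drift regimes.
#'
#' @param n_subjects Number of records (>= 1).
#' @param seed Master seed; record `i` uses `seed + i` for its own spec and
#'   generation, so the suite is reproducible and records are distinct.
#' @param duration,fs Record geometry, defaults 60 s at 500 Hz.
#' @param amp_range Wander peak amplitude range in R-amplitude units,
#'   default `c(0.2, 3)`.
#' @param envelope_prob Probability that a record gets a drifting envelope,
#'   default 0.3.
#' @return List of `synth_record` objects.
#' @export
lbnp_like_suite <- function(n_subjects, seed = 1L, duration = 60, fs = 500,
                            amp_range = c(0.2, 3), envelope_prob = 0.3) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  lapply(seq_len(n_subjects), function(i) {
    sp <- with_local_seed(seed + i, {
      k <- sample(2:4, 1)
      freq <- sort(stats::runif(k, 0.05, 0.5))
      rel <- 0.5^(seq_len(k) - 1)               # decreasing with frequency
      phase <- stats::runif(k, 0, 2 * pi)
      peak <- exp(stats::runif(1, log(amp_range[1]), log(amp_range[2])))
      amp <- rel * peak / sum(rel)              # peak envelope ~ `peak`
      env <- if (stats::runif(1) < envelope_prob) {
        lv <- stats::runif(2, 0.3, 1)
        list(times = c(0, duration), values = lv / max(lv))
      } else NULL
      hr <- stats::runif(1, 55, 95)
      synth_spec(fs = fs, duration = duration, heart_rate = hr,
                 wander = data.frame(freq = freq, amplitude = amp,
                                     phase = phase),
                 wander_envelope = env, seed = seed + i)
    })
    synth_ecg(sp)
  })
}

#' Write a synthetic record to CSV
#'
#' Columns `t`, `mixture`, `ecg_clean`, `wander_true`, `powerline_true`,
#' `noise`; comma separated, one header line.
#'
#' @param record A `synth_record`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "synth_record"))
  df <- data.frame(t = signal_time(record$mixture),
                   mixture = record$mixture$samples,
                   ecg_clean = record$ecg_clean$samples,
                   wander_true = record$wander_true$samples,
                   powerline_true = record$powerline_true$samples,
                   noise = record$noise$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
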