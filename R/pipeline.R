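#' Delay-embedding configuration
#'
#' How a single-channel signal is expanded into a pseudo-multichannel matrix:
#' `n_channels` copies delayed in steps of `delay_step` samples.  The default
#' 60 channels x 10 samples mirrors the embedding used for 500 Hz ECG.
#'
#' @param n_channels Number of delayed copies (>= 2), default 60.
#' @param delay_step Delay between consecutive copies in samples (>= 1),
#'   default 10.
#' @return An `embedding_config` object.
#' @export
embedding_config <- function(n_channels = 60L, delay_step = 10L) {
  n_channels <- as.integer(n_channels)
  delay_step <- as.integer(delay_step)
  if (is.na(n_channels) || n_channels < 2L) {
    stop("`n_channels` must be >= 2", call. = FALSE)
  }
  if (is.na(delay_step) || delay_step < 1L) {
    stop("`delay_step` must be >= 1", call. = FALSE)
  }
  structure(list(n_channels = n_channels, delay_step = delay_step),
            class = "embedding_config")
}

#' Build a multichannel matrix from one signal by delay embedding
#'
#' Row `i` (1-based) holds the signal advanced by `(i - 1) * delay_step`
#' samples; all rows are truncated to the common support of length
#' `L = length - (n_channels - 1) * delay_step`, so row 1 is the undelayed
#' original over the support and no padding is fabricated.  The per-row
#' offsets into the original record are stored in the `"offsets"` attribute.
#'
#' @param signal An [ecg_signal()] longer than
#'   `(n_channels - 1) * delay_step + 1` samples.
#' @param cfg An [embedding_config()].
#' @return A [mixture_matrix()] with an `"offsets"` attribute (0-based
#'   sample offset of each row relative to the original record).
#' @export
build_multichannel <- function(signal, cfg = embedding_config()) {
  signal <- as_signal(signal)
  stopifnot(inherits(cfg, "embedding_config"))
  n <- length(signal$samples)
  span <- (cfg$n_channels - 1L) * cfg$delay_step
  L <- n - span
  if (L < cfg$n_channels + 1L) {
    stop(sprintf(
      "signal too short for the embedding: need more than %d samples, got %d",
      span + cfg$n_channels + 1L, n), call. = FALSE)
  }
  offs <- (seq_len(cfg$n_channels) - 1L) * cfg$delay_step
  m <- vapply(offs, function(o) signal$samples[(o + 1):(o + L)], numeric(L))
  mm <- mixture_matrix(t(m), signal$fs)
  attr(mm, "offsets") <- offs
  mm
}

#' Score components by low-frequency power and pick the baseline candidate
#'
#' The baseline-wander component is identified as the one whose spectral
#' power is most concentrated below `f_cut`: each component's score is the
#' fraction of its periodogram power (mean removed, DC bin excluded) below
#' `f_cut` Hz, and the highest-scoring component wins (ties to the lower
#' index).
#'
#' @param model An `ica_model` from [fastica()].
#' @param fs Sampling rate in Hz (defaults to the model's).
#' @param f_cut Cut-off in Hz, `0 < f_cut < fs/2`; default 0.8 Hz, just above
#'   the conventional 0.5 Hz upper edge of the wander band.
#' @return List with `index` (selected component) and `scores` (all power
#'   fractions).
#' @export
select_baseline_component <- function(model, fs = model$fs, f_cut = 0.8) {
  stopifnot(inherits(model, "ica_model"))
  if (!is.finite(fs) || f_cut <= 0 || f_cut >= fs / 2) {
    stop("need 0 < f_cut < fs/2 and a known sampling rate", call. = FALSE)
  }
  n <- ncol(model$components)
  fgrid <- (seq_len(n) - 1) * fs / n
  # two-sided bins below f_cut (and their aliases), DC excluded
  low <- (fgrid < f_cut | fgrid > fs - f_cut) & fgrid > 0
  scores <- apply(model$components, 1, function(s) {
    p <- Mod(stats::fft(s - mean(s)))^2
    p[1] <- 0
    tot <- sum(p)
    if (tot == 0) 0 else sum(p[low]) / tot
  })
  list(index = which.max(scores), scores = as.numeric(scores))
}

#' Project independent components onto an observed channel
#'
#' Returns the components' contribution to the chosen (centered) channel,
#' `sum_i mixing_estimate[channel, i] * components[i, ]`, which undoes the
#' sign/scale indeterminacy of ICA: flipping the sign of a component and of
#' its mixing column leaves the result unchanged.  `index` may be a vector,
#' in which case the contributions are summed -- used when the wander splits
#' across several narrowband components.  Channel means are not added back;
#' the downstream elevation fit absorbs them.
#'
#' @param model An `ica_model`.
#' @param index Component index or vector of indices (1-based).
#' @param channel Channel index (1-based), default 1 (the undelayed row of a
#'   delay embedding).
#' @return An [ecg_signal()] (fs taken from the model).
#' @export
component_on_channel <- function(model, index, channel = 1L) {
  stopifnot(inherits(model, "ica_model"))
  index <- as.integer(index)
  if (any(index < 1 | index > nrow(model$components))) {
    stop("component index out of range", call. = FALSE)
  }
  if (channel < 1 || channel > nrow(model$mixing_estimate)) {
    stop("channel index out of range", call. = FALSE)
  }
  contrib <- drop(model$mixing_estimate[channel, index, drop = FALSE] %*%
                    model$components[index, , drop = FALSE])
  ecg_signal(contrib, if (is.finite(model$fs)) model$fs else 1)
}

#' Zero-phase low-pass trend of a signal
#'
#' Forward-backward (zero-phase) 4th-order Butterworth low-pass, used as the
#' blind adjustment target: the sub-`f_cut` trend of the raw record is the
#' natural stand-in for a reference baseline when none is available.
#'
#' @param signal An [ecg_signal()].
#' @param f_cut Cut-off frequency in Hz.
#' @param order Butterworth order, default 4.
#' @return An [ecg_signal()] of the same length.
#' @export
lowpass_target <- function(signal, f_cut = 0.8, order = 4L) {
  signal <- as_signal(signal)
  bt <- signal::butter(order, f_cut / (signal$fs / 2), type = "low")
  ecg_signal(signal::filtfilt(bt, signal$samples), signal$fs)
}

#' Align and rescale a raw baseline component (shift / elevation / gain)
#'
#' The component extracted by ICA approximates the baseline wander only up to
#' a time shift, an amplitude offset and a scale.  For every candidate
#' integer shift in `shift_range` this fits
#' `gain * raw(k - shift) + elevation` to the target by closed-form affine
#' least squares over the overlap and keeps the shift with the smallest mean
#' squared residual.  Because shift 0 with a free gain/elevation is always in
#' the search set, the adjusted baseline never fits the target worse than the
#' raw component does.
#'
#' @param raw The raw baseline component (an [ecg_signal()]), aligned so its
#'   first sample corresponds to original sample `1 + offset`.
#' @param target The alignment target on the full original grid: a reference
#'   baseline (reference mode) or the low-pass trend of the original record
#'   (blind mode).
#' @param shift_range Integer vector `c(lo, hi)` of candidate shifts in
#'   samples; default `c(0, 1180)`, twice the span of the default 60 x 10
#'   embedding.
#' @param offset Sample offset of `raw[1]` within the original record
#'   (0-based), default 0.
#' @param fit_elevation Fit the vertical offset (default `TRUE`).  Set
#'   `FALSE` to constrain the fit through the origin: appropriate when the
#'   target's DC level belongs to the signal itself (e.g. the beat-mean of
#'   an ECG inside a low-pass trend) rather than to the drift, since the
#'   extracted components and the modelled wander are zero-mean.
#' @param components Optional matrix (rows = individual baseline components
#'   on the channel scale, summing to `raw`).  When given, the shift is
#'   chosen by the scalar-gain scan and then each component receives its own
#'   gain by multiple affine least squares at that shift, which undoes
#'   frequency-dependent attenuation across narrowband components.  The
#'   scalar fit is nested in this model (all gains equal), so the residual
#'   can only improve.
#' @return A `baseline_estimate`: list with `shift`, `elevation`, `gain`
#'   (scalar, or per-component vector when `components` is used), `mse`
#'   (residual against the target on the overlap), `overlap` (the fitted
#'   target-index window), `raw_component`, and `baseline` (the adjusted
#'   series on the full original grid, edge values held outside the shifted
#'   support).
#' @export
adjust_baseline <- function(raw, target, shift_range = c(0L, 1180L),
                            offset = 0L, fit_elevation = TRUE,
                            components = NULL) {
  raw <- as_signal(raw); target <- as_signal(target)
  if (abs(raw$fs - target$fs) > 1e-9 * target$fs) {
    stop("`raw` and `target` must share a sampling rate", call. = FALSE)
  }
  r <- raw$samples
  tg <- target$samples
  nL <- length(r); nT <- length(tg)
  shifts <- seq.int(as.integer(shift_range[1]), as.integer(shift_range[2]))
  best <- NULL
  any_valid <- FALSE
  for (s in shifts) {
    # raw sample j sits at original index j + offset + s
    j0 <- max(1L, 1L - offset - s)          # first usable raw index
    j1 <- min(nL, nT - offset - s)          # last usable raw index
    if (j1 - j0 + 1L < 2L) next
    any_valid <- TRUE
    x <- r[j0:j1]
    y <- tg[(j0 + offset + s):(j1 + offset + s)]
    n <- length(x)
    if (fit_elevation) {
      sx <- sum(x); sy <- sum(y)
      vxx <- sum(x * x) - sx * sx / n
      vxy <- sum(x * y) - sx * sy / n
      g <- if (vxx > 0) vxy / vxx else 0
      e <- (sy - g * sx) / n
    } else {
      sxx <- sum(x * x)
      g <- if (sxx > 0) sum(x * y) / sxx else 0
      e <- 0
    }
    resid <- y - (g * x + e)
    mse <- sum(resid^2) / n
    if (is.null(best) || mse < best$mse) {
      best <- list(shift = s, gain = g, elevation = e, mse = mse)
    }
  }
  if (!any_valid) {
    stop("no candidate shift leaves an overlap with the target", call. = FALSE)
  }
  gains <- best$gain
  if (!is.null(components)) {
    components <- as.matrix(components)
    if (ncol(components) != nL) {
      stop("`components` must have one column per raw sample", call. = FALSE)
    }
    s <- best$shift
    j0 <- max(1L, 1L - offset - s)
    j1 <- min(nL, nT - offset - s)
    Xc <- t(components[, j0:j1, drop = FALSE])
    X <- if (fit_elevation) cbind(1, Xc) else Xc
    yw <- tg[(j0 + offset + s):(j1 + offset + s)]
    cf <- stats::lm.fit(X, yw)$coefficients
    cf[is.na(cf)] <- 0
    resid <- yw - drop(X %*% cf)
    best$elevation <- if (fit_elevation) unname(cf[1]) else 0
    gains <- if (fit_elevation) unname(cf[-1]) else unname(cf)
    best$mse <- sum(resid^2) / length(resid)
  }
  # assemble the adjusted baseline on the full original grid
  base <- numeric(nT)
  lo <- best$shift + offset + 1L
  hi <- min(nT, best$shift + offset + nL)
  j1 <- hi - best$shift - offset
  seg <- if (is.null(components)) {
    best$gain * r[seq_len(j1)] + best$elevation
  } else {
    drop(gains %*% components[, seq_len(j1), drop = FALSE]) + best$elevation
  }
  if (lo > 1L) base[seq_len(lo - 1L)] <- seg[1]
  base[lo:hi] <- seg
  if (hi < nT) base[(hi + 1L):nT] <- seg[length(seg)]
  structure(list(
    shift = best$shift, elevation = best$elevation, gain = gains,
    mse = best$mse, overlap = c(lo, hi),
    raw_component = raw,
    baseline = ecg_signal(base, target$fs)
  ), class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf(
    "<baseline_estimate: shift=%d samples, elevation=%.4g, gain=[%s], mse=%.4g>\n",
    x$shift, x$elevation, paste(signif(x$gain, 4), collapse = ", "), x$mse))
  invisible(x)
}

#' Pipeline configuration
#'
#' All tunable parameters of [remove_baseline()] in one declarative object.
#'
#' @param powerline Apply the 60 Hz adaptive notch before anything else
#'   (default `FALSE`; enable for mains-contaminated records).
#' @param dc_notch [notch_config()] of the DC/high-pass stage whose
#'   interference estimate is the low-frequency sub-signal fed to ICA.
#' @param embedding [embedding_config()] for the delay embedding.
#' @param n_components Components to extract (default 20 of the 60 whitened
#'   dimensions; the wander concentrates in the leading low-frequency
#'   variance).
#' @param kind,tol,max_iter FastICA controls, see [fastica()].
#' @param f_cut Selection / blind-target cut-off in Hz (default 0.8).
#' @param shift_range Shift search interval in samples, see
#'   [adjust_baseline()].
#' @param mode `"blind"` (target = low-pass trend of the input; deployment
#'   default) or `"reference"` (target supplied to [remove_baseline()]).
#' @param min_score Lowest acceptable selection score; if no component
#'   concentrates at least this fraction of its power below `f_cut` the run
#'   aborts rather than subtracting a non-baseline component. Default 0.2.
#' @param score_threshold Components whose score reaches this value are all
#'   counted as baseline and their channel contributions summed (the wander
#'   can split into several narrowband components under the delay
#'   embedding); the top-scoring component is always included. Default 0.5.
#' @param seed Seed for all pipeline randomness (the ICA initial directions).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(powerline = FALSE,
                            dc_notch = notch_config(N = 10000L, step = 1e-4,
                                                    C = 0.1, w_r = 0),
                            embedding = embedding_config(),
                            n_components = 20L,
                            kind = "g1", tol = 1e-6, max_iter = 500L,
                            f_cut = 0.8,
                            shift_range = c(0L, 1180L),
                            mode = c("blind", "reference"),
                            min_score = 0.2,
                            score_threshold = 0.5,
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dc_notch, "notch_config"),
            inherits(embedding, "embedding_config"))
  structure(list(powerline = isTRUE(powerline), dc_notch = dc_notch,
                 embedding = embedding,
                 n_components = as.integer(n_components), kind = kind,
                 tol = tol, max_iter = as.integer(max_iter), f_cut = f_cut,
                 shift_range = as.integer(shift_range), mode = mode,
                 min_score = min_score, score_threshold = score_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Remove baseline wander from a single-channel ECG
#'
#' The full hierarchical method: (1) optional 60 Hz adaptive notch; (2) the
#' DC-mode adaptive notch splits the record and its interference estimate
#' (the sub-0.5 Hz band) becomes the low-frequency sub-signal; (3) the
#' sub-signal is delay-embedded into a pseudo-multichannel matrix; (4)
#' fixed-point ICA decomposes it; (5) the component with the most sub-`f_cut`
#' power is selected; (6) it is projected onto the undelayed channel; (7) a
#' shift/elevation/gain adjustment aligns it to the target (the record's own
#' low-pass trend in blind mode, a supplied reference baseline in reference
#' mode); (8) the adjusted baseline is subtracted.
#'
#' @param signal The contaminated record, an [ecg_signal()] (or numeric
#'   vector with `fs`).
#' @param config A [pipeline_config()].
#' @param reference_baseline Target for `mode = "reference"`, an
#'   [ecg_signal()] on the same grid as `signal` (e.g. from
#'   [lowess_baseline()]).
#' @param fs Sampling rate when `signal` is a bare vector.
#' @return List with `clean` (signal minus baseline, full length),
#'   `estimate` (the [adjust_baseline()] result, including the fitted shift,
#'   elevation and gain), and `report` (per-stage diagnostics: selection
#'   scores, chosen component, ICA iteration counts, sub-signal, embedding
#'   offsets).
#' @examples
#' rec <- synth_ecg(synth_spec(duration = 20, seed = 42))
#' out <- remove_baseline(rec$mixture, pipeline_config(seed = 1))
#' cor(out$estimate$baseline$samples, rec$wander_true$samples)
#' @export
remove_baseline <- function(signal, config = pipeline_config(),
                            reference_baseline = NULL, fs = NULL) {
  signal <- as_signal(signal, fs)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  work <- signal
  if (config$powerline) {
    work <- stage("powerline-notch",
                  notch_filter(work, mode = "powerline")$output)
  }
  sub <- stage("dc-notch",
               notch_filter(work, cfg = config$dc_notch)$interference_estimate)
  mm <- stage("embedding", build_multichannel(sub, config$embedding))
  model <- stage("ica",
                 fastica(mm, n_components = config$n_components,
                         kind = config$kind, tol = config$tol,
                         max_iter = config$max_iter, seed = config$seed))
  sel <- stage("selection",
               select_baseline_component(model, fs = signal$fs,
                                         f_cut = config$f_cut))
  if (max(sel$scores) < config$min_score) {
    stop(sprintf(paste0(
      "[selection] no low-frequency component found: best score %.3f < %.3f",
      " (the record may not contain baseline wander in the analysed band)"),
      max(sel$scores), config$min_score), call. = FALSE)
  }
  picked <- union(sel$index,
                  which(sel$scores >= config$score_threshold))
  raw <- stage("projection", component_on_channel(model, picked, 1L))
  comp_mat <- model$mixing_estimate[1L, picked] *
    model$components[picked, , drop = FALSE]
  target <- if (config$mode == "reference") {
    if (is.null(reference_baseline)) {
      stop("[adjustment] reference mode needs `reference_baseline`",
           call. = FALSE)
    }
    as_signal(reference_baseline)
  } else {
    stage("blind-target", lowpass_target(signal, config$f_cut))
  }
  est <- stage("adjustment",
               adjust_baseline(raw, target, shift_range = config$shift_range,
                               offset = 0L,
                               fit_elevation = config$mode == "reference",
                               components = if (length(picked) > 1L)
                                 comp_mat else NULL))
  clean <- ecg_signal(signal$samples - est$baseline$samples, signal$fs)
  report <- list(
    selection_scores = sel$scores,
    component_index = sel$index,
    component_indices = picked,
    ica_iterations = model$iterations,
    ica_converged = model$converged,
    sub_signal = sub,
    embedding_offsets = attr(mm, "offsets"),
    mode = config$mode,
    shift = est$shift, elevation = est$elevation, gain = est$gain,
    adjust_mse = est$mse
  )
  list(clean = clean, estimate = est, report = report)
}
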