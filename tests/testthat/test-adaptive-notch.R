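fs <- 500

test_that("reference generator matches its closed form", {
  cfg <- notch_config(N = 4, step = 0.01, C = 0.1, w_r = 0, theta = 0)
  expect_equal(make_reference(5, fs, cfg)$samples, rep(0.1, 5))
  cfg60 <- notch_config(N = 4, step = 0.01, C = 1, w_r = 2 * pi * 60)
  expect_equal(make_reference(1, fs, cfg60)$samples[1], 1.0)
  cfgp <- notch_config(N = 4, step = 0.01, C = 0.7, w_r = 2 * pi * 13,
                       theta = 1.1)
  r <- make_reference(1000, fs, cfgp)$samples
  expect_true(max(abs(r)) <= 0.7 + 1e-12)
  k <- 0:999
  expect_equal(r, 0.7 * cos(2 * pi * 13 * k / fs + 1.1))
})

test_that("a zero reference leaves the primary untouched", {
  d <- ecg_signal(rnorm(300), fs)
  z <- ecg_signal(rep(0, 300), fs)
  res <- lms_cancel(d, z, N = 16, step = 0.05)
  expect_identical(res$output$samples, d$samples)
  expect_identical(res$final_weights, rep(0, 16))
})

test_that("a matched sinusoidal reference is cancelled to steady state", {
  t <- (0:(10 * fs - 1)) / fs
  s <- ecg_signal(sin(2 * pi * 60 * t), fs)
  res <- lms_cancel(s, s, N = 32, step = 0.01)
  last_sec <- (9 * fs + 1):(10 * fs)
  expect_lt(max(abs(res$output$samples[last_sec])), 1e-3)
})

test_that("cancellation output and interference estimate sum exactly to the primary", {
  set.seed(11)
  for (case in 1:4) {
    d <- ecg_signal(rnorm(1500), fs)
    cfg <- notch_config(N = sample(c(8, 64, 256), 1), step = 1e-3, C = 0.5,
                        w_r = 2 * pi * runif(1, 0, 100))
    ref <- make_reference(1500, fs, cfg)
    res <- lms_cancel(d, ref, N = cfg$N, step = cfg$step)
    expect_equal(res$output$samples + res$interference_estimate$samples,
                 d$samples, tolerance = 1e-14)
  }
})

test_that("a frozen step passes the primary through unchanged", {
  d <- ecg_signal(rnorm(400), fs)
  cfg <- notch_config(N = 32, step = 0, C = 1, w_r = 2 * pi * 60)
  res <- notch_filter(d, cfg)
  expect_identical(res$output$samples, d$samples)
})

test_that("a step above the stability bound diverges with a diagnosis", {
  t <- (0:(4 * fs - 1)) / fs
  strong <- ecg_signal(10 * cos(2 * pi * 60 * t), fs)
  d <- ecg_signal(rnorm(4 * fs), fs)
  expect_warning(
    expect_error(lms_cancel(d, strong, N = 100, step = 0.1),
                 "diverged at sample"),
    "stability bound")
})

test_that("mismatched inputs are rejected", {
  a <- ecg_signal(rnorm(100), fs)
  b <- ecg_signal(rnorm(99), fs)
  expect_error(lms_cancel(a, b, 8, 0.01), "length")
  c2 <- ecg_signal(rnorm(100), 250)
  expect_error(lms_cancel(a, c2, 8, 0.01), "rate")
})

test_that("the DC notch removes a constant level", {
  cst <- ecg_signal(rep(5, 5000), fs)
  res <- suppressWarnings(notch_filter(cst, mode = "dc"))
  expect_lt(max(abs(res$output$samples[4001:5000])), 0.01 * 5)
})

test_that("the 60 Hz notch attenuates pure powerline by at least 20 dB", {
  t <- (0:(10 * fs - 1)) / fs
  pl <- ecg_signal(sin(2 * pi * 60 * t), fs)
  res <- notch_filter(pl, mode = "powerline")
  last <- (9 * fs + 1):(10 * fs)
  att <- sqrt(mean(res$output$samples[last]^2)) / sqrt(mean(pl$samples^2))
  expect_lt(att, 10^(-20 / 20))
})

test_that("the DC notch preserves ECG morphology beyond the removed DC", {
  nowander <- data.frame(freq = numeric(), amplitude = numeric(),
                         phase = numeric())
  rec <- synth_ecg(synth_spec(duration = 60, seed = 2, wander = nowander,
                              noise_sd = 0))
  res <- notch_filter(rec$mixture, mode = "dc")
  # steady state after the LMS transient; the filter's job includes taking
  # out the beat-mean DC, so compare against the mean-removed clean ECG
  ss <- 10001:30000
  d <- rec$mixture$samples
  rmse <- sqrt(mean((res$output$samples[ss] - (d[ss] - mean(d)))^2))
  expect_lt(rmse, 0.05 * 1.0)  # R amplitude is 1 in the default template
})

test_that("analytic transfer magnitude has the designed null and all-pass limits", {
  cfg <- notch_config(2048, 1e-3, 0.1, w_r = 2 * pi * 60)
  expect_equal(notch_transfer(cfg, fs, 60), 0, tolerance = 1e-12)
  # N * step * C^2 = 0 makes numerator and denominator identical
  cfg0 <- notch_config(2048, 0, 0.1, w_r = 2 * pi * 60)
  freqs <- seq(0, fs / 2, by = 5)
  expect_equal(notch_transfer(cfg0, fs, freqs), rep(1, length(freqs)))
  # far from the notch the response is essentially unity
  bw_hz <- notch_bandwidth(cfg, 1 / fs) / (2 * pi)
  far <- freqs[abs(freqs - 60) > 5 * bw_hz & freqs > 0]
  expect_true(all(abs(notch_transfer(cfg, fs, far) - 1) < 0.05))
  expect_error(notch_transfer(cfg, fs, fs), "fs/2")
})

test_that("the time-varying gain factor follows sin(Nx)/sin(x)", {
  expect_equal(notch_beta(64, 1e-15, 1), 64)       # limit at w_r T -> 0
  expect_equal(notch_beta(1, 2 * pi * 60, 1 / fs), 1)
  expect_equal(notch_beta(3, pi / 6, 1), sin(pi / 2) / sin(pi / 6))
  expect_equal(notch_beta(3, pi / 6, 1), 2)
})

test_that("design bandwidth follows N step C^2 / (2T)", {
  cfg <- notch_config(2048, 1e-3, 0.1, w_r = 2 * pi * 60)
  expect_equal(notch_bandwidth(cfg, 1 / 500), 5.12)
  cfg2 <- notch_config(2048, 1e-3, 0.2, w_r = 2 * pi * 60)
  expect_equal(notch_bandwidth(cfg2, 1 / 500),
               4 * notch_bandwidth(cfg, 1 / 500))
  cfg0 <- notch_config(2048, 1e-3, 0, w_r = 2 * pi * 60)
  expect_equal(notch_bandwidth(cfg0, 1 / 500), 0)
})
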