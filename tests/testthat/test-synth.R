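test_that("spec validation rejects out-of-band wander and bad templates", {
  expect_error(synth_spec(wander = data.frame(freq = 0.7, amplitude = 1,
                                              phase = 0)),
               "0.05, 0.5")
  bad <- beat_template()
  bad$width[3] <- -0.01
  expect_error(synth_spec(template = bad), "width")
  expect_error(synth_spec(duration = 0), "duration")
})

test_that("records decompose additively and are seed-deterministic", {
  sp <- synth_spec(duration = 10, seed = 12,
                   powerline = list(amplitude = 0.1, freq = 60, phase = 0.3))
  r1 <- synth_ecg(sp)
  expect_identical(r1$mixture$samples,
                   r1$ecg_clean$samples + r1$wander_true$samples +
                     r1$powerline_true$samples + r1$noise$samples)
  r2 <- synth_ecg(sp)
  expect_identical(r1, r2)
  # with everything but the beats switched off, mixture == clean ECG
  quiet <- synth_ecg(synth_spec(duration = 5, seed = 1,
                                wander = data.frame(freq = numeric(),
                                                    amplitude = numeric(),
                                                    phase = numeric()),
                                noise_sd = 0))
  expect_identical(quiet$mixture$samples, quiet$ecg_clean$samples)
})

test_that("beat count follows the programmed heart rate", {
  for (case in list(c(20, 72), c(30, 55), c(15, 95))) {
    rec <- synth_ecg(synth_spec(duration = case[1], heart_rate = case[2],
                                seed = 2))
    expect_lte(abs(length(rec$r_peaks) - round(case[1] * case[2] / 60)), 1)
  }
})

test_that("generated wander is spectrally confined to its band", {
  rec <- synth_ecg(synth_spec(duration = 60, seed = 1))
  w <- rec$wander_true$samples
  total <- band_power(w, 500, 0, 250)
  inband <- band_power(w, 500, 0.03, 0.6)
  expect_lt(1 - inband / total, 0.01)
})

test_that("the multi-subject suite spans weak to severe wander", {
  suite <- lbnp_like_suite(20, seed = 1, duration = 10)
  expect_length(suite, 20)
  for (rec in suite) {
    expect_identical(rec$mixture$samples,
                     rec$ecg_clean$samples + rec$wander_true$samples +
                       rec$powerline_true$samples + rec$noise$samples)
  }
  peaks <- vapply(suite, function(r) max(abs(r$wander_true$samples)),
                  numeric(1))
  expect_gt(max(peaks), 1)        # at least one record beyond the R amplitude
  expect_gt(length(unique(round(peaks, 6))), 15)   # distinct draws
  suite2 <- lbnp_like_suite(20, seed = 1, duration = 10)
  expect_identical(suite, suite2)
})

test_that("record csv export round-trips through the reader", {
  rec <- synth_ecg(synth_spec(duration = 5, seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, f)
  sig <- read_signal(f)
  expect_equal(sig$fs, 500, tolerance = 1e-6)
  expect_equal(sig$samples, rec$mixture$samples, tolerance = 1e-12)
})
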