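test_that("configuration guards its invariants", {
  expect_error(lowess_config(span = 2, degree = 1), "degree")
  expect_error(lowess_config(robust_iters = -1), "robust_iters")
  expect_s3_class(lowess_config(21, 1, 0), "lowess_config")
})

test_that("a global line and a constant are reproduced exactly", {
  k <- 0:499
  line <- ecg_signal(0.37 * k - 12, 500)
  fit <- lowess_baseline(line, lowess_config(span = 101))
  expect_equal(fit$samples, line$samples, tolerance = 1e-9)
  cst <- ecg_signal(rep(2.5, 300), 500)
  expect_equal(lowess_baseline(cst, lowess_config(span = 51))$samples,
               rep(2.5, 300), tolerance = 1e-12)
})

test_that("smoother matches the brute-force weighted least-squares oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    y <- cumsum(rnorm(50)) + 3 * sin((1:50) / 5)
    y[seed * 7] <- y[seed * 7] + 15   # one gross outlier
    for (span in c(11, 21, 35)) {
      got <- lowess_baseline(ecg_signal(y, 500),
                             lowess_config(span = span))$samples
      want <- oracle_lowess(y, span, degree = 1L, robust_iters = 2L)
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("degree-2 local fits also match the oracle", {
  set.seed(7)
  y <- sin((1:60) / 6) + rnorm(60, sd = 0.1)
  got <- lowess_baseline(ecg_signal(y, 100),
                         lowess_config(span = 25, degree = 2))$samples
  expect_equal(got, oracle_lowess(y, 25, degree = 2L, robust_iters = 2L),
               tolerance = 1e-8)
})

test_that("bisquare iterations grant robustness to sparse large spikes", {
  set.seed(4)
  n <- 4000
  t <- (0:(n - 1)) / 500
  sig <- 1.5 * sin(2 * pi * 0.1 * t) + rnorm(n, sd = 0.05)
  spiked <- sig
  idx <- sample(n, n / 100)
  spiked[idx] <- spiked[idx] + 10 * 1.5 * sample(c(-1, 1), n / 100, TRUE)
  rel_change <- function(iters) {
    cfg <- lowess_config(span = 1001, robust_iters = iters)
    b0 <- lowess_baseline(ecg_signal(sig, 500), cfg)$samples
    b1 <- lowess_baseline(ecg_signal(spiked, 500), cfg)$samples
    sqrt(mean((b1 - b0)^2)) / sqrt(mean(b0^2))
  }
  expect_lt(rel_change(2), 0.05)
  expect_gte(rel_change(0), 0.05)
})

test_that("reference removal is an exact decomposition that flattens drift", {
  # pure linear drift: clean part goes to zero
  drift <- ecg_signal(0.002 * (0:1999), 500)
  res <- remove_baseline_reference(drift, lowess_config(span = 301))
  expect_lt(max(abs(res$clean$samples)), 1e-8)
  expect_equal(res$clean$samples + res$baseline$samples, drift$samples)
  # synthetic ECG: wander-band power drops by at least 80%
  rec <- synth_ecg(synth_spec(duration = 30, seed = 6))
  out <- remove_baseline_reference(rec$mixture)
  before <- band_power(rec$mixture$samples, 500, 0.03, 0.5)
  after <- band_power(out$clean$samples, 500, 0.03, 0.5)
  expect_lt(after / before, 0.2)
})

test_that("a span longer than the record is rejected", {
  expect_error(lowess_baseline(ecg_signal(rnorm(100), 500),
                               lowess_config(span = 1500)),
               "shorter than span")
})
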