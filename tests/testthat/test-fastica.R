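test_that("centering removes row means and records them", {
  X <- rbind(c(1, 2, 3), rep(4, 3), c(-1, 0, 1))
  cen <- ica_center(X)
  expect_equal(cen$centered[1, ], c(-1, 0, 1))
  expect_equal(cen$centered[2, ], rep(0, 3))
  expect_equal(cen$centered[3, ], c(-1, 0, 1))
  expect_equal(cen$means, c(2, 4, 0))
})

test_that("whitening of exactly orthogonal rows gives the diagonal transform", {
  # two orthogonal zero-mean rows with sample variances exactly 4 and 9
  n <- 400
  a <- rep(c(1, -1), n / 2)
  b <- rep(c(1, 1, -1, -1), n / 4)
  sa <- 2 * a / stats::sd(a)
  sb <- 3 * b / stats::sd(b)
  wh <- ica_whiten(rbind(sb, sa))
  expect_equal(unname(wh$model$transform), diag(c(1 / 3, 1 / 2)),
               tolerance = 1e-10)
})

test_that("whitened data has identity covariance", {
  set.seed(21)
  for (i in 1:5) {
    X <- matrix(rnorm(8 * 3000), 8) * runif(8, 0.5, 4)
    cen <- ica_center(X)
    wh <- ica_whiten(cen$centered)
    cv <- tcrossprod(wh$Z) / (ncol(wh$Z) - 1)
    expect_lt(max(abs(cv - diag(nrow(cv)))), 1e-8)
  }
})

test_that("degenerate inputs reduce rank or fail loudly", {
  expect_error(ica_whiten(matrix(0, 3, 100)), "rank 0")
  set.seed(5)
  x <- rnorm(1000)
  X <- rbind(x, x, rnorm(1000))
  cen <- ica_center(X)
  expect_warning(wh <- ica_whiten(cen$centered), "rank deficient")
  expect_equal(wh$model$rank, 2)
  expect_equal(nrow(wh$Z), 2)
})

test_that("contrast nonlinearities and derivatives match their closed forms", {
  expect_equal(ica_contrast(0, "g1", a1 = 1.5), list(g = 0, dg = 1.5))
  expect_equal(ica_contrast(2, "g3"), list(g = 8, dg = 12))
  expect_equal(ica_contrast(0, "g2"), list(g = 0, dg = 1))
  # derivatives agree with finite differences for all three kinds
  u <- seq(-2, 2, by = 0.5)
  h <- 1e-6
  for (kind in c("g1", "g2", "g3")) {
    ct <- ica_contrast(u, kind)
    fd <- (ica_contrast(u + h, kind)$g - ica_contrast(u - h, kind)$g) / (2 * h)
    expect_equal(ct$dg, fd, tolerance = 1e-6)
  }
  expect_error(ica_contrast(1, "g4"))
  expect_error(ica_contrast(1, "g1", a1 = 3), "a1")
})

test_that("one-unit iteration finds a dominant non-Gaussian direction", {
  set.seed(31)
  n <- 20000
  S <- rbind(ifelse(runif(n) < 0.5, 1, -1) * rexp(n), rnorm(n))
  A <- matrix(c(1, 0.6, -0.4, 1), 2)
  X <- A %*% S
  cen <- ica_center(X)
  wh <- ica_whiten(cen$centered)
  # true Laplace direction in whitened space
  w_true <- wh$model$transform %*% A[, 1]
  w_true <- w_true / sqrt(sum(w_true^2))
  w0 <- c(1, 1) / sqrt(2)
  res <- fastica_one_unit(wh$Z, w0, kind = "g1")
  expect_true(res$converged)
  angle <- acos(min(1, abs(sum(res$w * w_true)))) * 180 / pi
  expect_lt(angle, 2)
})

test_that("an exact fixed point converges in one iteration", {
  set.seed(32)
  Z <- matrix(rnorm(3000), 1)  # one whitened dimension: w = +-1 is fixed
  res <- fastica_one_unit(Z, 1, kind = "g1")
  expect_equal(res$n_iter, 1)
  expect_true(res$converged)
})

test_that("tighter tolerance never converges faster on the same start", {
  set.seed(33)
  n <- 4000
  S <- rbind(runif(n, -1, 1), ifelse(runif(n) < 0.5, 1, -1) * rexp(n))
  X <- matrix(c(1, 0.3, -0.5, 1), 2) %*% S
  wh <- ica_whiten(ica_center(X)$centered)
  w0 <- c(0.8, 0.6)
  it_loose <- fastica_one_unit(wh$Z, w0, tol = 1e-4)$n_iter
  it_tight <- fastica_one_unit(wh$Z, w0, tol = 1e-8)$n_iter
  expect_gte(it_tight, it_loose)
})

make_three_sources <- function(n, fs = 500, seed = 1) {
  set.seed(seed)
  t <- (0:(n - 1)) / fs
  rbind(sin(2 * pi * 0.3 * t),
        sign(sin(2 * pi * 7 * t)),
        ifelse(runif(n) < 0.5, 1, -1) * rexp(n) / sqrt(2))
}

test_that("three known sources are recovered up to sign and permutation", {
  for (seed in 1:3) {
    S <- make_three_sources(2000, seed = seed)
    set.seed(seed + 100)
    A <- matrix(rnorm(9), 3)
    model <- fastica(mixture_matrix(A %*% S, 500), n_components = 3,
                     seed = seed)
    expect_true(all(match_correlations(S, model$components) >= 0.95))
  }
})

test_that("full-rank mixing estimate reconstructs the centered data", {
  S <- make_three_sources(3000, seed = 9)
  set.seed(42)
  A <- matrix(rnorm(9), 3)
  X <- A %*% S
  model <- fastica(mixture_matrix(X, 500), n_components = 3, seed = 7)
  Xc <- ica_center(X)$centered
  rec <- model$mixing_estimate %*% model$components
  expect_lt(norm(rec - Xc, "F") / norm(Xc, "F"), 1e-6)
})

test_that("unmixing rows are unit norm and pairwise orthogonal", {
  S <- make_three_sources(3000, seed = 13)
  set.seed(14)
  model <- fastica(mixture_matrix(matrix(rnorm(9), 3) %*% S, 500), seed = 3)
  G <- model$unmixing %*% t(model$unmixing)
  expect_lt(max(abs(G - diag(3))), 1e-8)
})

test_that("identical inputs and seed give identical models", {
  S <- make_three_sources(2000, seed = 17)
  set.seed(18)
  X <- mixture_matrix(matrix(rnorm(9), 3) %*% S, 500)
  m1 <- fastica(X, n_components = 3, seed = 5)
  m2 <- fastica(X, n_components = 3, seed = 5)
  expect_identical(m1, m2)
})

test_that("component count beyond the whitened rank is refused", {
  S <- make_three_sources(2000, seed = 19)
  X <- mixture_matrix(matrix(rnorm(9), 3) %*% S, 500)
  expect_error(fastica(X, n_components = 4), "whitened rank")
})

test_that("negentropy vanishes for Gaussian data and ranks uniform above it", {
  set.seed(51)
  g <- rnorm(1e5)
  expect_lt(negentropy(g, "g1"), 1e-3)
  u <- runif(1e5)
  expect_gt(negentropy(u, "g2"), negentropy(g, "g2"))
  # nonnegative for arbitrary data
  expect_gte(negentropy(rexp(1000), "g3"), 0)
  expect_error(negentropy(rep(1, 100)), "zero-variance")
})
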