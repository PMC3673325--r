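# Brute-force robust locally weighted regression oracle: at every point it
# explicitly forms and solves the local weighted least-squares system, with
# the same window, tricube weight and bisquare robustness conventions as the
# production smoother.  Intentionally slow and direct.
oracle_lowess <- function(y, span, degree = 1L, robust_iters = 2L) {
  n <- length(y)
  one_pass <- function(rw) {
    fit <- numeric(n)
    for (i in seq_len(n)) {
      lo <- min(max(1L, i - (span - 1L) %/% 2L), n - span + 1L)
      hi <- lo + span - 1L
      k <- lo:hi
      dmax <- max(abs(k - i))
      u <- if (dmax > 0) abs(k - i) / dmax else rep(0, span)
      w <- (1 - u^3)^3
      w[u >= 1] <- 0
      w <- w * rw[k]
      X <- outer(k - i, 0:degree, "^")
      A <- t(X) %*% (w * X)
      b <- t(X) %*% (w * y[k])
      fit[i] <- solve(A, b)[1]
    }
    fit
  }
  rw <- rep(1, n)
  fit <- one_pass(rw)
  for (it in seq_len(robust_iters)) {
    r <- abs(y - fit)
    s <- 6 * stats::median(r)
    if (s <= 0) break
    u <- r / s
    rw <- ifelse(u < 1, (1 - u^2)^2, 0)
    fit <- one_pass(rw)
  }
  fit
}

# Independent reference ICA (scikit-learn FastICA) run through the system
# python; used only to cross-check component recovery in tests.  Returns a
# components x samples matrix.
sklearn_fastica <- function(X, n_components, seed = 0L) {
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  utils::write.table(t(X), infile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from sklearn.decomposition import FastICA\n",
    "x = np.loadtxt(%s, delimiter=',')\n",
    "ica = FastICA(n_components=%d, random_state=%d, max_iter=1000,\n",
    "              whiten='unit-variance')\n",
    "s = ica.fit_transform(x)\n",
    "np.savetxt(%s, s, delimiter=',')\n"),
    deparse(infile), n_components, seed, deparse(outfile))
  status <- system2("python", c("-c", shQuote(script)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("reference ICA (python/sklearn) failed")
  t(as.matrix(utils::read.table(outfile, sep = ",")))
}

# Best |correlation| match of each true source to any recovered component.
match_correlations <- function(sources, components) {
  apply(sources, 1, function(s) {
    max(abs(apply(components, 1, stats::cor, y = s)))
  })
}

# Fraction of spectral power below f_cut (two-sided, DC excluded) and the
# total power in a band -- small local helpers for spectral assertions.
band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- ((f >= f_lo & f <= f_hi) | (f >= fs - f_hi & f <= fs - f_lo)) & f > 0
  sum(p[sel])
}

quiet_pipeline <- function(signal, config, ...) {
  suppressWarnings(remove_baseline(signal, config, ...))
}
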