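#' Mixture matrix for blind source separation
#'
#' Container for a set of mixture signals observed at a common sampling rate:
#' one row per channel, one column per sample.  The ICA model assumes each
#' row is an unknown linear combination of statistically independent latent
#' sources.
#'
#' @param data Numeric matrix, `n_channels x n_samples`, with
#'   `n_samples > n_channels` and finite entries.
#' @param fs Sampling rate in Hz.
#' @return A `mixture_matrix` object.
#' @export
mixture_matrix <- function(data, fs) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("mixture contains non-finite entries",
                                  call. = FALSE)
  if (ncol(data) <= nrow(data)) {
    stop("need more samples than channels (got ",
         nrow(data), " channels x ", ncol(data), " samples)", call. = FALSE)
  }
  if (!is.finite(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  structure(list(data = data, fs = as.numeric(fs)), class = "mixture_matrix")
}

#' @export
print.mixture_matrix <- function(x, ...) {
  cat(sprintf("<mixture_matrix: %d channels x %d samples @ %g Hz>\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Center each channel of a mixture to zero mean
#'
#' @param X A [mixture_matrix()] or plain matrix (rows = channels).
#' @return List with `centered` (same shape, each row mean zero) and `means`
#'   (the per-channel means, recorded for reconstruction).
#' @export
ica_center <- function(X) {
  m <- if (inherits(X, "mixture_matrix")) X$data else as.matrix(X)
  mu <- rowMeans(m)
  list(centered = m - mu, means = mu)
}

#' Whiten centered data by eigendecomposition of the covariance
#'
#' Computes the sample covariance of the centered channels, its
#' eigendecomposition `D V D'`, and returns `Z = D V^{-1/2} D' Y` so that the
#' covariance of `Z` is the identity.  Eigenvalues below
#' `var_floor * max(eigenvalue)` are dropped with a warning (dimension
#' reduction to the numerical rank); in that case the transform is the
#' `rank x n_channels` PCA-whitening matrix `V_r^{-1/2} D_r'` rather than the
#' symmetric full-rank form.
#'
#' @param Y Centered data matrix (rows = channels).
#' @param var_floor Relative eigenvalue floor, default `1e-12`.
#' @param n_keep Optional dimension reduction: keep only the `n_keep` leading
#'   eigen-directions (PCA order), the standard preprocessing when fewer
#'   components than channels are wanted.  `NULL` keeps the full numerical
#'   rank.
#' @return List with `Z` (whitened data, `rank x n_samples`) and `model`, a
#'   `whitening_model` holding `transform`, `eigvecs`, `eigvals` and the rank.
#' @export
ica_whiten <- function(Y, var_floor = 1e-12, n_keep = NULL) {
  Y <- as.matrix(Y)
  ns <- ncol(Y)
  cv <- tcrossprod(Y) / (ns - 1)
  eg <- eigen(cv, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (max(lam) <= 0) stop("all-zero input: covariance has rank 0",
                          call. = FALSE)
  keep <- lam > var_floor * max(lam)
  r <- sum(keep)
  if (r < nrow(Y)) {
    warning(sprintf(
      "covariance is rank deficient: keeping %d of %d dimensions", r,
      nrow(Y)), call. = FALSE)
  }
  if (!is.null(n_keep)) r <- min(r, as.integer(n_keep))
  if (r < nrow(Y)) {
    K <- diag(1 / sqrt(lam[seq_len(r)]), r) %*%
      t(eg$vectors[, seq_len(r), drop = FALSE])
  } else {
    # symmetric (zero-phase) whitening D V^{-1/2} D'
    K <- eg$vectors %*% diag(1 / sqrt(lam), r) %*% t(eg$vectors)
  }
  model <- structure(list(transform = K, eigvecs = eg$vectors,
                          eigvals = lam, rank = r),
                     class = "whitening_model")
  list(Z = K %*% Y, model = model)
}

gauss_expectation <- function(G) {
  # E[G(v)] for v ~ N(0,1) by Gauss-Hermite quadrature
  q <- pracma::gaussHermite(64)
  sum(q$w * G(sqrt(2) * q$x)) / sqrt(pi)
}

#' Negentropy contrast functions
#'
#' The three standard contrast nonlinearities used by fixed-point ICA,
#' returned with their exact first derivatives:
#' `g1(y) = tanh(a1*y)`, `g2(y) = y*exp(-a2*y^2/2)`, `g3(y) = y^3`
#' (derivatives `a1*(1 - tanh(a1*y)^2)`, `(1 - a2*y^2)*exp(-a2*y^2/2)`,
#' `3*y^2`).  These are the derivatives of `G1 = log(cosh(a1*y))/a1`,
#' `G2 = -exp(-a2*y^2/2)/a2` and `G3 = y^4/4`.
#'
#' @param u Numeric vector at which to evaluate.
#' @param kind One of `"g1"`, `"g2"`, `"g3"`.
#' @param a1 Constant for `g1`, in `[1, 2]` (default 1).
#' @param a2 Constant for `g2`, near 1 (default 1).
#' @return List with `g` and `dg`, both the length of `u`.
#' @export
ica_contrast <- function(u, kind = c("g1", "g2", "g3"), a1 = 1, a2 = 1) {
  kind <- match.arg(kind)
  if (kind == "g1" && (a1 < 1 || a1 > 2)) {
    stop("`a1` must lie in [1, 2]", call. = FALSE)
  }
  switch(kind,
    g1 = {
      th <- tanh(a1 * u)
      list(g = th, dg = a1 * (1 - th^2))
    },
    g2 = {
      ex <- exp(-a2 * u^2 / 2)
      list(g = u * ex, dg = (1 - a2 * u^2) * ex)
    },
    g3 = list(g = u^3, dg = 3 * u^2))
}

contrast_G <- function(kind, a1 = 1, a2 = 1) {
  switch(kind,
    g1 = function(y) log(cosh(a1 * y)) / a1,
    g2 = function(y) -exp(-a2 * y^2 / 2) / a2,
    g3 = function(y) y^4 / 4,
    stop("unknown contrast kind `", kind, "`", call. = FALSE))
}

#' Negentropy approximation of a sample
#'
#' `J(y) = (E[G(y)] - E[G(v)])^2` where `v` is standard Gaussian and `G` the
#' integral of the chosen contrast ([ica_contrast()]).  The input is
#' standardized to zero mean and unit variance first; `E[G(v)]` is computed
#' by 64-node Gauss-Hermite quadrature, so the only sampling noise is in
#' `E[G(y)]`.  Nonnegative, and zero only for Gaussian data (asymptotically).
#'
#' @param y Numeric sample.
#' @param kind Contrast kind, see [ica_contrast()].
#' @param a1,a2 Contrast constants.
#' @return A nonnegative scalar.
#' @export
negentropy <- function(y, kind = c("g1", "g2", "g3"), a1 = 1, a2 = 1) {
  kind <- match.arg(kind)
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) {
    stop("negentropy undefined for zero-variance input", call. = FALSE)
  }
  y <- (y - mean(y)) / s
  G <- contrast_G(kind, a1, a2)
  (mean(G(y)) - gauss_expectation(G))^2
}

#' One-unit fixed-point ICA iteration
#'
#' Extracts a single unmixing direction from whitened data by the fixed-point
#' update `w' = E[z g(w'z)] - E[g'(w'z)] w` (expectations as sample means),
#' followed by Gram-Schmidt decorrelation against previously found rows
#' (deflation) and normalization.  Convergence is directional and
#' sign-invariant: the iteration stops when
#' `|<w_new, w_old>| > 1 - tol`.
#'
#' @param Z Whitened data matrix (rows = whitened channels).
#' @param w0 Initial vector, unit norm.
#' @param kind,a1,a2 Contrast selection, see [ica_contrast()].
#' @param tol Convergence tolerance on the direction cosine (default `1e-6`).
#' @param max_iter Iteration cap (default 500).
#' @param decorrelate_against Optional matrix whose rows are previously
#'   extracted unit vectors.
#' @return List with `w` (unit vector), `n_iter`, and `converged` (logical;
#'   hitting `max_iter` flags the result rather than raising an error).
#' @export
fastica_one_unit <- function(Z, w0, kind = c("g1", "g2", "g3"), a1 = 1,
                             a2 = 1, tol = 1e-6, max_iter = 500L,
                             decorrelate_against = NULL) {
  kind <- match.arg(kind)
  Z <- as.matrix(Z)
  w <- as.numeric(w0)
  if (abs(sqrt(sum(w^2)) - 1) > 1e-8) {
    stop("`w0` must have unit norm", call. = FALSE)
  }
  ns <- ncol(Z)
  W <- decorrelate_against
  deflate <- function(v) {
    if (!is.null(W) && nrow(W) > 0) v <- v - drop(crossprod(W, W %*% v))
    v
  }
  w <- deflate(w)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("initial vector lies in the span of previous components",
                       call. = FALSE)
  w <- w / nw
  for (it in seq_len(max_iter)) {
    u <- drop(crossprod(Z, w))          # w'z for every sample
    ct <- ica_contrast(u, kind, a1, a2)
    w_new <- drop(Z %*% ct$g) / ns - mean(ct$dg) * w
    w_new <- deflate(w_new)
    nw <- sqrt(sum(w_new^2))
    if (nw < 1e-12) {
      return(list(w = w, n_iter = it, converged = FALSE))
    }
    w_new <- w_new / nw
    if (abs(sum(w_new * w)) > 1 - tol) {
      return(list(w = w_new, n_iter = it, converged = TRUE))
    }
    w <- w_new
  }
  list(w = w, n_iter = max_iter, converged = FALSE)
}

#' Fixed-point independent component analysis
#'
#' Full ICA decomposition of a multichannel mixture: center, whiten by
#' eigendecomposition ([ica_whiten()]) -- reducing to the `n_components`
#' leading eigen-directions when fewer components than channels are
#' requested, the standard FastICA preprocessing -- then extract
#' `n_components` directions sequentially with the one-unit fixed-point rule
#' and deflation ([fastica_one_unit()]).  Initial vectors are seeded uniform random unit
#' vectors; a component that fails to converge is restarted up to 3 times
#' with fresh seeded directions before being flagged.  The result is fully
#' reproducible for a fixed `seed` and does not disturb the caller's RNG
#' state.
#'
#' Components are identifiable only up to sign, scale and permutation; each
#' recovered component has unit variance and the least-squares mixing
#' estimate maps components back to the centered channels
#' (`mixing_estimate %*% components` reconstructs them when
#' `n_components` equals the whitened rank).
#'
#' @param X A [mixture_matrix()] or plain matrix (rows = channels).
#' @param n_components Number of components to extract (defaults to the
#'   whitened rank; must not exceed it).
#' @param kind,a1,a2 Contrast selection, see [ica_contrast()]. `"g1"`
#'   (`tanh`) is the default general-purpose choice.
#' @param tol,max_iter Convergence controls for each one-unit iteration.
#' @param seed Integer seed for the random initial directions.
#' @param var_floor Passed to [ica_whiten()].
#' @return An `ica_model`: list with `whitening` (whitening model plus
#'   `means`), `unmixing` (`n_components x rank`, orthonormal rows in
#'   whitened space), `components` (`n_components x n_samples`),
#'   `mixing_estimate` (`n_channels x n_components`), `iterations`,
#'   `converged`, and `fs`.
#' @export
fastica <- function(X, n_components = NULL, kind = c("g1", "g2", "g3"),
                    a1 = 1, a2 = 1, tol = 1e-6, max_iter = 500L, seed = 1L,
                    var_floor = 1e-12) {
  kind <- match.arg(kind)
  fs <- if (inherits(X, "mixture_matrix")) X$fs else NA_real_
  cen <- ica_center(X)
  full <- ica_whiten(cen$centered, var_floor)
  rfull <- full$model$rank
  if (is.null(n_components)) n_components <- rfull
  if (n_components < 1 || n_components > rfull) {
    stop(sprintf("`n_components` must be in [1, %d] (whitened rank)", rfull),
         call. = FALSE)
  }
  # reduce to the leading n_components eigen-directions (standard FastICA
  # preprocessing): deflation then works inside the retained subspace
  wh <- if (n_components < rfull) {
    suppressWarnings(ica_whiten(cen$centered, var_floor,
                                n_keep = n_components))
  } else full
  r <- wh$model$rank
  Z <- wh$Z
  W <- matrix(0, 0, r)
  iters <- integer(n_components)
  conv <- logical(n_components)
  # private RNG stream: seeded, and the caller's RNG state is untouched
  rng <- local({
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    stats::runif(2 * 8 * n_components * r)  # pre-draw all candidate inits
  })
  draw <- function(i) {
    v <- rng[((i - 1) * r + 1):(i * r)] * 2 - 1
    v / sqrt(sum(v^2))
  }
  di <- 0L
  for (cidx in seq_len(n_components)) {
    best <- NULL
    for (attempt in 1:4) {
      di <- di + 1L
      w0 <- draw(di)
      res <- fastica_one_unit(Z, w0, kind, a1, a2, tol, max_iter,
                              decorrelate_against = if (nrow(W)) W else NULL)
      best <- res
      if (res$converged) break
    }
    if (!best$converged) {
      warning(sprintf("component %d did not converge in %d iterations",
                      cidx, max_iter), call. = FALSE)
    }
    W <- rbind(W, best$w)
    iters[cidx] <- best$n_iter
    conv[cidx] <- best$converged
  }
  rownames(W) <- NULL
  S <- W %*% Z
  # least-squares map from components back to the centered channels
  A <- t(qr.coef(qr(t(S)), t(cen$centered)))
  model <- structure(list(
    whitening = c(wh$model, list(means = cen$means)),
    unmixing = W,
    components = S,
    mixing_estimate = A,
    iterations = iters,
    converged = conv,
    fs = fs
  ), class = "ica_model")
  model
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("<ica_model: %d components x %d samples (%d/%d converged)>\n",
              nrow(x$components), ncol(x$components), sum(x$converged),
              length(x$converged)))
  invisible(x)
}
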