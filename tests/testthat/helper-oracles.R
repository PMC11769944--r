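# Independent oracles and small fixtures shared across the test files.
# Everything here is deliberately written as a separate route from the
# package implementation (per-point lm() fits, a textbook tridiagonal
# spline solve, a Krylov-subspace PLS, a direct Monte-Carlo sampler).

# --- brute-force Savitzky-Golay: per-point least-squares polynomial fit ----
oracle_sg <- function(x, window, order) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, min(i - half, n - window + 1L))
    hi <- lo + window - 1L
    idx <- lo:hi
    fit <- stats::lm(y ~ poly(t, order, raw = TRUE),
                     data = data.frame(t = idx, y = x[idx]))
    out[i] <- unname(stats::predict(fit, newdata = data.frame(t = i)))
  }
  out
}

# --- textbook natural cubic spline via the tridiagonal second-derivative
#     system, evaluated piecewise ---------------------------------------------
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  # solve for second derivatives m_1..m_n with natural conditions m1 = mn = 0
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  m <- solve(A, rhs)
  vapply(xout, function(xx) {
    i <- findInterval(xx, x, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    dx <- x[i + 1] - x[i]
    a <- (x[i + 1] - xx) / dx
    b <- (xx - x[i]) / dx
    a * y[i] + b * y[i + 1] +
      ((a^3 - a) * m[i] + (b^3 - b) * m[i + 1]) * dx^2 / 6
  }, numeric(1))
}

# --- PLS1 as regression on the Krylov subspace span{X'y, (X'X)X'y, ...} ----
# (algebraically equivalent to NIPALS PLS1; numerically independent route)
oracle_pls1 <- function(X, y, ncomp, Xtest) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  p <- ncol(Xc)
  K <- matrix(0, p, ncomp)
  v <- crossprod(Xc, yc)
  S <- crossprod(Xc)
  for (a in seq_len(ncomp)) {
    # Lanczos-style orthogonalization keeps the Krylov basis well conditioned
    if (a > 1) {
      for (j in seq_len(a - 1)) v <- v - K[, j] * sum(K[, j] * v)
      for (j in seq_len(a - 1)) v <- v - K[, j] * sum(K[, j] * v)
    }
    v <- v / sqrt(sum(v^2))
    K[, a] <- v
    v <- S %*% v
  }
  Tm <- Xc %*% K
  gamma <- qr.coef(qr(Tm), yc)
  gamma[is.na(gamma)] <- 0
  beta <- K %*% gamma
  as.vector(sweep(as.matrix(Xtest), 2L, attr(Xc, "scaled:center")) %*% beta) +
    mean(y)
}

# --- direct Monte-Carlo sampler of the uniform-Gumbel hard selection rule --
oracle_gumbel_freq <- function(logits, tau, shrink, n) {
  k <- length(logits)
  counts <- integer(k)
  for (i in seq_len(n)) {
    j <- which.max((logits + stats::runif(k) / shrink) / tau)
    counts[j] <- counts[j] + 1L
  }
  counts / n
}

# --- tiny fixtures ----------------------------------------------------------
tiny_model_config <- function(n_bands = 32L, dropout = 0) {
  model_config(n_bands = n_bands, profile = "reduced", gconv_channels = 8L,
               attn_channels = 4L, recurrent_hidden = 4L, head_hidden = 8L,
               dropout_rate = dropout)
}

tiny_synth_config <- function(n_bands = 32L) {
  synthetic_config(n_bands = n_bands)
}

make_toy_dataset <- function(n = 12, p = 6, seed = 1) {
  set.seed(seed)
  wl <- seq(400, 900, length.out = p)
  refl <- matrix(runif(n * p, 0.1, 0.9), n, p)
  spectral_dataset(wl, refl, sprintf("T%02d", seq_len(n)),
                   vcmax = runif(n, 40, 150), jmax = runif(n, 80, 250))
}
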