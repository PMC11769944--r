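# Spectral preprocessing: Savitzky-Golay smoothing, power compression, and
# natural-cubic-spline band resampling.

#' Preprocessing configuration
#'
#' @param sg_window odd Savitzky-Golay window length (default 21).
#' @param sg_order polynomial order of the local fit (default 2).
#' @param poc_beta power-compression exponent in (0, 2]; 1 = no compression,
#'   smaller values compress (amplify weak visible-range signal relative to
#'   the near-infrared plateau).
#' @param resample_bands optional target band count for spline resampling.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(sg_window = 21L, sg_order = 2L, poc_beta = 1,
                              resample_bands = NULL) {
  sg_window <- as.integer(sg_window)
  sg_order <- as.integer(sg_order)
  if (sg_window %% 2L == 0L) stop("sg_window must be odd")
  if (sg_window <= sg_order) stop("sg_window must exceed sg_order")
  if (poc_beta <= 0) stop("poc_beta must be > 0")
  structure(list(sg_window = sg_window, sg_order = sg_order,
                 poc_beta = poc_beta, resample_bands = resample_bands),
            class = "preprocess_config")
}

# projection row of the local least-squares polynomial fit: value of the
# order-`order` polynomial fitted over `window` points, evaluated at
# relative position `at` (0 = window centre offset from its first point).
sg_coefficients <- function(window, order, at) {
  x <- seq_len(window) - 1
  A <- outer(x, 0:order, "^")
  # row of A(A'A)^{-1}A' evaluating the fit at position `at`
  e <- at^(0:order)
  as.vector(e %*% solve(crossprod(A), t(A)))
}

#' Savitzky-Golay smoothing
#'
#' Sliding-window local least-squares polynomial smoother. Interior points
#' take the centred fit; the first and last half-windows are filled by
#' evaluating the boundary-window polynomial at their positions (no padding).
#'
#' @param reflectance numeric vector.
#' @param window odd window length, `window > order`, `window <= length`.
#' @param order polynomial order.
#' @return smoothed vector of the same length.
#' @export
savitzky_golay_smooth <- function(reflectance, window = 21L, order = 2L) {
  n <- length(reflectance)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= order) stop("window must exceed polynomial order")
  if (n < window) stop("signal shorter than window")
  half <- (window - 1L) %/% 2L
  centre <- sg_coefficients(window, order, half)
  out <- numeric(n)
  # interior: moving dot product with the centred projection row
  for (i in (half + 1L):(n - half)) {
    out[i] <- sum(centre * reflectance[(i - half):(i + half)])
  }
  # edges: one polynomial fitted to the boundary window, evaluated per point
  head_seg <- reflectance[1:window]
  tail_seg <- reflectance[(n - window + 1L):n]
  for (j in seq_len(half)) {
    out[j] <- sum(sg_coefficients(window, order, j - 1L) * head_seg)
    out[n - half + j] <- sum(sg_coefficients(window, order, half + j) * tail_seg)
  }
  out
}

#' Power compression
#'
#' Elementwise `|X|^beta`. `beta = 1` is the identity on nonnegative input;
#' `beta < 1` compresses the dynamic range (relative amplification of weak
#' visible-range reflectance), `beta > 1` inflates strong signal.
#'
#' @param reflectance numeric vector or matrix.
#' @param beta exponent, `> 0`.
#' @return transformed values, same shape.
#' @export
power_compress <- function(reflectance, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("beta must be a single positive number")
  if (beta == 1) return(abs(reflectance))  # bit-for-bit identity on X >= 0
  abs(reflectance)^beta
}

#' Resample a spectrum with a natural cubic spline
#'
#' Fits the natural cubic spline through all original (wavelength,
#' reflectance) points and evaluates it on `n_bands` equally spaced points
#' spanning the original range. Evaluating at an original knot returns the
#' original value.
#'
#' @param wavelengths strictly increasing nm grid.
#' @param reflectance numeric vector, same length.
#' @param n_bands target band count (>= 4).
#' @return list with `wavelengths` and `reflectance` on the new grid.
#' @export
resample_spectrum <- function(wavelengths, reflectance, n_bands) {
  if (n_bands < 4L) stop("n_bands must be >= 4")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (length(wavelengths) != length(reflectance))
    stop("wavelengths and reflectance lengths differ")
  grid <- seq(min(wavelengths), max(wavelengths), length.out = n_bands)
  out <- stats::spline(wavelengths, reflectance, xout = grid,
                       method = "natural")
  list(wavelengths = out$x, reflectance = out$y)
}

#' Apply the preprocessing chain to a dataset
#'
#' Order of operations: Savitzky-Golay smoothing, then power compression,
#' then (optionally) spline resampling to a new band count.
#'
#' @param dataset a [spectral_dataset()].
#' @param config a [preprocess_config()].
#' @return a new `spectral_dataset` (values clipped back to `[0, 1]`; the
#'   smoother can overshoot slightly near sharp features).
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  refl <- dataset$reflectance
  sm <- t(apply(refl, 1L, savitzky_golay_smooth,
                window = config$sg_window, order = config$sg_order))
  sm <- power_compress(sm, config$poc_beta)
  wl <- dataset$wavelengths
  if (!is.null(config$resample_bands)) {
    nb <- as.integer(config$resample_bands)
    res <- t(apply(sm, 1L, function(r)
      resample_spectrum(wl, r, nb)$reflectance))
    wl <- seq(min(wl), max(wl), length.out = nb)
    sm <- res
  }
  sm[sm < 0] <- 0
  sm[sm > 1] <- 1
  spectral_dataset(wl, sm, dataset$sample_id, dataset$vcmax, dataset$jmax,
                   source = paste0(dataset$source, "|preprocessed"))
}
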