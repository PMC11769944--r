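# Synthetic leaf reflectance generator with a planted spectral-index link.
#
# A simple parametric model (logistic red edge + Gaussian pigment troughs)
# rather than a radiative-transfer code: the tests need controllable ground
# truth, not physical fidelity. The planted trait link uses the discovered
# index form (R_nir + R_g)/(R_nir * R_r) at 800/550/670 nm, which makes the
# planted bands and the add-mul index form recoverable ground truth.

#' Synthetic leaf-spectrum configuration
#'
#' Defaults emulate the reported field statistics: 204 bands over
#' 400-1000 nm, absorption troughs at 410-450 and 660-690 nm, a reflection
#' peak at 500-550 nm, Vcmax in 5-195 with most mass in 60-100, Jmax in
#' 5-350 with mean Jmax/Vcmax about 1.93.
#'
#' @param n_bands number of bands (default 204).
#' @param lambda_min,lambda_max grid span in nm.
#' @param chl_range chlorophyll-proxy sampling range (arbitrary units).
#' @param nir_range near-infrared plateau reflectance range.
#' @param vis_base visible-range baseline reflectance.
#' @param blue_center,blue_width,blue_depth blue absorption trough (nm, nm,
#'   reflectance units per chlorophyll unit).
#' @param red_center,red_width,red_depth red absorption trough.
#' @param green_center,green_width green reflection peak position/width.
#' @param red_edge_width logistic red-edge width (nm).
#' @param noise_sd additive white-noise standard deviation.
#' @param smooth_noise_sd amplitude of the smooth correlated noise component.
#' @param planted_bands named vector of the planted sensitive bands (nm).
#' @param a0,a1 affine trait-link coefficients mapping the planted index to
#'   Vcmax (calibrated once so the defaults give mean near 85 and most mass
#'   in 60-100 micromol m-2 s-1).
#' @param vcmax_sd trait scatter around the planted link.
#' @param jmax_ratio mean Jmax/Vcmax ratio.
#' @param jmax_sd scatter of Jmax around `jmax_ratio * vcmax`.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_bands = 204L, lambda_min = 400, lambda_max = 1000,
                             chl_range = c(0.2, 1.0),
                             nir_range = c(0.40, 0.60),
                             vis_base = 0.14,
                             blue_center = 450, blue_width = 30, blue_depth = 0.10,
                             red_center = 670, red_width = 25, red_depth = 0.12,
                             green_center = 550, green_width = 20,
                             red_edge_width = 9,
                             noise_sd = 0.005, smooth_noise_sd = 0.004,
                             planted_bands = c(R_nir = 800, R_g = 550, R_r = 670),
                             a0 = 35.4, a1 = 2.04,
                             vcmax_sd = 6, jmax_ratio = 1.93, jmax_sd = 18) {
  structure(as.list(environment()), class = "synthetic_config")
}

synthetic_grid <- function(config) {
  seq(config$lambda_min, config$lambda_max, length.out = config$n_bands)
}

# deterministic spectral shape for given latent chlorophyll/NIR/red-edge
leaf_shape <- function(wl, chl, nir, edge_center, config) {
  s <- 1 / (1 + exp(-(wl - edge_center) / config$red_edge_width))
  base <- config$vis_base + (nir - config$vis_base) * s
  base +
    (0.10 - 0.06 * chl) * exp(-(wl - config$green_center)^2 / (2 * config$green_width^2)) -
    chl * config$blue_depth * exp(-(wl - config$blue_center)^2 / (2 * config$blue_width^2)) -
    chl * config$red_depth * exp(-(wl - config$red_center)^2 / (2 * config$red_width^2))
}

#' Generate one leaf-like reflectance spectrum
#'
#' Draws chlorophyll, NIR plateau and red-edge latents from the configured
#' ranges, builds the deterministic shape, and adds white plus smooth
#' correlated noise. Uses the current RNG state (seed with `set.seed()` or
#' use [generate_dataset()]).
#'
#' @param config a [synthetic_config()].
#' @param latents optional list(chl, nir) to fix the latent variables.
#' @return list with `wavelengths`, `reflectance` (clipped to (0.01, 0.95))
#'   and the drawn `latents`.
#' @export
generate_leaf_spectrum <- function(config = synthetic_config(), latents = NULL) {
  wl <- synthetic_grid(config)
  if (is.null(latents)) {
    latents <- list(chl = stats::runif(1, config$chl_range[1], config$chl_range[2]),
                    nir = stats::runif(1, config$nir_range[1], config$nir_range[2]))
  }
  edge_center <- 700 + 15 * latents$chl   # red edge shifts with chlorophyll
  r <- leaf_shape(wl, latents$chl, latents$nir, edge_center, config)
  if (config$noise_sd > 0) r <- r + stats::rnorm(length(wl), 0, config$noise_sd)
  if (config$smooth_noise_sd > 0) {
    ph <- stats::runif(2, 0, 2 * pi)
    amp <- stats::rnorm(2, 0, config$smooth_noise_sd)
    u <- (wl - config$lambda_min) / (config$lambda_max - config$lambda_min)
    r <- r + amp[1] * sin(2 * pi * u + ph[1]) + amp[2] * sin(4 * pi * u + ph[2])
  }
  r <- pmin(pmax(r, 0.01), 0.95)
  list(wavelengths = wl, reflectance = r, latents = latents)
}

planted_index <- function(wavelengths, reflectance, config) {
  nb <- function(l) which.min(abs(wavelengths - l))
  rn <- reflectance[nb(config$planted_bands[["R_nir"]])]
  rg <- reflectance[nb(config$planted_bands[["R_g"]])]
  rr <- reflectance[nb(config$planted_bands[["R_r"]])]
  (rn + rg) / (rn * rr)
}

#' Assign traits through the planted index link
#'
#' Computes the planted index `I* = (R_nir + R_g)/(R_nir * R_r)` at the
#' configured bands and sets `vcmax = a0 + a1 * I* + eps` (clipped to
#' [5, 195]) and `jmax = jmax_ratio * vcmax + eta` (clipped to [5, 350]).
#' Uses the current RNG state.
#'
#' @param spectrum output of [generate_leaf_spectrum()] (or a list with
#'   `wavelengths` and `reflectance`).
#' @param config a [synthetic_config()].
#' @return named numeric vector `c(vcmax, jmax)`.
#' @export
assign_traits <- function(spectrum, config = synthetic_config()) {
  istar <- planted_index(spectrum$wavelengths, spectrum$reflectance, config)
  vc <- config$a0 + config$a1 * istar +
    if (config$vcmax_sd > 0) stats::rnorm(1, 0, config$vcmax_sd) else 0
  vc <- min(max(vc, 5), 195)
  jm <- config$jmax_ratio * vc +
    if (config$jmax_sd > 0) stats::rnorm(1, 0, config$jmax_sd) else 0
  jm <- min(max(jm, 5), 350)
  c(vcmax = vc, jmax = jm)
}

#' Generate a labeled synthetic dataset
#'
#' @param n number of samples.
#' @param config a [synthetic_config()].
#' @param seed integer seed; the dataset is a pure function of
#'   `(n, config, seed)`.
#' @return a labeled [spectral_dataset()].
#' @export
generate_dataset <- function(n, config = synthetic_config(), seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  wl <- synthetic_grid(config)
  refl <- matrix(0, n, config$n_bands)
  vc <- jm <- numeric(n)
  for (i in seq_len(n)) {
    sp <- generate_leaf_spectrum(config)
    refl[i, ] <- sp$reflectance
    tr <- assign_traits(sp, config)
    vc[i] <- tr[["vcmax"]]
    jm[i] <- tr[["jmax"]]
  }
  spectral_dataset(wl, refl, sprintf("SYN%05d", seq_len(n)), vc, jm,
                   source = sprintf("synthetic(seed=%d)", seed))
}
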