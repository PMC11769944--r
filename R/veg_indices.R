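# Classic two-band vegetation indices and exhaustive band-pair correlation
# maps against the photosynthetic traits.
#
# Formulas (lambda_ref = 440 nm for mNDVI and SIPI):
#   SR    = R_l1 / R_l2
#   mNDVI = (R_ref - R_l1) / (R_ref + R_l2)
#   SIPI  = (R_ref - R_l1) / (R_ref - R_l2)

.INDEX_EPS <- 1e-9

#' Classic index formula descriptor
#'
#' @param name `"SR"`, `"mNDVI"` or `"SIPI"`.
#' @param lambda_ref reference (blue) wavelength in nm, used by mNDVI and
#'   SIPI; ignored for SR.
#' @return a `classic_index` list.
#' @export
classic_index <- function(name = c("SR", "mNDVI", "SIPI"), lambda_ref = 440) {
  name <- match.arg(name)
  structure(list(name = name,
                 lambda_ref = if (name == "SR") NA_real_ else lambda_ref),
            class = "classic_index")
}

nearest_band <- function(wavelengths, lambda) {
  if (lambda < min(wavelengths) || lambda > max(wavelengths))
    stop("wavelength ", lambda, " nm outside grid span [",
         min(wavelengths), ", ", max(wavelengths), "]")
  which.min(abs(wavelengths - lambda))
}

.index_values <- function(name, r1, r2, rref) {
  switch(name,
         SR = r1 / (r2 + .INDEX_EPS),
         mNDVI = (rref - r1) / (rref + r2 + .INDEX_EPS),
         SIPI = (rref - r1) / (rref - r2 + .INDEX_EPS))
}

#' Evaluate a classic two-band index on one sample
#'
#' Wavelengths are resolved to the nearest grid band.
#'
#' @param sample a [spectral_sample()] (or any list with `wavelengths` and
#'   `reflectance`).
#' @param formula a [classic_index()].
#' @param lambda1,lambda2 band wavelengths in nm.
#' @return scalar index value.
#' @export
evaluate_classic_index <- function(sample, formula, lambda1, lambda2) {
  wl <- sample$wavelengths
  r <- sample$reflectance
  i1 <- nearest_band(wl, lambda1)
  i2 <- nearest_band(wl, lambda2)
  rref <- if (formula$name == "SR") NA_real_ else r[nearest_band(wl, formula$lambda_ref)]
  .index_values(formula$name, r[i1], r[i2], rref)
}

#' Exhaustive band-pair correlation map
#'
#' For every `(lambda1, lambda2)` pair on the full grid, computes the
#' correlation between the index values across labeled samples and the trait.
#' Cells where the index is constant across samples are `NaN`.
#'
#' @param dataset a labeled [spectral_dataset()].
#' @param trait `"vcmax"` or `"jmax"`.
#' @param formula a [classic_index()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a `correlation_map`: list with `lambda1_grid`, `lambda2_grid`,
#'   `rho` (matrix, rows = lambda1), `trait`, `formula`.
#' @export
correlation_map <- function(dataset, trait = c("vcmax", "jmax"),
                            formula = classic_index("SR"),
                            method = c("pearson", "spearman")) {
  trait <- match.arg(trait)
  method <- match.arg(method)
  y <- dataset[[trait]]
  keep <- !is.na(y)
  if (sum(keep) < 3L) stop("correlation_map needs >= 3 labeled samples")
  y <- y[keep]
  X <- dataset$reflectance[keep, , drop = FALSE]
  if (method == "spearman") {
    rk <- function(m) apply(m, 2L, rank)
    y <- rank(y)
  }
  p <- ncol(X)
  wl <- dataset$wavelengths
  rref <- if (formula$name == "SR") NULL
          else X[, nearest_band(wl, formula$lambda_ref)]
  rho <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) {
    M <- switch(formula$name,
                SR = X / (X[, j] + .INDEX_EPS),
                mNDVI = (rref - X) / (rref + X[, j] + .INDEX_EPS),
                SIPI = (rref - X) / (rref - X[, j] + .INDEX_EPS))
    if (method == "spearman") M <- rk(M)
    sds <- apply(M, 2L, stats::sd)
    ok <- is.finite(sds) & sds > 0
    if (stats::sd(y) > 0 && any(ok)) {
      rho[ok, j] <- suppressWarnings(as.vector(stats::cor(M[, ok, drop = FALSE], y)))
    }
  }
  structure(list(lambda1_grid = wl, lambda2_grid = wl, rho = rho,
                 trait = trait, formula = formula$name, method = method),
            class = "correlation_map")
}

#' Strongest band pairs of a correlation map
#'
#' @param map a [correlation_map()].
#' @param k number of pairs to return.
#' @return data.frame with `lambda1`, `lambda2`, `rho`, sorted by `|rho|`
#'   descending (ties broken by ascending `lambda1` then `lambda2`). If fewer
#'   than `k` finite cells exist the list is truncated with a warning.
#' @export
best_band_pairs <- function(map, k = 10L) {
  fin <- which(is.finite(map$rho), arr.ind = TRUE)
  if (nrow(fin) == 0L) stop("correlation map has no finite cells")
  if (nrow(fin) < k) {
    warning("only ", nrow(fin), " finite cells; truncating to that many")
    k <- nrow(fin)
  }
  vals <- map$rho[fin]
  l1 <- map$lambda1_grid[fin[, 1L]]
  l2 <- map$lambda2_grid[fin[, 2L]]
  o <- order(-abs(vals), l1, l2)
  utils::head(data.frame(lambda1 = l1[o], lambda2 = l2[o], rho = vals[o]), k)
}

#' Write a correlation map and its best pairs to disk
#'
#' The map is a CSV matrix (rows lambda1, columns lambda2) plus a JSON
#' summary of the strongest pairs.
#'
#' @param map a [correlation_map()].
#' @param csv_path output CSV path.
#' @param json_path optional JSON path for the [best_band_pairs()] summary.
#' @param k pairs in the summary.
#' @return `csv_path` invisibly.
#' @export
write_correlation_map <- function(map, csv_path, json_path = NULL, k = 10L) {
  m <- map$rho
  rownames(m) <- map$lambda1_grid
  colnames(m) <- map$lambda2_grid
  utils::write.csv(m, csv_path, row.names = TRUE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(trait = map$trait, formula = map$formula,
                              best = best_band_pairs(map, k)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
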