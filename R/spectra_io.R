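# Spectral dataset container and CSV input/output.
#
# External formats: a spectra CSV with a `sample_id` column plus numeric band
# columns named `R_<wavelength_nm>`, and a traits CSV with columns
# `sample_id, vcmax, jmax` (micromol m^-2 s^-1). UTF-8, '.' decimal separator.

#' Construct a spectral dataset
#'
#' All samples share one strictly increasing wavelength grid. Reflectance
#' outside `[0, 1]` is clipped on construction with a warning (sensor noise
#' can slightly exceed physical bounds); non-finite values are an error.
#'
#' @param wavelengths numeric vector of band centres in nm, strictly
#'   increasing.
#' @param reflectance numeric matrix, samples x bands.
#' @param sample_id character vector of sample identifiers.
#' @param vcmax,jmax optional numeric trait vectors (NA = unlabeled).
#' @param source free-text provenance tag.
#' @return an object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(wavelengths, reflectance, sample_id = NULL,
                             vcmax = NULL, jmax = NULL, source = "memory") {
  reflectance <- as.matrix(reflectance)
  n <- nrow(reflectance)
  if (length(wavelengths) != ncol(reflectance))
    stop("wavelength grid length does not match reflectance columns")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(reflectance)))
    stop("reflectance contains non-finite values")
  if (any(reflectance < 0 | reflectance > 1)) {
    warning("reflectance outside [0, 1] clipped on load")
    reflectance[reflectance < 0] <- 0
    reflectance[reflectance > 1] <- 1
  }
  if (is.null(sample_id)) sample_id <- sprintf("S%04d", seq_len(n))
  if (is.null(vcmax)) vcmax <- rep(NA_real_, n)
  if (is.null(jmax)) jmax <- rep(NA_real_, n)
  stopifnot(length(sample_id) == n, length(vcmax) == n, length(jmax) == n)
  rownames(reflectance) <- sample_id
  structure(list(
    wavelengths = as.numeric(wavelengths),
    reflectance = reflectance,
    sample_id = as.character(sample_id),
    vcmax = as.numeric(vcmax),
    jmax = as.numeric(jmax),
    source = source
  ), class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d samples x %d bands (%.1f-%.1f nm), %d labeled [%s]\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              sum(!is.na(x$vcmax)), x$source))
  invisible(x)
}

#' @export
length.spectral_dataset <- function(x) nrow(x$reflectance)

#' Subset a spectral dataset by sample
#' @param x a `spectral_dataset`.
#' @param i sample index vector.
#' @param ... unused.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  spectral_dataset(x$wavelengths, x$reflectance[i, , drop = FALSE],
                   x$sample_id[i], x$vcmax[i], x$jmax[i], x$source)
}

#' Reflectance matrix of a dataset (samples x bands)
#' @param x a `spectral_dataset` or a plain matrix (returned as-is).
#' @return numeric matrix.
#' @export
reflectance_matrix <- function(x) {
  if (inherits(x, "spectral_dataset")) x$reflectance else as.matrix(x)
}

#' Extract one sample
#' @param dataset a `spectral_dataset`.
#' @param i sample index or id.
#' @return list with `sample_id`, `wavelengths`, `reflectance`, `vcmax`,
#'   `jmax` (the per-leaf record).
#' @export
spectral_sample <- function(dataset, i) {
  if (is.character(i)) i <- match(i, dataset$sample_id)
  list(sample_id = dataset$sample_id[i],
       wavelengths = dataset$wavelengths,
       reflectance = dataset$reflectance[i, ],
       vcmax = dataset$vcmax[i], jmax = dataset$jmax[i])
}

band_names <- function(wavelengths) sprintf("R_%g", wavelengths)

#' Read spectra (and optional traits) from CSV
#'
#' The spectra file must contain a `sample_id` column and band columns named
#' `R_<wavelength_nm>`; every row therefore shares one grid by construction,
#' and files whose band columns disagree with that convention are rejected.
#' Samples missing from the traits file stay unlabeled.
#'
#' @param spectra_path path to the spectra CSV.
#' @param traits_path optional path to the traits CSV
#'   (`sample_id,vcmax,jmax`).
#' @return a [spectral_dataset()].
#' @export
read_spectra_csv <- function(spectra_path, traits_path = NULL) {
  df <- utils::read.csv(spectra_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("spectra CSV must have a 'sample_id' column")
  bandcols <- setdiff(names(df), "sample_id")
  if (!all(grepl("^R_[0-9.]+$", bandcols)))
    stop("band columns must be named R_<wavelength_nm>; found: ",
         paste(utils::head(setdiff(bandcols, grep("^R_[0-9.]+$", bandcols,
                                                  value = TRUE)), 3),
               collapse = ", "))
  wl <- as.numeric(sub("^R_", "", bandcols))
  o <- order(wl)
  wl <- wl[o]; bandcols <- bandcols[o]
  refl <- as.matrix(df[, bandcols, drop = FALSE])
  if (!is.numeric(refl)) stop("non-numeric reflectance values in ", spectra_path)
  storage.mode(refl) <- "double"
  if (any(!is.finite(refl))) stop("non-numeric reflectance values in ", spectra_path)
  vc <- jm <- rep(NA_real_, nrow(refl))
  if (!is.null(traits_path)) {
    tr <- utils::read.csv(traits_path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "vcmax", "jmax") %in% names(tr)))
      stop("traits CSV must have columns sample_id, vcmax, jmax")
    idx <- match(df$sample_id, tr$sample_id)
    vc <- tr$vcmax[idx]
    jm <- tr$jmax[idx]
  }
  spectral_dataset(wl, refl, df$sample_id, vc, jm, source = spectra_path)
}

#' Write a dataset as the standard spectra/traits CSV pair
#'
#' @param dataset a [spectral_dataset()].
#' @param spectra_path output path for the spectra CSV.
#' @param traits_path optional output path for the traits CSV; labeled
#'   samples only.
#' @return `spectra_path`, invisibly.
#' @export
write_spectra_csv <- function(dataset, spectra_path, traits_path = NULL) {
  df <- data.frame(sample_id = dataset$sample_id, stringsAsFactors = FALSE)
  # %.17g keeps the round-trip through text exact (bit-for-bit reflectance)
  refl <- apply(dataset$reflectance, 2L, function(x) sprintf("%.17g", x))
  refl <- matrix(refl, nrow = length(dataset$sample_id))
  colnames(refl) <- band_names(dataset$wavelengths)
  df <- cbind(df, as.data.frame(refl, optional = TRUE))
  utils::write.csv(df, spectra_path, row.names = FALSE, quote = FALSE)
  if (!is.null(traits_path)) {
    lab <- !is.na(dataset$vcmax) | !is.na(dataset$jmax)
    utils::write.csv(data.frame(sample_id = dataset$sample_id[lab],
                                vcmax = dataset$vcmax[lab],
                                jmax = dataset$jmax[lab]),
                     traits_path, row.names = FALSE, quote = FALSE)
  }
  invisible(spectra_path)
}
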