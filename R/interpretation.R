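# Interpretation of a trained band-selecting model: sensitive-band
# histograms, index-form importances, the discovered index formula, and
# band-subset export for filtered-band validation.

#' Extract hard band selections from a trained model
#'
#' Runs an evaluation-mode, noise-free forward pass (hard argmax per head per
#' channel) on a probe spectrum and returns every selection. With the
#' reference configuration this is 10 heads x 64 channels = 640 selections.
#' The probe defaults to the mean training spectrum stored by
#' [train_model()].
#'
#' @param model a trained [indexfindnet()] model.
#' @param probe optional probe spectrum (length `n_bands`); defaults to the
#'   stored mean training spectrum.
#' @return data.frame with head, branch, role, channel, band_index,
#'   wavelength.
#' @export
extract_band_selections <- function(model, probe = NULL) {
  if (!isTRUE(model$trained) && is.null(probe))
    stop("model is untrained and no probe spectrum was given")
  if (is.null(probe)) probe <- model$probe
  if (is.null(probe)) stop("no probe spectrum available; pass `probe`")
  fw <- model_forward(model, probe, hard = TRUE, noise = FALSE)
  fw$selections
}

#' Band-frequency sensitivity report
#'
#' Histogram of selection counts per wavelength across all heads and
#' channels; the top-k wavelengths are ranked by descending count with ties
#' broken by ascending wavelength. Also reports the modal wavelength per role
#' per branch (the discovered index formula).
#'
#' @param selections data.frame from [extract_band_selections()].
#' @param k number of top wavelengths (default 8).
#' @return a `sensitivity_report`: list with `band_counts` (data.frame
#'   wavelength/count), `top_k` (wavelengths), `discovered_formula`
#'   (data.frame branch/role/wavelength).
#' @export
band_frequency_report <- function(selections, k = 8L) {
  if (nrow(selections) == 0L) stop("no selections")
  key <- if (all(is.na(selections$wavelength))) "band_index" else "wavelength"
  tab <- stats::aggregate(list(count = selections$head),
                          by = list(wavelength = selections[[key]]), length)
  tab <- tab[order(-tab$count, tab$wavelength), ]
  rownames(tab) <- NULL
  modal <- do.call(rbind, lapply(split(selections,
                                       list(selections$branch, selections$role),
                                       drop = TRUE), function(d) {
    t2 <- sort(table(d[[key]]), decreasing = TRUE)
    data.frame(branch = d$branch[1L], role = d$role[1L],
               wavelength = as.numeric(names(t2)[1L]),
               count = as.integer(t2[1L]))
  }))
  rownames(modal) <- NULL
  modal <- modal[order(modal$branch, modal$role), ]
  structure(list(band_counts = tab,
                 top_k = utils::head(tab$wavelength, k),
                 k = k,
                 n_selections = nrow(selections),
                 discovered_formula = modal),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity report:", x$n_selections, "selections\n")
  cat("top", x$k, "wavelengths:", paste(round(x$top_k, 1), collapse = ", "),
      "\n")
  invisible(x)
}

#' Index-form importance scores
#'
#' Mean softmax gate score per index form over all samples of an evaluation
#' set and all feature positions; the three scores sum to 1. Form order
#' matches the branch definitions: double_diff, add_mul, ratio.
#'
#' @param model a trained [indexfindnet()] model.
#' @param dataset a [spectral_dataset()] (evaluation set).
#' @return named numeric 3-vector summing to 1.
#' @export
index_form_importance <- function(model, dataset) {
  refl <- t(reflectance_matrix(dataset))
  if (ncol(refl) == 0L) stop("empty evaluation set")
  fw <- model_forward(model, refl, hard = TRUE, noise = FALSE)
  fw$form_scores
}

#' Export a band subset of a dataset
#'
#' Keeps only the requested wavelengths (nearest grid band with a warning if
#' off-grid), preserving sample order and the given wavelength order. The
#' result is directly usable as baseline-model input for filtered-band
#' validation.
#'
#' @param dataset a [spectral_dataset()].
#' @param wavelengths wavelengths (nm) to keep, in the desired order.
#' @return a `band_subset` object (fields like a `spectral_dataset`; the
#'   reflectance matrix is samples x k).
#' @export
export_band_subset <- function(dataset, wavelengths) {
  idx <- vapply(wavelengths, function(l) {
    j <- which.min(abs(dataset$wavelengths - l))
    if (abs(dataset$wavelengths[j] - l) > 1e-9)
      warning("wavelength ", l, " nm off-grid; using nearest band ",
              signif(dataset$wavelengths[j], 6), " nm")
    j
  }, integer(1))
  structure(list(
    wavelengths = dataset$wavelengths[idx],
    reflectance = dataset$reflectance[, idx, drop = FALSE],
    sample_id = dataset$sample_id,
    vcmax = dataset$vcmax,
    jmax = dataset$jmax,
    source = paste0(dataset$source, "|subset")
  ), class = c("band_subset", "spectral_dataset"))
}

#' Write a sensitivity report to disk
#'
#' JSON for the full report plus a histogram CSV (wavelength, count).
#'
#' @param report a [band_frequency_report()] result.
#' @param json_path output JSON path.
#' @param csv_path optional histogram CSV path.
#' @param form_scores optional [index_form_importance()] vector to embed.
#' @return `json_path` invisibly.
#' @export
write_sensitivity_report <- function(report, json_path, csv_path = NULL,
                                     form_scores = NULL) {
  out <- list(top_k = report$top_k, n_selections = report$n_selections,
              discovered_formula = report$discovered_formula,
              band_counts = report$band_counts)
  if (!is.null(form_scores)) out$form_scores <- as.list(form_scores)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path))
    utils::write.csv(report$band_counts, csv_path, row.names = FALSE)
  invisible(json_path)
}
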