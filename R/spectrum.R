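#' Build or validate a spectrum table
#'
#' A spectrum is an ordinary tibble with a strictly increasing `wavenumber`
#' column (cm^-1) and an `intensity` column (arbitrary units). Synthetic
#' spectra additionally carry `true_baseline` and `true_signal` columns, so
#' that for noise-free spectra `intensity == true_signal + true_baseline`
#' exactly. Shape labels and noise levels travel in the `shape_label` and
#' `snr` attributes.
#'
#' @param data A data frame with at least `wavenumber` and `intensity`
#'   columns, or a two-column numeric data frame (taken as wavenumber,
#'   intensity in order).
#' @param shape_label Optional shape code, e.g. `"B&E"`.
#' @param snr Optional realized signal-to-noise ratio.
#'
#' @return A tibble with the spectrum columns, carrying `shape_label` and
#'   `snr` attributes when supplied.
#' @export
#' @examples
#' as_spectrum(data.frame(wavenumber = 1:10, intensity = rnorm(10)))
as_spectrum <- function(data, shape_label = NULL, snr = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with wavenumber and intensity columns.")
  }
  nm <- names(data)
  if (!all(c("wavenumber", "intensity") %in% nm)) {
    if (ncol(data) >= 2 && is.numeric(data[[1]]) && is.numeric(data[[2]])) {
      names(data)[1:2] <- c("wavenumber", "intensity")
    } else {
      abort("`data` must have `wavenumber` and `intensity` columns.")
    }
  }
  out <- as_tibble(data)
  check_spectrum(out)
  if (!is.null(shape_label)) attr(out, "shape_label") <- shape_label
  if (!is.null(snr)) attr(out, "snr") <- snr
  out
}

check_spectrum <- function(data, need_truth = FALSE, min_n = 8L) {
  wn <- data$wavenumber
  y <- data$intensity
  if (length(wn) < min_n) {
    abort(paste0("spectrum must have at least ", min_n, " points."))
  }
  if (any(!is.finite(wn)) || any(diff(wn) <= 0)) {
    abort("`wavenumber` must be finite and strictly increasing.")
  }
  if (any(!is.finite(y))) {
    abort("`intensity` must be finite (no NA/NaN/Inf).")
  }
  if (need_truth && is.null(data[["true_baseline"]])) {
    abort("this operation needs a known true baseline (`true_baseline` column).")
  }
  invisible(data)
}

spectrum_shape <- function(data) {
  lbl <- attr(data, "shape_label")
  if (is.null(lbl)) NA_character_ else lbl
}
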