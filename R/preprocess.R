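#' Savitzky–Golay denoising
#'
#' Local least-squares polynomial smoothing of the intensities. The
#' defaults (window 15, order 2) are the conditioning step used before
#' parameter prediction on measured spectra; an order-2 filter reproduces
#' any global quadratic exactly, edges included.
#'
#' @param data Spectrum tibble.
#' @param window_length Odd window size in channels (default 15).
#' @param poly_order Polynomial order, `< window_length` (default 2).
#' @return The spectrum with smoothed `intensity`; the `denoised`
#'   attribute records the filter settings.
#' @export
#' @examples
#' sp <- add_noise(generate_spectrum("D&E", seed = 1), snr = 20, seed = 2)
#' smoother <- savgol_denoise(sp)
savgol_denoise <- function(data, window_length = 15L, poly_order = 2L) {
  data <- as_spectrum(data)
  window_length <- as.integer(window_length)
  poly_order <- as.integer(poly_order)
  if (window_length %% 2L == 0L) abort("`window_length` must be odd.")
  if (poly_order >= window_length) {
    abort("`poly_order` must be smaller than `window_length`.")
  }
  if (nrow(data) < window_length) {
    abort("spectrum shorter than the filter window.")
  }
  out <- data
  out$intensity <- as.numeric(
    signal::sgolayfilt(data$intensity, p = poly_order, n = window_length))
  attr(out, "shape_label") <- attr(data, "shape_label")
  attr(out, "snr") <- attr(data, "snr")
  attr(out, "denoised") <- c(window_length = window_length,
                             poly_order = poly_order)
  out
}

#' Estimate the signal-to-noise ratio of a spectrum
#'
#' Model-free SNR proxy matching the generator's convention
#' (peak signal amplitude over noise standard deviation). The noise scale
#' is estimated from second differences, `sd(diff(y, differences = 2)) /
#' sqrt(6)`, which annihilates smooth structure; the signal amplitude is
#' the maximum of the Savitzky–Golay-smoothed, baseline-subtracted
#' spectrum (airPLS baseline at `lambda = 1e5, p = 2`). Nearly noise-free
#' spectra are capped at the sentinel value `1e6`.
#'
#' @param data Spectrum tibble with `n >= 32`.
#' @param cap Sentinel returned when the noise proxy underflows.
#' @return Estimated SNR (scalar).
#' @export
#' @examples
#' sp <- add_noise(generate_spectrum("D&E", seed = 1), snr = 20, seed = 2)
#' estimate_snr(sp)
estimate_snr <- function(data, cap = 1e6) {
  data <- as_spectrum(data)
  y <- data$intensity
  if (length(y) < 32) abort("need at least 32 channels to estimate SNR.")
  if (max(y) - min(y) < .Machine$double.eps) {
    abort("SNR undefined for a constant spectrum.")
  }
  noise_sd <- sd(diff(y, differences = 2)) / sqrt(6)
  smoothed <- data
  smoothed$intensity <- as.numeric(signal::sgolayfilt(y, p = 2, n = 15))
  fit <- airpls(smoothed, lambda = 1e5, tau = 1e-3, p = 2L)
  amp <- max(smoothed$intensity - fit$data$baseline)
  if (noise_sd <= amp / cap) return(cap)
  min(amp / noise_sd, cap)
}

#' Resample a spectrum onto a target wavenumber grid
#'
#' Linear interpolation of all numeric channels (`intensity` and, when
#' present, `true_baseline`/`true_signal`). Extrapolation is refused: the
#' target grid must lie inside the source range.
#'
#' @param data Spectrum tibble.
#' @param target_grid Strictly increasing wavenumber vector.
#' @return The resampled spectrum tibble.
#' @export
#' @examples
#' sp <- generate_spectrum("D&E", seed = 1)
#' resample_to_grid(sp, seq(500, 1900, by = 2))
resample_to_grid <- function(data, target_grid) {
  data <- as_spectrum(data)
  if (any(diff(target_grid) <= 0)) {
    abort("`target_grid` must be strictly increasing.")
  }
  rng <- range(data$wavenumber)
  if (min(target_grid) < rng[1] || max(target_grid) > rng[2]) {
    abort("`target_grid` extends beyond the source range (no extrapolation).")
  }
  cols <- intersect(c("intensity", "true_baseline", "true_signal"),
                    names(data))
  out <- tibble(wavenumber = as.numeric(target_grid))
  for (cl in cols) {
    out[[cl]] <- approx(data$wavenumber, data[[cl]], xout = target_grid)$y
  }
  attr(out, "shape_label") <- attr(data, "shape_label")
  attr(out, "snr") <- attr(data, "snr")
  out
}
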