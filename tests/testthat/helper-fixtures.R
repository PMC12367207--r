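# Shared fixtures: small deterministic spectra built in code.

toy_grid <- function(n = 256) seq(400, 2000, length.out = n)

# One narrow Gaussian peak on a straight-line baseline.
toy_peak_spectrum <- function(n = 256, slope = 5e-4, intercept = 0.5,
                              center = 1100, fwhm = 40, height = 1) {
  wn <- toy_grid(n)
  base <- intercept + slope * (wn - wn[1])
  sig <- height * exp(-(wn - center)^2 / (2 * (fwhm / 2.355)^2))
  tibble::tibble(wavenumber = wn, intensity = sig + base,
                 true_baseline = base, true_signal = sig)
}

# Pure nonnegative peaks, zero baseline.
toy_pure_peaks <- function(n = 256) {
  wn <- toy_grid(n)
  sig <- exp(-(wn - 800)^2 / (2 * 15^2)) + 0.6 * exp(-(wn - 1500)^2 / (2 * 20^2))
  tibble::tibble(wavenumber = wn, intensity = sig,
                 true_baseline = rep(0, n), true_signal = sig)
}

expect_spectrum_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$wavenumber, b$wavenumber, tolerance = tol)
  expect_equal(a$intensity, b$intensity, tolerance = tol)
}
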