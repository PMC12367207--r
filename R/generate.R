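#' Shape codes of the synthetic SERS library
#'
#' The generator covers three peak families — broad (B), convoluted (C),
#' distinct (D) — crossed with four baseline families — exponential (E),
#' Gaussian (G), fifth-order polynomial (P), sigmoidal (S). A shape code
#' joins the two with `&`, e.g. `"B&E"` is a broad-peak spectrum on an
#' exponential baseline. `compound_shape_codes()` lists the twelve compound
#' shapes used for robustness checks: the four equal-weight baseline sums
#' (E+P, E+G, E+S, G+S) under C and D peaks, plus the compound B+C peak on
#' each single baseline.
#'
#' @return A character vector of shape codes.
#' @export
#' @examples
#' shape_codes()
shape_codes <- function() {
  as.vector(outer(c("B", "C", "D"), c("E", "G", "P", "S"),
                  function(a, b) paste0(a, "&", b)))
}

#' @rdname shape_codes
#' @export
compound_shape_codes <- function() {
  c(as.vector(outer(c("C", "D"), c("E+P", "E+G", "E+S", "G+S"),
                    function(a, b) paste0(a, "&", b))),
    paste0("B+C&", c("E", "G", "P", "S")))
}

split_shape_code <- function(shape) {
  parts <- strsplit(shape, "&", fixed = TRUE)[[1]]
  if (length(parts) != 2) abort(paste0("malformed shape code: '", shape, "'"))
  peaks <- strsplit(parts[1], "+", fixed = TRUE)[[1]]
  bases <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
  if (!all(peaks %in% c("B", "C", "D"))) {
    abort(paste0("unknown peak type in '", shape, "' (expected B, C or D)"))
  }
  if (!all(bases %in% c("E", "G", "P", "S"))) {
    abort(paste0("unknown baseline type in '", shape, "' (expected E, G, P or S)"))
  }
  list(peaks = peaks, baselines = bases)
}

# Amplitude convention: broad-peak (B) spectra live on a ~100x larger
# intensity scale than C/D spectra, reproducing the scale contrast between
# peak families in measured SERS data.
default_amplitude_scale <- function(peaks) {
  if ("B" %in% peaks) 100 else 1
}

#' Generate a synthetic baseline
#'
#' Draws one baseline of the requested family on the given wavenumber grid.
#' Families: `E` exponential decay `a * exp(-b (nu - nu_0))`; `G` wide
#' Gaussian `a * exp(-(nu - mu)^2 / 2 sigma^2)` with `sigma` comparable to
#' the grid span; `P` fifth-order polynomial rescaled into `[0, a]`;
#' `S` sigmoid `a / (1 + exp(-k (nu - nu_c)))` with random steepness sign.
#' A compound type (e.g. `"E+S"`) is the equal-weight mean of its two
#' components. Parameters are drawn from the current RNG state; callers
#' seed it for reproducibility.
#'
#' @param wavenumbers Strictly increasing grid (cm^-1).
#' @param type Baseline family: `"E"`, `"G"`, `"P"`, `"S"` or a compound
#'   pair like `"E+S"`.
#' @param amplitude Baseline amplitude scale (a.u.).
#' @return Numeric baseline vector on the grid.
#' @export
generate_baseline <- function(wavenumbers, type, amplitude = 1) {
  parts <- strsplit(type, "+", fixed = TRUE)[[1]]
  if (length(parts) > 1) {
    comps <- vapply(parts, function(tp) generate_baseline(wavenumbers, tp, amplitude),
                    numeric(length(wavenumbers)))
    return(rowMeans(comps))
  }
  nu <- wavenumbers
  rng <- range(nu)
  span <- diff(rng)
  a <- runif(1, 0.5, 1.5) * amplitude
  switch(type,
    E = {
      b <- runif(1, 0.8, 4.8) / span   # decay factor e^-0.8 .. e^-4.8 over the grid
      a * exp(-b * (nu - rng[1]))
    },
    G = {
      mu <- runif(1, rng[1], rng[2])
      sigma <- runif(1, 0.4, 1.0) * span
      a * exp(-(nu - mu)^2 / (2 * sigma^2))
    },
    P = {
      x <- 2 * (nu - rng[1]) / span - 1
      cf <- rnorm(6) / (1 + (0:5))^2   # decaying scale keeps high orders gentle
      v <- outer(x, 0:5, "^") %*% cf
      v <- as.vector(v)
      vr <- range(v)
      if (diff(vr) < .Machine$double.eps) return(rep(a, length(nu)))
      (v - vr[1]) / diff(vr) * a
    },
    S = {
      k <- sample(c(-1, 1), 1) * runif(1, 4, 10) / span
      nu_c <- runif(1, rng[1] + 0.2 * span, rng[2] - 0.2 * span)
      a / (1 + exp(-k * (nu - nu_c)))
    },
    abort(paste0("unknown baseline type: '", type, "'"))
  )
}

#' Generate a synthetic peak signal
#'
#' Draws a nonnegative sum of Gaussian peaks of the requested family.
#' `B` (broad): 2–3 well-separated peaks with FWHM of 4–8% of the grid
#' span (64–128 cm^-1 on the default grid), several times wider than the
#' other families. `C` (convoluted): 6–12 equal-width peaks chained with
#' centre spacing below 1.5 FWHM, so envelopes overlap into an unresolved
#' profile. `D` (distinct): 5–10 narrow peaks placed with spacing above 3
#' times the largest FWHM, so every peak resolves. A compound type
#' (`"B+C"`) is the sum of one draw of each family. The summed signal is
#' rescaled so its maximum lands in `[0.7, 1.5] * amplitude`.
#'
#' @param wavenumbers Strictly increasing grid (cm^-1).
#' @param type Peak family: `"B"`, `"C"`, `"D"` or compound like `"B+C"`.
#' @param amplitude Peak amplitude scale (a.u.).
#' @return Numeric signal vector, `min >= 0`, carrying a `peaks` attribute
#'   (tibble of center, fwhm, amplitude per drawn peak).
#' @export
generate_peaks <- function(wavenumbers, type, amplitude = 1) {
  parts <- strsplit(type, "+", fixed = TRUE)[[1]]
  if (length(parts) > 1) {
    comps <- lapply(parts, function(tp) generate_peaks(wavenumbers, tp, amplitude))
    out <- Reduce(`+`, lapply(comps, as.numeric))
    attr(out, "peaks") <- dplyr::bind_rows(lapply(comps, attr, "peaks"))
    return(out)
  }
  nu <- wavenumbers
  rng <- range(nu)
  span <- diff(rng)
  pk_meta <- NULL
  gauss_sum <- function(centers, fwhms, amps) {
    pk_meta <<- tibble(center = centers, fwhm = fwhms, amplitude = amps)
    sig <- fwhms / (2 * sqrt(2 * log(2)))
    v <- numeric(length(nu))
    for (i in seq_along(centers)) {
      v <- v + amps[i] * exp(-(nu - centers[i])^2 / (2 * sig[i]^2))
    }
    v
  }
  v <- switch(type,
    B = {
      k <- sample(2:3, 1)
      fw <- runif(k, 0.04, 0.08) * span
      gaps <- runif(k, 1.8, 3.5) * max(fw)
      ct <- rng[1] + runif(1, 0.05, 0.2) * span + cumsum(gaps)
      keep <- ct < rng[2] - 0.05 * span
      if (!any(keep)) keep[1] <- TRUE
      gauss_sum(ct[keep], fw[keep], runif(sum(keep), 0.3, 1))
    },
    C = {
      k <- sample(6:12, 1)
      fw <- runif(1, 0.02, 0.05) * span
      start <- runif(1, rng[1] + 0.05 * span, rng[1] + 0.35 * span)
      ct <- start + cumsum(c(0, runif(k - 1, 0.5, 1.4) * fw))
      ct <- ct[ct < rng[2] - 0.05 * span]
      gauss_sum(ct, rep(fw, length(ct)), runif(length(ct), 0.3, 1))
    },
    D = {
      k <- sample(5:10, 1)
      fw <- runif(k, 0.01, 0.03) * span
      gaps <- runif(k, 3.2, 6) * max(fw)
      ct <- rng[1] + 0.05 * span + cumsum(gaps)
      keep <- ct < rng[2] - 0.05 * span
      gauss_sum(ct[keep], fw[keep], runif(sum(keep), 0.3, 1))
    },
    abort(paste0("unknown peak type: '", type, "'"))
  )
  vmax <- max(v)
  if (vmax <= 0) abort("degenerate peak draw (no peaks on grid)")
  scale <- runif(1, 0.7, 1.5) * amplitude / vmax
  out <- v * scale
  pk_meta$amplitude <- pk_meta$amplitude * scale
  attr(out, "peaks") <- pk_meta
  out
}

# Distinct per-spectrum seed substreams derived from one master seed.
# Kept below 2^31 so the value is a valid R integer seed.
spectrum_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1e5) * 20011 + index) %% .Machine$integer.max
}

#' Generate one synthetic spectrum
#'
#' Draws a labeled spectrum of the given shape: a peak signal plus a
#' baseline on a uniform wavenumber grid, with the exact decomposition
#' stored (`intensity = true_signal + true_baseline`). Broad-peak (B)
#' shapes default to a 100x amplitude scale relative to C/D shapes.
#'
#' @param shape Shape code such as `"B&E"` or compound `"B+C&E+S"`.
#' @param n_points Grid length (default 1024).
#' @param wavenumber_range Grid interval in cm^-1 (default 400–2000).
#' @param amplitude_scale Peak/baseline amplitude scale; `NULL` picks the
#'   family default (100 for B shapes, 1 otherwise).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A spectrum tibble with `wavenumber`, `intensity`,
#'   `true_baseline`, `true_signal`; `shape_label` attribute set.
#' @export
#' @examples
#' sp <- generate_spectrum("C&P", seed = 7)
#' range(sp$true_signal)
generate_spectrum <- function(shape, n_points = 1024L,
                              wavenumber_range = c(400, 2000),
                              amplitude_scale = NULL, seed = NULL) {
  parts <- split_shape_code(shape)
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  if (is.null(amplitude_scale)) {
    amplitude_scale <- default_amplitude_scale(parts$peaks)
  }
  nu <- seq(wavenumber_range[1], wavenumber_range[2], length.out = n_points)
  sig <- generate_peaks(nu, paste(parts$peaks, collapse = "+"), amplitude_scale)
  base <- generate_baseline(nu, paste(parts$baselines, collapse = "+"),
                            amplitude_scale)
  out <- tibble(wavenumber = nu, intensity = as.numeric(sig + base),
                true_baseline = as.numeric(base),
                true_signal = as.numeric(sig))
  attr(out, "shape_label") <- shape
  attr(out, "peak_table") <- attr(sig, "peaks")
  out
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n_per_shape` spectra for every shape code, each from its own seed
#' substream derived from `seed`, so the dataset is reproducible as a whole
#' and any single spectrum can be regenerated alone from its stored seed.
#'
#' @param shapes Character vector of shape codes (default: all 12).
#' @param n_per_shape Spectra per shape.
#' @param seed Master seed (integer).
#' @param n_points,wavenumber_range Grid, passed to [generate_spectrum()].
#' @return A nested tibble with one row per spectrum: `id`, `shape_label`,
#'   `seed`, `snr` (NA for noise-free) and a `spectrum` list-column.
#' @export
#' @examples
#' ds <- generate_dataset(n_per_shape = 1, seed = 1)
#' ds$shape_label
generate_dataset <- function(shapes = shape_codes(), n_per_shape = 500L,
                             seed = 1L, n_points = 1024L,
                             wavenumber_range = c(400, 2000)) {
  if (n_per_shape < 1) abort("`n_per_shape` must be at least 1.")
  grid <- tidyr::expand_grid(shape_label = shapes, rep = seq_len(n_per_shape))
  grid$id <- seq_len(nrow(grid))
  grid$seed <- spectrum_seed(seed, grid$id)
  grid$spectrum <- purrr::map2(grid$shape_label, grid$seed, function(sh, sd) {
    generate_spectrum(sh, n_points = n_points,
                      wavenumber_range = wavenumber_range, seed = sd)
  })
  out <- grid[, c("id", "shape_label", "seed", "spectrum")]
  out$snr <- NA_real_
  as_tibble(out[, c("id", "shape_label", "seed", "snr", "spectrum")])
}

#' Add Gaussian noise at a target SNR
#'
#' Adds zero-mean i.i.d. Gaussian noise to the intensities, scaled so the
#' signal-to-noise ratio hits the target. SNR is defined here as
#' `max(true_signal) / sd(noise)` — the peak-amplitude convention common in
#' spectroscopy. The `true_baseline`/`true_signal` columns are preserved, so
#' `intensity - true_signal - true_baseline` recovers the noise draw.
#'
#' @param data A spectrum tibble carrying `true_signal`.
#' @param snr Target SNR, `> 0`.
#' @param seed Optional integer seed.
#' @return The noisy spectrum tibble; attribute `snr` records the target.
#' @export
#' @examples
#' sp <- generate_spectrum("D&G", seed = 2)
#' noisy <- add_noise(sp, snr = 10, seed = 3)
add_noise <- function(data, snr, seed = NULL) {
  data <- as_spectrum(data)
  if (is.null(data[["true_signal"]])) {
    abort("`add_noise()` needs a `true_signal` column to reference the SNR.")
  }
  if (!is.finite(snr) || snr <= 0) abort("`snr` must be positive.")
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  sigma <- max(data$true_signal) / snr
  out <- data
  out$intensity <- data$intensity + rnorm(nrow(data), 0, sigma)
  attr(out, "shape_label") <- attr(data, "shape_label")
  attr(out, "snr") <- snr
  out
}

#' The ten SNR levels of the noise-robustness study
#'
#' Log-spaced levels spanning the experimentally observed range 6.47–49.92.
#'
#' @return Numeric vector of length 10.
#' @export
snr_levels <- function() {
  exp(seq(log(6.47), log(49.92), length.out = 10))
}
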