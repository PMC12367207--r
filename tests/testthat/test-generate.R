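test_that("spectra decompose exactly and are reproducible from their seed", {
  sp <- generate_spectrum("C&G", seed = 301)
  expect_equal(sp$intensity, sp$true_signal + sp$true_baseline)
  expect_identical(attr(sp, "shape_label"), "C&G")
  expect_true(all(diff(sp$wavenumber) > 0))
  expect_true(min(sp$true_signal) >= 0)
  sp2 <- generate_spectrum("C&G", seed = 301)
  expect_identical(sp, sp2)
})

test_that("datasets are balanced, reproducible and per-spectrum regenerable", {
  ds <- generate_dataset(n_per_shape = 2, seed = 77, n_points = 128)
  expect_equal(nrow(ds), 24)
  expect_equal(as.integer(table(ds$shape_label)), rep(2L, 12))
  ds2 <- generate_dataset(n_per_shape = 2, seed = 77, n_points = 128)
  expect_identical(ds, ds2)
  # any single spectrum regenerates alone from its stored seed
  i <- 17
  alone <- generate_spectrum(ds$shape_label[i], n_points = 128,
                             seed = ds$seed[i])
  expect_identical(ds$spectrum[[i]], alone)
  # single-per-shape dataset carries exactly the 12 codes
  ds1 <- generate_dataset(n_per_shape = 1, seed = 3, n_points = 64)
  expect_setequal(ds1$shape_label, shape_codes())
})

test_that("compound baselines equal the mean of their components", {
  nu <- toy_grid(200)
  set.seed(55); b_e <- generate_baseline(nu, "E", amplitude = 2)
  b_s <- generate_baseline(nu, "S", amplitude = 2)
  set.seed(55); b_es <- generate_baseline(nu, "E+S", amplitude = 2)
  expect_equal(b_es, (b_e + b_s) / 2)
})

test_that("baseline families produce nonnegative, bounded curves", {
  nu <- toy_grid(300)
  set.seed(9)
  for (tp in c("E", "G", "P", "S")) {
    b <- generate_baseline(nu, tp, amplitude = 1)
    expect_true(all(b >= -1e-12), info = tp)
    expect_lte(max(b), 1.5 + 1e-12)
  }
  expect_error(generate_baseline(nu, "Q"), "unknown baseline")
})

test_that("peak families respect their geometry constraints", {
  nu <- toy_grid(1024)
  set.seed(31)
  for (rep in 1:5) {
    d <- generate_peaks(nu, "D", amplitude = 1)
    pk <- attr(d, "peaks")
    if (nrow(pk) > 1) {
      gaps <- diff(sort(pk$center))
      expect_true(all(gaps > 3 * max(pk$fwhm)))
    }
    c_ <- generate_peaks(nu, "C", amplitude = 1)
    pc <- attr(c_, "peaks")
    if (nrow(pc) > 1) {
      expect_true(all(diff(sort(pc$center)) < 1.5 * max(pc$fwhm)))
    }
    for (v in list(d, c_)) {
      expect_gte(min(v), 0)
      expect_gte(max(v), 0.5)
      expect_lte(max(v), 2)
    }
  }
  # compound peak is the sum of one draw of each family
  set.seed(8); pb <- generate_peaks(nu, "B", 1); pc2 <- generate_peaks(nu, "C", 1)
  set.seed(8); pbc <- generate_peaks(nu, "B+C", 1)
  expect_equal(as.numeric(pbc), as.numeric(pb) + as.numeric(pc2))
  expect_error(generate_peaks(nu, "Z"), "unknown peak")
})

test_that("broad-peak spectra live on a much larger default-fit error scale", {
  set.seed(13)
  mae_dp <- function(shape, s) {
    sp <- generate_spectrum(shape, n_points = 512, seed = s)
    fit <- airpls(sp, 100, 1e-3, 1)
    mae(fit$data$baseline, sp$true_baseline)
  }
  b <- vapply(1:4, function(s) mae_dp("B&E", 100 + s), numeric(1))
  cd <- vapply(1:4, function(s) mae_dp(sample(c("C&E", "D&G"), 1), 200 + s),
               numeric(1))
  expect_gte(mean(b) / mean(cd), 100)
})

test_that("noise injection hits the target SNR and preserves the truth", {
  sp <- generate_spectrum("D&E", seed = 501)
  noisy <- add_noise(sp, snr = 6.47, seed = 77)
  draw <- noisy$intensity - noisy$true_signal - noisy$true_baseline
  realized <- max(noisy$true_signal) / sd(draw)
  expect_lt(abs(realized - 6.47) / 6.47, 0.05)
  expect_identical(noisy$true_baseline, sp$true_baseline)

  # both published endpoints, across replicates
  for (target in c(6.47, 49.92)) {
    rel <- vapply(1:25, function(i) {
      nz <- add_noise(sp, snr = target, seed = i)
      d <- nz$intensity - sp$intensity
      max(nz$true_signal) / sd(d)
    }, numeric(1))
    expect_true(all(abs(rel - target) / target < 0.05))
  }

  # enormous SNR leaves the spectrum essentially untouched
  quiet <- add_noise(sp, snr = 1e9, seed = 1)
  expect_lt(max(abs(quiet$intensity - sp$intensity)),
            1e-6 * max(sp$true_signal))

  # moment oracle on a long grid
  big <- generate_spectrum("D&E", n_points = 10000, seed = 9)
  nz <- add_noise(big, snr = 10, seed = 2)
  d <- nz$intensity - big$intensity
  sigma <- max(big$true_signal) / 10
  expect_lt(abs(mean(d)), 4 * sigma / sqrt(10000))
  expect_lt(abs(sd(d) - sigma) / sigma, 0.05)

  expect_error(add_noise(sp, snr = -1), "positive")
  no_truth <- tibble::tibble(wavenumber = toy_grid(64),
                             intensity = rnorm(64))
  expect_error(add_noise(no_truth, 10), "true_signal")
})

test_that("snr level ladder spans the published range", {
  lv <- snr_levels()
  expect_length(lv, 10)
  expect_equal(lv[1], 6.47, tolerance = 1e-8)
  expect_equal(lv[10], 49.92, tolerance = 1e-8)
  expect_true(all(diff(lv) > 0))
})
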