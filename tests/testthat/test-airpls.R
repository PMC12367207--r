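test_that("difference penalty matrices match brute-force construction", {
  # order 1, n = 4: tridiagonal with diagonal (1, 2, 2, 1), off-diagonal -1
  P1 <- as.matrix(build_penalty(4, 1))
  expect_equal(diag(P1), c(1, 2, 2, 1))
  expect_equal(P1[cbind(1:3, 2:4)], rep(-1, 3))
  expect_true(isSymmetric(P1))

  # order 2 annihilates straight lines (null space of dimension 2)
  v <- 3 + 0.7 * seq_len(9)
  expect_equal(as.numeric(build_penalty(9, 2) %*% v), rep(0, 9),
               tolerance = 1e-12)

  # n = 6, p = 2 equals explicit D'D computed by loops
  D <- matrix(0, 4, 6)
  for (k in 1:4) D[k, k:(k + 2)] <- c(1, -2, 1)
  expect_equal(as.matrix(build_penalty(6, 2)), t(D) %*% D,
               ignore_attr = TRUE)

  expect_error(build_penalty(2, 2), "exceed")
  expect_error(build_penalty(5, 3), "must be 1 or 2")
})

test_that("weighted Whittaker smoother honors its limiting cases", {
  set.seed(11)
  y <- cumsum(rnorm(120))
  w <- rep(1, 120)

  # fidelity-only limit: lambda -> 0 returns the data
  expect_lt(max(abs(whittaker_smooth(y, w, lambda = 1e-12, p = 2) - y)), 1e-6)

  # heavy smoothing with p = 2 reproduces the straight-line OLS fit
  x <- seq_along(y)
  line <- unname(fitted(lm(y ~ x)))
  z <- whittaker_smooth(y, w, lambda = 1e12, p = 2)
  expect_lt(max(abs(z - line)) / max(abs(line)), 1e-4)

  # heavy smoothing with p = 1 reproduces the weighted mean
  w2 <- runif(120, 0.1, 2)
  z1 <- whittaker_smooth(y, w2, lambda = 1e12, p = 1)
  expect_equal(z1, rep(sum(w2 * y) / sum(w2), 120), tolerance = 1e-4)

  # constants lie in the null space and satisfy fidelity exactly
  expect_equal(whittaker_smooth(rep(4.2, 50), runif(50, 0.5, 1), 100, 2),
               rep(4.2, 50), tolerance = 1e-8)

  expect_error(whittaker_smooth(y, rep(0, 120), 10, 2), "positive entry")
  expect_error(whittaker_smooth(c(y[-1], NA), w, 10, 2), "finite")
})

test_that("whittaker solution satisfies the normal equations to 1e-8", {
  set.seed(7)
  for (p in 1:2) {
    y <- rnorm(200)
    w <- runif(200)
    lam <- 10^runif(1, 0, 6)
    z <- whittaker_smooth(y, w, lam, p)
    A <- diag(w) + lam * as.matrix(build_penalty(200, p))
    resid <- max(abs(A %*% z - w * y))
    expect_lt(resid, 1e-8 * max(abs(w * y)))
  }
})

test_that("airpls fit contract: decomposition, weights, convergence flag", {
  sp <- toy_peak_spectrum()
  fit <- airpls(sp, lambda = 1e5, tau = 1e-6, p = 2)
  expect_s3_class(fit, "airpls_fit")
  d <- tidy(fit)
  expect_equal(d$corrected, d$intensity - d$baseline)
  expect_true(all(d$weight >= 0 & d$weight <= 1))
  expect_true(fit$converged)
  expect_lte(fit$iterations, fit$max_iter)

  # final-weight solver exactness on the fitted baseline
  wraw <- d$weight * fit$weight_max
  A <- diag(wraw) + 1e5 * as.matrix(build_penalty(nrow(d), 2))
  expect_lt(max(abs(A %*% d$baseline - wraw * d$intensity)),
            1e-8 * max(abs(wraw * d$intensity)) + 1e-12)

  # glance is a single row
  expect_equal(nrow(glance(fit)), 1)

  expect_error(airpls(sp, lambda = -1), "positive")
  expect_error(airpls(sp, tau = 2), "in \\(0, 1\\)")
  sp_bad <- sp
  sp_bad$intensity[3] <- NaN
  expect_error(airpls(sp_bad), "finite")
})

test_that("unconverged fits report converged = FALSE instead of throwing", {
  sp <- toy_peak_spectrum()
  fit <- airpls(sp, lambda = 100, tau = 1e-12, p = 2, max_iter = 5)
  expect_false(fit$converged)
  expect_equal(fit$iterations, 5L)
})

test_that("iteration count is non-increasing in tau", {
  set.seed(23)
  for (s in 1:4) {
    sp <- generate_spectrum(sample(shape_codes(), 1), n_points = 512, seed = s)
    taus <- 10^c(-2, -3, -4, -6)
    iters <- vapply(taus, function(tv) {
      airpls(sp, lambda = 100, tau = tv, p = 2)$iterations
    }, integer(1))
    expect_true(all(diff(iters) >= 0))
  }
})

test_that("baseline estimate is equivariant to constant shifts (p = 2)", {
  # run both fits for the same fixed number of iterations (a tiny tau never
  # triggers early stopping), since the reweighting itself is
  # shift-invariant while the stopping threshold scales with sum(|y|)
  sp <- toy_peak_spectrum()
  f0 <- airpls(sp, lambda = 1e4, tau = 1e-14, p = 2, max_iter = 25)
  sp2 <- sp
  sp2$intensity <- sp$intensity + 37.5
  f1 <- airpls(sp2, lambda = 1e4, tau = 1e-14, p = 2, max_iter = 25)
  expect_equal(f0$iterations, f1$iterations)
  scale <- max(abs(f0$data$baseline))
  expect_lt(max(abs(f1$data$baseline - f0$data$baseline - 37.5)) / scale, 1e-6)
})

test_that("pure peaks on a zero baseline yield a near-zero baseline", {
  sp <- toy_pure_peaks()
  fit <- airpls(sp, lambda = 1e6, tau = 1e-4, p = 2)
  expect_lt(max(abs(fit$data$baseline)), 0.05 * max(sp$true_signal))
})

test_that("fitting beats the trivial zero baseline on a sloped spectrum", {
  sp <- toy_peak_spectrum()
  fit <- airpls(sp, lambda = 1e5, tau = 1e-6, p = 2)
  expect_lt(mae(fit$data$baseline, sp$true_baseline),
            mae(rep(0, nrow(sp)), sp$true_baseline))
})

test_that("airpls_weights follows the documented dialect", {
  res <- c(-0.5, 0.2, -0.1, 0, -0.4)
  w <- airpls_weights(res, iteration = 2, total_mass = 10)
  m <- 0.5 + 0.1 + 0.4
  expect_equal(w[2], 0)
  expect_equal(w[4], 0)
  expect_equal(w[3], exp(2 * 0.1 / m))
  # endpoints anchored at the maximum weight
  expect_equal(w[1], exp(2 * 0.5 / m))
  expect_equal(w[5], w[1])
  # overflow safety: huge residuals still give finite weights
  wbig <- airpls_weights(c(-1e300, 1, -1e-12), iteration = 100, total_mass = 1)
  expect_true(all(is.finite(wbig)))
})
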