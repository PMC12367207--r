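test_that("mae is the mean absolute difference with its simple algebra", {
  expect_equal(mae(c(1, 2, 3), c(2, 2, 1)), 1)
  a <- rnorm(20)
  expect_equal(mae(a, a), 0)
  expect_equal(mae(a, a + 0.7), 0.7)
  b <- rnorm(20)
  expect_equal(mae(a, b), mae(b, a))
  # linear in a common scale factor
  expect_equal(mae(3 * a, 3 * b), 3 * mae(a, b))
  expect_error(mae(1:3, 1:4), "equal length")
})

test_that("percentage improvement encodes order-of-magnitude reductions", {
  expect_equal(percentage_improvement(10, 1), 90)
  expect_equal(percentage_improvement(0.103, 5.55e-4), 99.46, tolerance = 1e-3)
  m <- runif(1, 0.5, 2)
  expect_equal(percentage_improvement(m, m / 100), 99)
  expect_equal(percentage_improvement(m, m), 0)
  # worse fits go negative (the outlier-flagging convention)
  expect_lt(percentage_improvement(1, 2), 0)
  # scale invariance
  expect_equal(percentage_improvement(3 * 10, 3 * 1), 90)
  expect_warning(out <- percentage_improvement(0, 1), "0")
  expect_equal(out, 0)
})

test_that("pct_above counts threshold attainment as a percentage", {
  expect_equal(pct_above(c(70, 80, 90), 80), 2 / 3 * 100)
  expect_equal(pct_above(c(91, 95), 90), 100)
  expect_equal(pct_above(c(10, 20), 90), 0)
  expect_error(pct_above(numeric(0), 50), "nonempty")
})

test_that("cosine similarity is bounded, normalized and guards zero vectors", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), sqrt(0.5))
  a <- rnorm(30)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, 5 * a), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("LOC and LIC are the log- and linear-space centers", {
  pairs <- data.frame(lambda = c(10, 1000), tau = c(1e-2, 1e-4))
  ctr <- loc_lic(pairs)
  expect_equal(ctr$lambda[ctr$strategy == "LOC"], 100)
  expect_equal(ctr$tau[ctr$strategy == "LOC"], 1e-3)
  expect_equal(ctr$lambda[ctr$strategy == "LIC"], 505)
  expect_equal(ctr$tau[ctr$strategy == "LIC"], 0.00505)
  one <- loc_lic(data.frame(lambda = 42, tau = 1e-5))
  expect_equal(one$lambda, c(42, 42))
  expect_equal(one$tau, c(1e-5, 1e-5))
  expect_error(loc_lic(data.frame(lambda = -1, tau = 1e-3)), "positive")
})

test_that("parameter-region fit matches a hand normal-equations oracle", {
  set.seed(41)
  x <- runif(10, 0.5, 5)
  y <- 0.9 * x - 8 + rnorm(10, sd = 0.3)
  pairs <- data.frame(lambda = 10^x, tau = 10^y)
  fit <- fit_parameter_region(pairs)
  # closed-form OLS via normal equations
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_gte(fit$r_squared, 0); expect_lte(fit$r_squared, 1)
  expect_equal(fit$lam_log_range, range(x))
  # exactly collinear points recover the slope with R^2 = 1
  col <- data.frame(lambda = 10^c(1, 2, 3), tau = 10^(0.865 * c(1, 2, 3) - 8.765))
  cfit <- fit_parameter_region(col)
  expect_equal(cfit$slope, 0.865, tolerance = 1e-10)
  expect_equal(cfit$r_squared, 1, tolerance = 1e-10)
  # order invariance
  fit2 <- fit_parameter_region(pairs[sample(10), ])
  expect_equal(glance(fit)$slope, glance(fit2)$slope)
  expect_error(fit_parameter_region(data.frame(lambda = c(1, 1, 1),
                                               tau = c(1e-3, 1e-4, 1e-5))),
               "undefined")
})

test_that("confidence ellipse uses the chi-square radius and covers ~95%", {
  set.seed(97)
  pts <- matrix(rnorm(2e4), ncol = 2)
  ell <- confidence_ellipse(pts, level = 0.95)
  r_expect <- sqrt(qchisq(0.95, 2))
  expect_lt(abs(ell$radii[1] - r_expect) / r_expect, 0.05)
  expect_lt(abs(ell$radii[2] - r_expect) / r_expect, 0.05)
  # Monte-Carlo containment
  S_inv <- solve(ell$cov)
  ctr <- sweep(pts, 2, ell$center)
  d2 <- rowSums((ctr %*% S_inv) * ctr)
  inside <- mean(d2 <= qchisq(0.95, 2))
  expect_gte(inside, 0.93); expect_lte(inside, 0.97)
  # affine equivariance under scaling
  ell2 <- confidence_ellipse(2 * pts, level = 0.95)
  expect_equal(sort(ell2$radii), sort(2 * ell$radii), tolerance = 1e-8)
  expect_error(confidence_ellipse(cbind(1:5, 2 * (1:5))), "collinear")
  # boundary polygon lies at the Mahalanobis radius
  ep <- ellipse_points(ell, n = 73)
  dd <- sweep(as.matrix(ep), 2, ell$center)
  md <- rowSums((dd %*% S_inv) * dd)
  expect_equal(md, rep(qchisq(0.95, 2), 73), tolerance = 1e-8)
})

test_that("per-shape summaries aggregate mean and sd of metric columns", {
  rec <- tibble::tibble(shape_label = rep(c("A", "B"), each = 3),
                        pi = c(1, 2, 3, 10, 20, 30))
  s <- summarize_by_shape(rec)
  expect_equal(s$pi_mean, c(2, 20))
  expect_equal(s$pi_sd, c(1, 10))
  expect_equal(s$n, c(3L, 3L))
})
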