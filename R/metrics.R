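#' Mean absolute error
#'
#' @param a,b Numeric vectors of equal length.
#' @return `mean(abs(a - b))`.
#' @export
#' @examples
#' mae(c(1, 2, 3), c(2, 2, 1))  # 1
mae <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  mean(abs(a - b))
}

#' Percentage improvement of one baseline fit over a reference
#'
#' `PI = (mae_ref - mae_new) / mae_ref * 100`. Positive when the new fit
#' improves on the reference; 90 corresponds to a one-order-of-magnitude
#' MAE reduction, 99 to two orders. Negative values flag a fit that is
#' worse than the reference (which happens, e.g., for predicted parameters
#' on noisy spectra). A zero reference MAE is degenerate and returns 0 with
#' a warning rather than dividing by zero.
#'
#' @param mae_ref Reference MAE (default-parameter fit), `> 0`.
#' @param mae_new MAE of the fit being scored.
#' @return PI in percent.
#' @export
#' @examples
#' percentage_improvement(10, 1)    # 90
#' percentage_improvement(0.103, 5.55e-4)
percentage_improvement <- function(mae_ref, mae_new) {
  if (any(mae_ref == 0)) {
    warn("reference MAE is 0; PI defined as 0 for those entries.")
  }
  ifelse(mae_ref == 0, 0, (mae_ref - mae_new) / mae_ref * 100)
}

#' Fraction of spectra at or above a PI threshold
#'
#' `Pct(PI >= threshold)`: the percentage of entries meeting the threshold.
#'
#' @param pis Numeric vector of PI values (percent), nonempty.
#' @param threshold Threshold in percent.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' pct_above(c(70, 80, 90), 80)  # 66.67
pct_above <- function(pis, threshold) {
  if (length(pis) == 0) abort("`pis` must be nonempty.")
  mean(pis >= threshold) * 100
}

#' Cosine similarity
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return `sum(a * b) / (||a|| ||b||)`, in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))  # 0.7071
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine similarity is undefined for a zero vector.")
  sum(a * b) / (na * nb)
}

#' Logarithmic and linear center of optimized parameter pairs
#'
#' Two fixed-parameter strategies summarizing a set of per-spectrum optima:
#' LOC is the elementwise geometric mean (the center in log space), LIC the
#' elementwise arithmetic mean.
#'
#' @param pairs Data frame with positive `lambda` and `tau` columns.
#' @return A tibble with rows `LOC` and `LIC` and columns
#'   `strategy`, `lambda`, `tau`.
#' @export
#' @examples
#' loc_lic(data.frame(lambda = c(10, 1000), tau = c(1e-2, 1e-4)))
loc_lic <- function(pairs) {
  if (!all(c("lambda", "tau") %in% names(pairs))) {
    abort("`pairs` must have `lambda` and `tau` columns.")
  }
  if (nrow(pairs) == 0) abort("`pairs` must be nonempty.")
  if (any(pairs$lambda <= 0) || any(pairs$tau <= 0)) {
    abort("all parameters must be positive.")
  }
  tibble(
    strategy = c("LOC", "LIC"),
    lambda = c(10^mean(log10(pairs$lambda)), mean(pairs$lambda)),
    tau = c(10^mean(log10(pairs$tau)), mean(pairs$tau))
  )
}

#' Log-linear fit of the optimal-parameter region
#'
#' Optimized `(lambda*, tau*)` pairs concentrate along a rising diagonal in
#' the `(log10 lambda, log10 tau)` plane. This fits
#' `log10(tau*) ~ log10(lambda*)` by ordinary least squares and reports the
#' slope, intercept, R^2 and the observed `log10(lambda*)` range.
#'
#' @param pairs Data frame with positive `lambda` and `tau` columns,
#'   at least 3 rows, `lambda` not all equal.
#' @return A `param_region_fit` object; `tidy()` gives term estimates,
#'   `glance()` the one-row summary, `autoplot()` the scatter with the
#'   fitted line and a 95% confidence ellipse.
#' @export
#' @examples
#' pr <- fit_parameter_region(
#'   data.frame(lambda = 10^c(1, 2, 3), tau = 10^c(-8, -7.2, -6.1)))
#' glance(pr)
fit_parameter_region <- function(pairs) {
  if (!all(c("lambda", "tau") %in% names(pairs))) {
    abort("`pairs` must have `lambda` and `tau` columns.")
  }
  if (nrow(pairs) < 3) abort("need at least 3 pairs.")
  if (any(pairs$lambda <= 0) || any(pairs$tau <= 0)) {
    abort("all parameters must be positive.")
  }
  x <- log10(pairs$lambda); y <- log10(pairs$tau)
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    abort("slope undefined: all lambda* values are (numerically) equal.")
  }
  fit <- lm(y ~ x)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         lam_log_range = range(x),
         pairs = tibble(log10_lambda = x, log10_tau = y)),
    class = "param_region_fit"
  )
}

#' @export
print.param_region_fit <- function(x, ...) {
  cat("Optimal-parameter region (log-log OLS)\n")
  cat(sprintf("  log10(tau*) = %.3f log10(lambda*) %+0.3f   (R^2 = %.3f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  log10(lambda*) in [%.3f, %.3f], n = %d\n",
              x$lam_log_range[1], x$lam_log_range[2], nrow(x$pairs)))
  invisible(x)
}

#' @rdname fit_parameter_region
#' @param x,object A `param_region_fit`.
#' @param ... Unused.
#' @export
tidy.param_region_fit <- function(x, ...) {
  tibble(term = c("intercept", "log10_lambda"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_parameter_region
#' @export
glance.param_region_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         lam_log_min = x$lam_log_range[1], lam_log_max = x$lam_log_range[2],
         n = nrow(x$pairs))
}

#' @rdname fit_parameter_region
#' @export
autoplot.param_region_fit <- function(object, ...) {
  ell <- confidence_ellipse(
    cbind(object$pairs$log10_lambda, object$pairs$log10_tau), level = 0.95)
  ep <- ellipse_points(ell)
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$log10_lambda, .data$log10_tau)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::geom_path(data = ep, ggplot2::aes(.data$x, .data$y),
                       colour = "red", linetype = 2) +
    ggplot2::labs(x = expression(log[10](lambda ^ "*")),
                  y = expression(log[10](tau ^ "*"))) +
    ggplot2::theme_minimal()
}

#' Confidence ellipse of a 2-D point cloud
#'
#' Ellipse from the sample mean and covariance, with the squared Mahalanobis
#' radius set to the chi-square quantile with 2 degrees of freedom at the
#' requested level (the large-sample normal-theory ellipse).
#'
#' @param points A two-column matrix or data frame (`>= 3` non-collinear rows).
#' @param level Coverage probability in `(0, 1)`, default 0.95.
#' @return A list with `center` (length 2), `radii` (semi-axes, decreasing),
#'   `angle` (radians, orientation of the major axis), and `cov`.
#' @export
#' @examples
#' pts <- matrix(rnorm(2000), ncol = 2)
#' confidence_ellipse(pts)$radii  # both near sqrt(qchisq(.95, 2))
confidence_ellipse <- function(points, level = 0.95) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) abort("`points` must have exactly 2 columns.")
  if (nrow(pts) < 3) abort("need at least 3 points.")
  if (level <= 0 || level >= 1) abort("`level` must lie in (0, 1).")
  ctr <- colMeans(pts)
  S <- cov(pts)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= .Machine$double.eps * max(e$values)) {
    abort("points are (numerically) collinear; covariance is degenerate.")
  }
  r <- sqrt(e$values * qchisq(level, df = 2))
  list(center = unname(ctr), radii = r,
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       cov = S, level = level)
}

#' @rdname confidence_ellipse
#' @param ellipse A value from `confidence_ellipse()`.
#' @param n Number of polygon vertices.
#' @return `ellipse_points()`: a tibble of `x`, `y` boundary coordinates.
#' @export
ellipse_points <- function(ellipse, n = 181L) {
  th <- seq(0, 2 * pi, length.out = n)
  R <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  xy <- cbind(ellipse$radii[1] * cos(th), ellipse$radii[2] * sin(th)) %*% t(R)
  tibble(x = xy[, 1] + ellipse$center[1], y = xy[, 2] + ellipse$center[2])
}

#' Per-shape summary of evaluation records
#'
#' Mean and standard deviation of every MAE/PI column present, by shape.
#'
#' @param records Tibble with a `shape_label` column plus numeric metric
#'   columns (e.g. from [optimize_dataset()] or [evaluate_predictor()]).
#' @return A tibble with one row per shape.
#' @export
summarize_by_shape <- function(records) {
  if (!"shape_label" %in% names(records)) {
    abort("`records` must have a `shape_label` column.")
  }
  num <- names(records)[vapply(records, is.numeric, logical(1))]
  num <- setdiff(num, c("id", "seed"))
  records |>
    group_by(.data$shape_label) |>
    summarise(n = dplyr::n(),
              across(dplyr::all_of(num),
                     list(mean = ~mean(.x, na.rm = TRUE),
                          sd = ~sd(.x, na.rm = TRUE))),
              .groups = "drop")
}
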