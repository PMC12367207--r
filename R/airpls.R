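#' Difference penalty matrix D'D
#'
#' Builds the banded symmetric penalty matrix of a Whittaker smoother:
#' `crossprod(D)` where `D` is the `(n - p) x n` forward difference operator
#' of order `p`. The result is positive semidefinite with a null space of
#' dimension `p` (constants for `p = 1`, all straight lines for `p = 2`).
#'
#' @param n Grid length (`n >= p + 1`).
#' @param p Difference order, 1 or 2.
#' @return A sparse symmetric `Matrix` of size `n x n`.
#' @export
#' @examples
#' build_penalty(5, 2)
build_penalty <- function(n, p = 2L) {
  p <- as.integer(p)
  if (!p %in% c(1L, 2L)) abort("`p` must be 1 or 2.")
  if (n <= p) abort("`n` must exceed the difference order `p`.")
  coefs <- if (p == 1L) c(-1, 1) else c(1, -2, 1)
  i <- rep(seq_len(n - p), each = p + 1L)
  j <- as.vector(outer(0:p, seq_len(n - p), "+"))
  D <- Matrix::sparseMatrix(i = i, j = j, x = rep(coefs, n - p),
                            dims = c(n - p, n))
  Matrix::forceSymmetric(Matrix::crossprod(D))
}

#' Weighted Whittaker smoothing
#'
#' Solves the penalized least-squares system `(W + lambda * D'D) z = W y`
#' with `W = diag(weights)`, i.e. a weighted Whittaker smoother with an
#' order-`p` difference penalty. The solve uses a banded Cholesky
#' factorization, so cost and memory are linear in `length(y)`.
#'
#' @param y Numeric vector of intensities (finite).
#' @param weights Nonnegative weights, same length as `y`, not all zero.
#' @param lambda Smoothness weight, `> 0`; larger values give smoother `z`.
#' @param p Difference order (1 or 2).
#' @return The smoothed vector `z`.
#' @export
#' @examples
#' y <- sin(seq(0, pi, length.out = 50)) + rnorm(50, sd = 0.05)
#' z <- whittaker_smooth(y, rep(1, 50), lambda = 100)
whittaker_smooth <- function(y, weights = rep(1, length(y)), lambda, p = 2L) {
  if (length(weights) != length(y)) abort("`weights` must match `y` in length.")
  if (any(!is.finite(y))) abort("`y` must be finite.")
  if (any(weights < 0) || all(weights == 0)) {
    abort("`weights` must be nonnegative with at least one positive entry.")
  }
  if (!is.finite(lambda) || lambda <= 0) abort("`lambda` must be positive.")
  p <- as.integer(p)
  if (!p %in% c(1L, 2L)) abort("`p` must be 1 or 2.")
  if (length(y) <= p) abort("`y` must be longer than the difference order.")
  .whittaker_solve_cpp(as.numeric(y), as.numeric(weights), lambda, p)
}

#' airPLS channel reweighting
#'
#' One step of the adaptive reweighting used by airPLS. Channels at or above
#' the current baseline (`residuals >= 0`) get weight 0 so peaks stop pulling
#' the fit upward; channels below get `exp(iteration * |d_i| / m)` where `m`
#' is the total negative-residual mass, so the deepest undershoots dominate
#' as iterations progress. The first and last channel are anchored at the
#' maximum weight, which keeps the penalized system nonsingular when few
#' channels remain weighted. The exponent is clipped at 700 and `m` floored
#' at `.Machine$double.eps * total_mass` for overflow safety.
#'
#' This function isolates the reweighting dialect: swap it to explore
#' variants from the airPLS literature.
#'
#' @param residuals `y - z` at the current iterate.
#' @param iteration Iteration counter `t >= 1`.
#' @param total_mass `sum(abs(y))`, used only for the `m` floor.
#' @return Nonnegative weight vector (raw scale, maximum can exceed 1).
#' @export
airpls_weights <- function(residuals, iteration, total_mass = sum(abs(residuals))) {
  neg <- residuals < 0
  m <- sum(-residuals[neg])
  m <- max(m, .Machine$double.eps * total_mass, .Machine$double.xmin)
  w <- numeric(length(residuals))
  a <- pmin(iteration * (-residuals[neg]) / m, 700)
  w[neg] <- exp(a)
  aend <- min(iteration * max(c(0, -residuals[neg])) / m, 700)
  w[1] <- exp(aend)
  w[length(w)] <- w[1]
  w
}

#' Fit an airPLS baseline
#'
#' Adaptive iteratively reweighted penalized least squares (airPLS) baseline
#' estimation. Starting from uniform weights, alternates a weighted
#' Whittaker smooth with downweighting of channels above the current
#' baseline, stopping once the negative-residual mass falls below
#' `tau * sum(abs(intensity))` or `max_iter` is reached. The defaults
#' `(lambda = 100, tau = 1e-3, p = 1)` are the conventional airPLS defaults
#' ("DP" mode); parameter-optimized fitting uses `p = 2` with tuned
#' `(lambda, tau)`.
#'
#' @param data A spectrum data frame (`wavenumber`, `intensity`).
#' @param lambda Smoothness weight `> 0`.
#' @param tau Convergence tolerance in `(0, 1)`.
#' @param p Difference order (1 or 2).
#' @param max_iter Maximum number of reweighting iterations.
#'
#' @return An object of class `airpls_fit`. `tidy()` returns the per-channel
#'   table (`wavenumber`, `intensity`, `baseline`, `corrected`, `weight`);
#'   `glance()` a one-row summary; `autoplot()` a diagnostic plot. Reported
#'   weights are normalized to `[0, 1]` (divided by their maximum, stored
#'   as `weight_max`; the raw iteration weights are `weight * weight_max`).
#' @export
#' @examples
#' sp <- generate_spectrum("D&E", seed = 1)
#' fit <- airpls(sp, lambda = 1e5, tau = 1e-6, p = 2)
#' glance(fit)
airpls <- function(data, lambda = 100, tau = 1e-3, p = 1L, max_iter = 100L) {
  data <- as_spectrum(data)
  check_spectrum(data)
  if (!is.finite(lambda) || lambda <= 0) abort("`lambda` must be positive.")
  if (!is.finite(tau) || tau <= 0 || tau >= 1) abort("`tau` must lie in (0, 1).")
  p <- as.integer(p)
  if (!p %in% c(1L, 2L)) abort("`p` must be 1 or 2.")
  if (max_iter < 1) abort("`max_iter` must be a positive integer.")
  y <- as.numeric(data$intensity)
  res <- .airpls_cpp(y, lambda, tau, p, as.integer(max_iter))
  w <- res$weights
  wmax <- max(w)
  structure(
    list(
      data = tibble(
        wavenumber = data$wavenumber,
        intensity = y,
        baseline = res$baseline,
        corrected = y - res$baseline,
        weight = if (wmax > 0) w / wmax else w
      ),
      lambda = lambda, tau = tau, p = p, max_iter = as.integer(max_iter),
      iterations = res$iterations, converged = res$converged,
      weight_max = wmax
    ),
    class = "airpls_fit"
  )
}

#' @export
print.airpls_fit <- function(x, ...) {
  cat("airPLS baseline fit\n")
  cat(sprintf("  lambda = %g, tau = %g, p = %d\n", x$lambda, x$tau, x$p))
  cat(sprintf("  %d channels; %d iteration(s); converged: %s\n",
              nrow(x$data), x$iterations, x$converged))
  invisible(x)
}

#' @rdname airpls
#' @param x,object An `airpls_fit`.
#' @param ... Unused.
#' @export
tidy.airpls_fit <- function(x, ...) x$data

#' @rdname airpls
#' @export
glance.airpls_fit <- function(x, ...) {
  tibble(
    lambda = x$lambda, tau = x$tau, p = x$p,
    iterations = x$iterations, converged = x$converged,
    baseline_mean = mean(x$data$baseline),
    corrected_min = min(x$data$corrected)
  )
}

#' @rdname airpls
#' @export
autoplot.airpls_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$data[, c("wavenumber", "intensity", "baseline", "corrected")],
    -"wavenumber", names_to = "component", values_to = "value"
  )
  d$component <- factor(d$component, c("intensity", "baseline", "corrected"))
  ggplot2::ggplot(d, ggplot2::aes(.data$wavenumber, .data$value,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("Wavenumber (", cm^-1, ")")),
                  y = "Intensity (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}
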