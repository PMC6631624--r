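#' Fit the wound closure velocity and lag time
#'
#' After wounding, the normalized area A/A0 typically stays near 1 for a
#' lag time tL and then declines at a constant rate; the magnitude of
#' that linear slope is the closure velocity alpha. The linear range is
#' detected by a continuous two-segment piecewise-linear fit (flat lag
#' followed by a declining line), scanning every admissible breakpoint
#' and keeping the least-squares optimum. The breakpoint is tL; alpha is
#' the magnitude of the declining slope.
#'
#' A series that never declines (best slope `>= 0`) returns `alpha = 0`
#' with `no_closure = TRUE`. A lag longer than half the record triggers
#' a warning (little linear range left to fit).
#'
#' @param series [wound_time_series()] (or data.frame with `time_h` and
#'   `a_over_a0`), at least 5 points, first value 1.
#' @return An object of class `closure_fit`: list with `alpha` (1/h,
#'   `>= 0`), `t_lag` (h; `NA` when no closure), `r_squared`, `window`
#'   (indices of the fitted linear range), `slope` (signed),
#'   `no_closure`.
#' @examples
#' t <- seq(0, 10, 0.5)
#' fit_closure_velocity(wound_time_series(t, 1000 * pmax(1 - 0.05 * t, 0)))
#' @export
fit_closure_velocity <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "a_over_a0") %in% names(series)))
  t <- series$time_h
  a <- series$a_over_a0
  n <- length(t)
  if (n < 5) stop("need at least 5 points to fit a closure velocity")
  if (abs(a[1] - 1) > 1e-9) stop("series is not normalized: first value must be 1")

  min_tail <- 5L  # a slope from fewer points is refused
  best <- NULL
  for (j in seq_len(n - min_tail)) {
    z <- pmax(t - t[j], 0)
    fit <- stats::lm.fit(cbind(1, z), a)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, j = j, coef = fit$coefficients)
  }
  slope <- unname(best$coef[2])
  sst <- sum((a - mean(a))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - best$sse / sst)) else NA_real_
  if (!is.finite(slope) || slope >= -1e-10) {
    return(structure(list(alpha = 0, t_lag = NA_real_, r_squared = r2,
                          window = c(best$j, n), slope = unname(slope),
                          no_closure = TRUE),
                     class = "closure_fit"))
  }
  t_lag <- t[best$j] - t[1]
  if (t_lag > 0.5 * (t[n] - t[1]))
    warning(sprintf("lag time (%.2g h) exceeds half the record; alpha is fit on few points",
                    t_lag))
  structure(list(alpha = -slope, t_lag = t_lag, r_squared = r2,
                 window = c(best$j, n), slope = slope, no_closure = FALSE),
            class = "closure_fit")
}

#' @export
print.closure_fit <- function(x, ...) {
  if (x$no_closure) {
    cat("closure_fit: no closure detected (alpha = 0)\n")
  } else {
    cat(sprintf("closure_fit: alpha = %.4g 1/h, t_lag = %.3g h, R^2 = %.3f\n",
                x$alpha, x$t_lag, x$r_squared))
  }
  invisible(x)
}

#' Wound-edge propagation speed from the closure velocity
#'
#' For a straight wound of initial width b closing from both sides, the
#' normalized area shrinks at rate alpha when each edge advances at
#' `v = alpha * b / 2`.
#'
#' @param fit [fit_closure_velocity()] result, or a plain alpha (1/h).
#' @param b initial wound width (um), `> 0`.
#' @return Edge speed v (um/h).
#' @export
edge_speed <- function(fit, b) {
  stopifnot(b > 0)
  alpha <- if (inherits(fit, "closure_fit")) fit$alpha else fit
  stopifnot(is.numeric(alpha), alpha >= 0)
  alpha * b / 2
}

#' Fit the population doubling time
#'
#' Fits the doubling law `n(t) = n0 * 2^((t - t0)/tau)` with `n0` pinned
#' to the first observation, so the doubling time is the only adjustable
#' parameter. The fit is linear least squares in log2 space through the
#' origin, hence exact on noiseless data.
#'
#' @param growth [growth_curve()] (or data.frame with `time_h`,
#'   `count`), at least 3 points, positive counts.
#' @return An object of class `logistic_fit`: list with `n0`, `tau` (h),
#'   `residual` (RMS log2 residual).
#' @examples
#' fit_doubling_time(growth_curve(c(0, 24, 48), c(100, 200, 400)))
#' @export
fit_doubling_time <- function(growth) {
  stopifnot(is.data.frame(growth),
            all(c("time_h", "count") %in% names(growth)))
  t <- growth$time_h
  n <- growth$count
  if (length(t) < 3) stop("need at least 3 time points")
  stopifnot(all(n > 0))
  t0 <- t[1]
  y <- log2(n / n[1])
  z <- t - t0
  rate <- sum(z * y) / sum(z^2)  # doublings per hour
  if (!is.finite(rate) || rate <= 0)
    stop("counts do not increase: no growth to fit")
  tau <- 1 / rate
  residual <- sqrt(mean((y - rate * z)^2))
  structure(list(n0 = n[1], tau = tau, residual = residual),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: tau = %.4g h (n0 = %g, RMS log2 residual %.3g)\n",
              x$tau, x$n0, x$residual))
  invisible(x)
}

#' Growth kinetic constant from the doubling time
#'
#' `k = ln(2) / tau`, the exponential rate equivalent to doubling every
#' tau hours.
#'
#' @param tau doubling time (h), `> 0` (may be `Inf`).
#' @return k (1/h).
#' @export
growth_rate <- function(tau) {
  stopifnot(is.numeric(tau), all(tau > 0))
  log(2) / tau
}

#' Random motility coefficient from the edge speed
#'
#' Inverts the Fisher-KPP traveling-wave speed relation: a front moving
#' at `v = 2 sqrt(D k)` with `k = ln(2)/tau` implies
#' `D = tau * v^2 / (4 ln 2)`.
#'
#' @param v edge propagation speed (um/h), `>= 0`.
#' @param tau doubling time (h), `> 0`.
#' @return D (um^2/h).
#' @export
motility_from_speed <- function(v, tau) {
  stopifnot(is.numeric(v), all(v >= 0), is.numeric(tau), all(tau > 0))
  tau * v^2 / (4 * log(2))
}

#' Fisher-KPP front speed from motility and doubling time
#'
#' `v = sqrt(4 D ln(2) / tau)`, i.e. the classical minimum wave speed
#' `2 sqrt(D k)` with `k = ln(2)/tau`. Exact inverse of
#' [motility_from_speed()].
#'
#' @param D random motility coefficient (um^2/h), `>= 0`.
#' @param tau doubling time (h), `> 0`.
#' @return v (um/h).
#' @export
forward_speed <- function(D, tau) {
  stopifnot(is.numeric(D), all(D >= 0), is.numeric(tau), all(tau > 0))
  sqrt(4 * D * log(2) / tau)
}

#' Thiele modulus of wound closure
#'
#' Dimensionless group comparing proliferation to motility over the
#' wound width: large values mean closure is proliferation-dominated,
#' small values migration-dominated. The default is the standard
#' first-order form `phi = b * sqrt(k / D)`, which is dimensionless;
#' `literal = TRUE` gives the alternative ratio `b^2 * k / D` (the
#' squared modulus) for comparison.
#'
#' @param b initial wound width (um), `> 0`.
#' @param k growth kinetic constant (1/h), `> 0`.
#' @param D random motility coefficient (um^2/h), `> 0`.
#' @param literal return `b^2 k / D` instead of `b sqrt(k/D)`.
#' @return phi (dimensionless).
#' @export
thiele_modulus <- function(b, k, D, literal = FALSE) {
  stopifnot(all(b > 0), all(k > 0), all(D > 0))
  if (literal) b^2 * k / D else b * sqrt(k / D)
}

#' Motility estimate for one condition
#'
#' Combines the closure fit, the initial wound width and the
#' independently fitted doubling time into the model's derived
#' quantities: edge speed `v = alpha b / 2`, growth constant
#' `k = ln2/tau`, random motility `D = tau v^2 / (4 ln 2)` and the
#' Thiele modulus.
#'
#' @param fit [fit_closure_velocity()] result or plain alpha (1/h).
#' @param b initial wound width (um).
#' @param tau doubling time (h).
#' @return An object of class `motility_estimate`: list with `alpha`,
#'   `b`, `tau`, `v`, `k`, `D`, `phi` (phi is `NA` when `v = 0`).
#' @export
motility_estimate <- function(fit, b, tau) {
  alpha <- if (inherits(fit, "closure_fit")) fit$alpha else fit
  v <- edge_speed(alpha, b)
  k <- growth_rate(tau)
  D <- motility_from_speed(v, tau)
  phi <- if (D > 0) thiele_modulus(b, k, D) else NA_real_
  structure(list(alpha = alpha, b = b, tau = tau, v = v, k = k, D = D,
                 phi = phi),
            class = "motility_estimate")
}

#' @export
print.motility_estimate <- function(x, ...) {
  cat("motility_estimate\n")
  cat(sprintf("  alpha = %.4g 1/h, b = %g um -> v = %.4g um/h\n",
              x$alpha, x$b, x$v))
  cat(sprintf("  tau = %.4g h (k = %.4g 1/h) -> D = %.4g um^2/h, phi = %.3g\n",
              x$tau, x$k, x$D, x$phi))
  invisible(x)
}
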