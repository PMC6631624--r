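#' Cell density field on a 1D grid
#'
#' Container for the Fisher-KPP state u(x, t): a snapshot-times vector
#' and a matrix of densities with one row per time and one column per
#' grid node.
#'
#' @param times strictly increasing snapshot times (h).
#' @param values numeric matrix, `length(times)` rows x `grid$n_nodes`
#'   columns, densities `>= 0`.
#' @param grid a [grid_1d()] object.
#' @return An object of class `density_field`.
#' @export
density_field <- function(times, values, grid) {
  values <- matrix(values, nrow = length(times))
  stopifnot(inherits(grid, "grid_1d"),
            ncol(values) == grid$n_nodes,
            all(is.finite(values)), all(values >= 0),
            length(times) >= 1, all(diff(times) > 0))
  structure(list(times = as.numeric(times), values = values, grid = grid),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("density_field: %d snapshot(s) x %d nodes, t in [%g, %g] h\n",
              length(x$times), ncol(x$values),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Scratch-wound initial condition
#'
#' Builds the t = 0 density profile of a scratch assay: confluent
#' density `u_hat` everywhere except a centered cell-free interval of
#' width `b` (the freshly scraped wound), where the density is zero.
#'
#' @param params [fk_parameters()]; `b` must be narrower than the domain.
#' @param grid [grid_1d()].
#' @return A single-snapshot [density_field()] at t = 0.
#' @examples
#' g <- grid_1d(0, 2000, 401, t_end = 18)
#' p <- fk_parameters(D = 600, tau = 20, b = 500)
#' init <- make_scratch_initial_condition(p, g)
#' @export
make_scratch_initial_condition <- function(params, grid) {
  stopifnot(inherits(params, "fk_parameters"), inherits(grid, "grid_1d"))
  if (params$b >= (grid$x_max - grid$x_min))
    stop("invalid parameters: wound width b (", params$b,
         " um) must be smaller than the domain (",
         grid$x_max - grid$x_min, " um)")
  center <- (grid$x_min + grid$x_max) / 2
  u <- ifelse(abs(grid$x - center) <= params$b / 2, 0, params$u_hat)
  density_field(0, matrix(u, nrow = 1), grid)
}

#' FTCS stability limit
#'
#' Largest stable time step of the explicit central-difference scheme,
#' `dx^2 / (2 D)`. Infinite when `D = 0`.
#'
#' @param D random motility coefficient (um^2/h).
#' @param dx grid spacing (um).
#' @return Maximum stable `dt` (h).
#' @export
fk_stability_limit <- function(D, dx) {
  stopifnot(D >= 0, dx > 0)
  if (D == 0) Inf else dx^2 / (2 * D)
}

stability_error <- function(dt, limit) {
  stop(structure(class = c("wk_stability_error", "error", "condition"),
                 list(message = sprintf(
                   paste0("unstable time step: dt = %g h exceeds the FTCS ",
                          "stability limit dx^2/(2D) = %g h; reduce dt or ",
                          "refine the grid"), dt, limit),
                   call = sys.call(-1))))
}

#' Integrate the 1D Fisher-Kolmogoroff equation
#'
#' Explicit forward-time central-space (FTCS) integration of
#' `du/dt = D u_xx + k u (1 - u/u_hat)` with no-flux boundaries. The
#' boundary stencil is the cell-centered finite-volume one (single-sided
#' difference), so with `k = 0` the total mass `sum(u) * dx` is
#' conserved to machine precision. The scheme refuses to run when the
#' requested `dt` violates the stability limit `dx^2/(2D)`; with
#' `dt = NA` a step at 80% of the limit is chosen and rounded down so
#' snapshots fall exactly on multiples of `grid$save_every`.
#'
#' @param init single-snapshot [density_field()] (the initial condition).
#' @param params [fk_parameters()].
#' @param grid [grid_1d()]; must be the grid `init` was built on.
#' @param output_times times at which to store snapshots; default
#'   `seq(0, t_end, by = save_every)`. Must start at `init$times`.
#' @return A [density_field()] with one row per output time.
#' @examples
#' g <- grid_1d(0, 2000, 201, t_end = 6, save_every = 1)
#' p <- fk_parameters(D = 300, tau = 20, b = 500)
#' u <- simulate_fk_1d(make_scratch_initial_condition(p, g), p, g)
#' @export
simulate_fk_1d <- function(init, params, grid, output_times = NULL) {
  stopifnot(inherits(init, "density_field"), inherits(params, "fk_parameters"),
            inherits(grid, "grid_1d"))
  if (ncol(init$values) != grid$n_nodes)
    stop("initial condition is not defined on `grid`")
  if (is.null(output_times))
    output_times <- seq(init$times[1], init$times[1] + grid$t_end,
                        by = grid$save_every)
  stopifnot(length(output_times) >= 2, all(diff(output_times) > 0),
            abs(output_times[1] - init$times[1]) < 1e-12)

  D <- params$D; k <- params$k; u_hat <- params$u_hat
  dx <- grid$dx
  limit <- fk_stability_limit(D, dx)
  if (!is.na(grid$dt)) {
    if (grid$dt > limit * (1 + 1e-12)) stability_error(grid$dt, limit)
    dt_max <- grid$dt
  } else {
    dt_max <- min(0.8 * limit, 0.1 / max(k, 1e-12),
                  min(diff(output_times)))
  }

  n <- grid$n_nodes
  u <- as.numeric(init$values[nrow(init$values), ])
  out <- matrix(NA_real_, nrow = length(output_times), ncol = n)
  out[1, ] <- u
  r_cache <- NULL
  for (s in seq_len(length(output_times) - 1)) {
    span <- output_times[s + 1] - output_times[s]
    n_sub <- max(1L, ceiling(span / dt_max - 1e-9))
    h <- span / n_sub
    rD <- D * h / dx^2
    for (i in seq_len(n_sub)) {
      lap <- c(u[2] - u[1],
               u[-c(1, 2)] - 2 * u[-c(1, n)] + u[-c(n - 1, n)],
               u[n - 1] - u[n])
      u <- u + rD * lap + h * k * u * (1 - u / u_hat)
    }
    out[s + 1, ] <- u
  }
  if (any(!is.finite(out)))
    stop("Fisher-KPP integration diverged; check dt against the stability limit")
  # guard tiny negative undershoot from the explicit scheme
  out[out < 0 & out > -1e-9 * u_hat] <- 0
  density_field(output_times, out, grid)
}

#' Front position over time
#'
#' Position of the advancing cell front, defined as the level set
#' `u = level * u_hat` of the sheet invading from the left domain edge
#' (the largest x where the density is still at or above the level),
#' located by linear interpolation between grid nodes.
#'
#' @param field [density_field()].
#' @param u_hat confluent density the level is relative to.
#' @param level level-set fraction in (0, 1); default 0.5.
#' @return Numeric vector of front positions (um), `NA` where the level
#'   set is absent or has reached the right boundary.
#' @export
front_positions <- function(field, u_hat, level = 0.5) {
  stopifnot(inherits(field, "density_field"), level > 0, level < 1)
  uc <- level * u_hat
  x <- field$grid$x
  n <- length(x)
  apply(field$values, 1, function(u) {
    above <- which(u >= uc)
    if (length(above) == 0) return(NA_real_)
    i <- max(above)
    if (i == n) return(NA_real_)
    x[i] + (x[i + 1] - x[i]) * (u[i] - uc) / (u[i] - u[i + 1])
  })
}

#' Measure the traveling-front speed of a simulated field
#'
#' Fits the trajectory of the half-maximum level set. Fisher-KPP fronts
#' started from compact initial data approach their asymptotic speed
#' slowly, with a transient that decays like `ln(t)/t`; the default fit
#' therefore uses the model `x(t) = v t - c ln(t) + x0` over the late
#' part of the record, whose linear coefficient is an accurate estimate
#' of the asymptotic speed at moderate horizons. Set
#' `log_correction = FALSE` for a plain linear fit.
#'
#' @param field [density_field()].
#' @param u_hat confluent density.
#' @param level level-set fraction; default 0.5.
#' @param fit_start fraction of the record before which snapshots are
#'   discarded from the fit; default 0.5.
#' @param log_correction include the `ln(t)` transient term (default TRUE).
#' @return Estimated front speed (um/h).
#' @export
estimate_front_speed <- function(field, u_hat, level = 0.5,
                                 fit_start = 0.5, log_correction = TRUE) {
  pos <- front_positions(field, u_hat, level)
  t <- field$times
  keep <- is.finite(pos) & t >= fit_start * max(t) & t > 0
  if (sum(keep) < 4)
    stop("too few usable front positions to fit a speed")
  t <- t[keep]; pos <- pos[keep]
  if (log_correction) {
    fit <- stats::lm(pos ~ t + log(t))
    unname(stats::coef(fit)["t"])
  } else {
    unname(stats::coef(stats::lm(pos ~ t))["t"])
  }
}

#' Total cell mass of a density field
#'
#' `sum(u) * dx` per snapshot - the discrete invariant of the
#' finite-volume no-flux scheme when proliferation is switched off.
#'
#' @param field [density_field()].
#' @return Numeric vector, one value per snapshot.
#' @export
total_cell_mass <- function(field) {
  rowSums(field$values) * field$grid$dx
}
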