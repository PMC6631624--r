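#' Fisher-Kolmogoroff model parameters
#'
#' Bundles the parameters of the reaction-diffusion wound-closure model
#' \deqn{\partial u/\partial t = D \partial^2 u/\partial x^2 + k u (1 - u/\hat u)}
#' together with the initial wound width. Internally the package works in
#' micrometers and hours; `u_hat` may be kept at 1 to work with normalized
#' density.
#'
#' Exactly one of `k` (growth kinetic constant, 1/h) or `tau` (population
#' doubling time, h) must be supplied; they are related by `k = ln(2)/tau`.
#'
#' @param D random motility coefficient (um^2/h), `>= 0`.
#' @param tau population doubling time (h), `> 0`; mutually exclusive with `k`.
#' @param k growth kinetic constant (1/h), `>= 0`; mutually exclusive with `tau`.
#' @param u_hat maximum (confluent) cell density; `> 0`. Default 1 (normalized).
#' @param b initial wound width (um), `> 0`.
#' @return An object of class `fk_parameters`: list with `D`, `k`, `tau`,
#'   `u_hat`, `b`.
#' @examples
#' fk_parameters(D = 600, tau = 20, b = 1000)
#' @export
fk_parameters <- function(D, tau = NULL, k = NULL, u_hat = 1, b) {
  if (is.null(tau) == is.null(k))
    stop("supply exactly one of `tau` or `k`")
  if (!is.null(tau)) {
    stopifnot(is.numeric(tau), length(tau) == 1, tau > 0)
    k <- log(2) / tau
  } else {
    stopifnot(is.numeric(k), length(k) == 1, k >= 0)
    tau <- if (k > 0) log(2) / k else Inf
  }
  stopifnot(is.numeric(D), length(D) == 1, D >= 0,
            is.numeric(u_hat), length(u_hat) == 1, u_hat > 0,
            is.numeric(b), length(b) == 1, b > 0)
  structure(list(D = D, k = k, tau = tau, u_hat = u_hat, b = b),
            class = "fk_parameters")
}

#' @export
print.fk_parameters <- function(x, ...) {
  cat("Fisher-Kolmogoroff parameters\n")
  cat(sprintf("  D     = %g um^2/h\n", x$D))
  cat(sprintf("  tau   = %g h  (k = %g 1/h)\n", x$tau, x$k))
  cat(sprintf("  u_hat = %g\n", x$u_hat))
  cat(sprintf("  b     = %g um (initial wound width)\n", x$b))
  invisible(x)
}

#' 1D simulation grid
#'
#' Uniform spatial grid and time-stepping contract for the explicit
#' finite-difference Fisher-KPP solver. When `dt` is `NA` (default) the
#' solver chooses a stable step automatically (80% of the FTCS stability
#' limit `dx^2 / (2 D)`); an explicit `dt` that violates the limit makes
#' [simulate_fk_1d()] refuse with a stability error.
#'
#' @param x_min,x_max domain bounds (um), `x_max > x_min`.
#' @param n_nodes number of grid nodes, `>= 3`.
#' @param t_end simulation horizon (h), `> 0`.
#' @param save_every interval between stored snapshots (h); default stores
#'   73 snapshots over `t_end` (matching 15-min frames over 18 h).
#' @param dt explicit time step (h), or `NA` to auto-select.
#' @return An object of class `grid_1d` with fields `x_min`, `x_max`,
#'   `n_nodes`, `dx`, `x`, `dt`, `t_end`, `save_every`.
#' @export
grid_1d <- function(x_min, x_max, n_nodes, t_end,
                    save_every = t_end / 72, dt = NA_real_) {
  stopifnot(is.numeric(x_min), is.numeric(x_max), x_max > x_min,
            is.numeric(n_nodes), length(n_nodes) == 1, n_nodes >= 3,
            n_nodes == round(n_nodes),
            is.numeric(t_end), t_end > 0,
            is.numeric(save_every), save_every > 0, save_every <= t_end)
  if (!is.na(dt)) stopifnot(is.numeric(dt), dt > 0)
  dx <- (x_max - x_min) / (n_nodes - 1)
  structure(list(x_min = x_min, x_max = x_max, n_nodes = as.integer(n_nodes),
                 dx = dx, x = seq(x_min, x_max, length.out = n_nodes),
                 dt = dt, t_end = t_end, save_every = save_every),
            class = "grid_1d")
}

#' @export
print.grid_1d <- function(x, ...) {
  cat(sprintf("1D grid: [%g, %g] um, %d nodes (dx = %g um)\n",
              x$x_min, x$x_max, x$n_nodes, x$dx))
  cat(sprintf("  t_end = %g h, snapshots every %g h, dt = %s\n",
              x$t_end, x$save_every,
              if (is.na(x$dt)) "auto" else format(x$dt)))
  invisible(x)
}

#' Rendering configuration for synthetic phase-contrast stacks
#'
#' Controls how a simulated density field is turned into a grayscale
#' time-lapse. Cell-occupied pixels (density at or above
#' `occupancy_threshold * u_hat`) receive zero-mean speckle of standard
#' deviation `cell_texture_amplitude` on top of the uniform background;
#' all pixels receive Gaussian read noise of standard deviation
#' `noise_sd`. Intensities are clipped to [0, 1]. The ground-truth wound
#' mask marks the sub-threshold (cell-free) region.
#'
#' @param pixel_size physical pixel size (um/pixel), `> 0`.
#' @param frame_shape integer `c(height, width)` in pixels, or `NULL`
#'   (default) to derive the width from the simulated domain.
#' @param background uniform background intensity in [0, 1].
#' @param cell_texture_amplitude speckle standard deviation on
#'   cell-occupied pixels (intensity units).
#' @param noise_sd per-pixel Gaussian noise standard deviation, `>= 0`.
#' @param occupancy_threshold density fraction of `u_hat` above which a
#'   pixel is considered cell-covered; in (0, 1).
#' @param seed integer seed; the same seed and configuration give a
#'   bit-identical stack.
#' @return An object of class `render_config`.
#' @export
render_config <- function(pixel_size = 4, frame_shape = NULL,
                          background = 0.35, cell_texture_amplitude = 0.25,
                          noise_sd = 0.02, occupancy_threshold = 0.2,
                          seed = 1L) {
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            is.numeric(background), background >= 0, background <= 1,
            is.numeric(cell_texture_amplitude), cell_texture_amplitude >= 0,
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(occupancy_threshold),
            occupancy_threshold > 0, occupancy_threshold < 1,
            is.numeric(seed), length(seed) == 1)
  if (!is.null(frame_shape))
    stopifnot(length(frame_shape) == 2, all(frame_shape >= 1))
  structure(list(pixel_size = pixel_size, frame_shape = frame_shape,
                 background = background,
                 cell_texture_amplitude = cell_texture_amplitude,
                 noise_sd = noise_sd,
                 occupancy_threshold = occupancy_threshold,
                 seed = as.integer(seed)),
            class = "render_config")
}

#' Segmentation settings
#'
#' Knobs of the texture-based wound segmentation: a local
#' standard-deviation filter of side `window` pixels produces a texture
#' map; Otsu's method splits it into textured (cells) and smooth (wound)
#' classes; morphological closing then opening with a disc of radius
#' `morph_radius` cleans the mask; the largest smooth component touching
#' the wound axis (`axis_col`, default the frame's center column) is
#' kept. When the Otsu split is not informative (the two texture classes
#' differ by less than `min_separation` in their mean ratio), the
#' absolute fallback `texture < min_texture` decides, which maps a fully
#' confluent frame to an empty mask and an empty frame to a full one.
#'
#' @param window side of the square local-sd window (pixels, odd).
#' @param morph_radius radius of the disc structuring element (pixels).
#' @param min_texture absolute texture level (intensity units) below
#'   which a pixel counts as cell-free when the Otsu split is degenerate.
#' @param min_separation maximum ratio of smooth-class to textured-class
#'   mean texture for the Otsu split to be considered informative.
#' @param axis_col column index the wound component must touch, or
#'   `NULL` for the frame's center column.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(window = 15, morph_radius = 7,
                                min_texture = 0.05, min_separation = 0.5,
                                axis_col = NULL) {
  stopifnot(window >= 3, window %% 2 == 1, morph_radius >= 1,
            min_texture > 0, min_separation > 0, min_separation < 1)
  structure(list(window = as.integer(window),
                 morph_radius = as.integer(morph_radius),
                 min_texture = min_texture, min_separation = min_separation,
                 axis_col = axis_col),
            class = "segmentation_config")
}
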