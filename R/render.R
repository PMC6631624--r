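#' Grayscale time-lapse stack
#'
#' Ordered grayscale frames with acquisition times and physical pixel
#' size; the in-memory form of a multi-frame TIFF.
#'
#' @param frames list of numeric matrices in [0, 1], all the same shape.
#' @param times strictly increasing acquisition times (h).
#' @param pixel_size physical pixel size (um/pixel).
#' @param gt_masks optional list of ground-truth wound masks (logical
#'   matrices, TRUE = wound), one per frame; carried by the synthetic
#'   renderer.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, times, pixel_size, gt_masks = NULL) {
  stopifnot(is.list(frames), length(frames) == length(times),
            length(frames) >= 1, all(diff(times) > 0), pixel_size > 0)
  shp <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), shp), logical(1))
  if (!all(ok)) stop("all frames must have the same shape")
  if (!is.null(gt_masks)) stopifnot(length(gt_masks) == length(frames))
  structure(list(frames = frames, times = as.numeric(times),
                 pixel_size = pixel_size, gt_masks = gt_masks),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  shp <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d frame(s) of %d x %d px (%g um/px), t in [%g, %g] h%s\n",
              length(x$frames), shp[1], shp[2], x$pixel_size,
              min(x$times), max(x$times),
              if (is.null(x$gt_masks)) "" else ", with ground-truth masks"))
  invisible(x)
}

#' Render a density field into a phase-contrast-like time-lapse
#'
#' Extrudes a 1D density profile into 2D frames of a vertical wound
#' stripe, the closure direction running horizontally. A pixel column is
#' cell-covered when the local density reaches
#' `occupancy_threshold * u_hat`; covered pixels carry zero-mean speckle
#' (local texture), mimicking how confluent cells appear under phase
#' contrast, while the cell-free wound stays smooth. Per-pixel Gaussian
#' read noise is added everywhere and intensities are clipped to [0, 1].
#' A ground-truth wound mask (the sub-threshold region) is attached per
#' frame. Rendering is bit-reproducible for a fixed seed and leaves the
#' global RNG state untouched.
#'
#' @param field [density_field()]; values must not exceed `u_hat`.
#' @param cfg [render_config()].
#' @param u_hat confluent density used to normalize the field; default 1.
#' @return An [image_stack()] with `gt_masks` filled in.
#' @examples
#' g <- grid_1d(0, 800, 161, t_end = 2, save_every = 1)
#' p <- fk_parameters(D = 300, tau = 20, b = 300)
#' u <- simulate_fk_1d(make_scratch_initial_condition(p, g), p, g)
#' stack <- render_timelapse(u, render_config(pixel_size = 4, seed = 7))
#' @export
render_timelapse <- function(field, cfg, u_hat = 1) {
  stopifnot(inherits(field, "density_field"), inherits(cfg, "render_config"))
  if (max(field$values) > u_hat * (1 + 1e-6))
    stop("field values exceed u_hat; pass the correct `u_hat`")
  extent <- field$grid$x_max - field$grid$x_min
  width <- as.integer(round(extent / cfg$pixel_size))
  height <- 160L
  if (!is.null(cfg$frame_shape)) {
    height <- as.integer(cfg$frame_shape[1])
    if (cfg$frame_shape[2] < width)
      stop(sprintf(paste0("frame too small: %d px at %g um/px cannot hold ",
                          "the %g um domain (needs %d px)"),
                   cfg$frame_shape[2], cfg$pixel_size, extent, width))
    width <- as.integer(cfg$frame_shape[2])
  }
  if (width < 3 || height < 3) stop("frame too small to render")
  # pixel-center positions along the closure axis
  px_x <- field$grid$x_min + (seq_len(width) - 0.5) * extent / width
  px_x <- pmin(pmax(px_x, field$grid$x_min), field$grid$x_max)
  uc <- cfg$occupancy_threshold * u_hat

  withr::with_seed(cfg$seed, {
    frames <- vector("list", length(field$times))
    masks <- vector("list", length(field$times))
    for (i in seq_along(field$times)) {
      u_px <- stats::approx(field$grid$x, field$values[i, ], xout = px_x,
                            rule = 2)$y
      occ <- u_px >= uc
      occ_mat <- matrix(rep(occ, each = height), nrow = height)
      img <- matrix(cfg$background, nrow = height, ncol = width)
      if (cfg$cell_texture_amplitude > 0 && any(occ)) {
        speckle <- matrix(stats::rnorm(height * width,
                                       sd = cfg$cell_texture_amplitude),
                          nrow = height)
        img <- img + speckle * occ_mat
      }
      if (cfg$noise_sd > 0)
        img <- img + matrix(stats::rnorm(height * width, sd = cfg$noise_sd),
                            nrow = height)
      frames[[i]] <- pmin(pmax(img, 0), 1)
      masks[[i]] <- !occ_mat
    }
    image_stack(frames, field$times, cfg$pixel_size, gt_masks = masks)
  })
}

#' Write an image stack as multi-frame TIFF plus JSON sidecar
#'
#' The sidecar (`<path>.json`) records acquisition times, pixel size and
#' any extra metadata (e.g. ground-truth parameters and seeds), so a
#' stack on disk round-trips through [read_image_stack()].
#'
#' @param stack [image_stack()].
#' @param path output TIFF path.
#' @param metadata optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, metadata = list()) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(stack$frames, path, bits.per.sample = 16L)
  sidecar <- c(list(times_h = stack$times, pixel_size_um = stack$pixel_size),
               metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-frame TIFF stack (with optional JSON sidecar)
#'
#' @param path TIFF path. If `<path>.json` exists, times and pixel size
#'   are taken from it; otherwise they must be supplied.
#' @param times,pixel_size overrides / fallbacks for missing sidecar.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, times = NULL, pixel_size = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (is.null(times)) times <- sc$times_h
    if (is.null(pixel_size)) pixel_size <- sc$pixel_size_um
  }
  if (is.null(times) || is.null(pixel_size))
    stop("no sidecar found; supply `times` and `pixel_size`")
  image_stack(frames, times, pixel_size)
}
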