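#' Normalized wound-area time series
#'
#' @param times acquisition times (h).
#' @param areas wound areas (um^2), one per frame; the first must be
#'   positive (it is the normalization A0).
#' @return Data.frame with columns `time_h`, `area_um2`, `a_over_a0`
#'   (first element exactly 1) and class `wound_time_series`.
#' @export
wound_time_series <- function(times, areas) {
  stopifnot(length(times) == length(areas), all(diff(times) > 0),
            all(areas >= 0))
  if (areas[1] <= 0)
    stop("A0 = 0: no wound in the first frame, cannot normalize")
  a0 <- areas[1]
  structure(data.frame(time_h = as.numeric(times),
                       area_um2 = as.numeric(areas),
                       a_over_a0 = as.numeric(areas) / a0),
            class = c("wound_time_series", "data.frame"))
}

# local standard deviation in a w x w box, replicate boundary
local_texture_sd <- function(frame, window) {
  f <- matrix(1 / window^2, window, window)
  m1 <- EBImage::filter2(frame, f, boundary = "replicate")
  m2 <- EBImage::filter2(frame^2, f, boundary = "replicate")
  sqrt(pmax(m2 - m1^2, 0))
}

#' Segment the cell-free wound region of one frame
#'
#' Texture-based segmentation of phase-contrast frames: cell-covered
#' regions are locally rough, the cell-free wound is smooth. The frame's
#' local standard deviation map is thresholded by Otsu's method
#' (wound = low texture), the raw mask is cleaned by morphological
#' closing then opening, and the largest wound component touching the
#' wound axis is kept. Adding a constant to all pixel intensities leaves
#' the mask unchanged.
#'
#' Degenerate frames are resolved by the absolute texture fallback of
#' [segmentation_config()]: a frame with texture everywhere (confluent
#' monolayer, wound closed) yields an empty mask, a frame with no
#' texture anywhere (no cells) yields a full-frame mask. A perfectly
#' constant frame returns a full-frame mask carrying attribute
#' `flag = "constant-frame"` along with a warning.
#'
#' @param frame numeric matrix (grayscale image), finite values.
#' @param config [segmentation_config()].
#' @return Logical matrix (TRUE = wound), possibly with attribute `flag`.
#' @export
segment_wound <- function(frame, config = segmentation_config()) {
  stopifnot(is.matrix(frame), all(is.finite(frame)),
            inherits(config, "segmentation_config"))
  sdmap <- local_texture_sd(frame, config$window)
  rng <- max(sdmap)
  if (rng <= 1e-6) {  # constant frame up to convolution round-off
    warning("constant-intensity frame: no texture anywhere, returning full mask")
    mask <- matrix(TRUE, nrow(frame), ncol(frame))
    attr(mask, "flag") <- "constant-frame"
    return(mask)
  }
  thr <- EBImage::otsu(EBImage::Image(sdmap / rng)) * rng
  low <- sdmap < thr
  mean_low <- mean(sdmap[low])
  mean_high <- mean(sdmap[!low])
  if (!any(low) || !any(!low) || mean_low / mean_high > config$min_separation) {
    # uninformative split: the frame is essentially one texture class;
    # decide by absolute texture level
    raw <- sdmap < config$min_texture
  } else {
    raw <- low
  }
  if (!any(raw)) return(matrix(FALSE, nrow(frame), ncol(frame)))
  if (all(raw)) return(matrix(TRUE, nrow(frame), ncol(frame)))

  kern <- EBImage::makeBrush(2 * config$morph_radius + 1, shape = "disc")
  m <- EBImage::Image(raw * 1)
  m <- EBImage::opening(EBImage::closing(m, kern), kern)
  lab <- EBImage::bwlabel(m)
  labv <- EBImage::imageData(lab)
  axis_col <- if (is.null(config$axis_col)) ceiling(ncol(frame) / 2)
              else config$axis_col
  touching <- setdiff(unique(labv[, axis_col]), 0)
  if (length(touching) == 0)
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  sizes <- vapply(touching, function(l) sum(labv == l), numeric(1))
  matrix(labv == touching[which.max(sizes)], nrow(frame), ncol(frame))
}

#' Measure the normalized wound-area series of a stack
#'
#' Segments each frame, converts mask pixel counts to physical areas
#' (`pixels * pixel_size^2`), and normalizes by the first frame's area
#' A0. Frames where the wound has fully closed contribute area 0 and are
#' kept, so the series stays aligned with the acquisition times.
#'
#' @param stack [image_stack()] with at least 3 frames.
#' @param config [segmentation_config()].
#' @param keep_masks attach the per-frame masks as attribute `masks`.
#' @return A [wound_time_series()]; attribute `areas` holds the raw
#'   areas, attribute `masks` the masks when requested.
#' @export
measure_area_series <- function(stack, config = segmentation_config(),
                                keep_masks = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) < 3)
    stop("need at least 3 frames to measure a closure series")
  masks <- lapply(stack$frames, segment_wound, config = config)
  areas <- vapply(masks, sum, numeric(1)) * stack$pixel_size^2
  series <- wound_time_series(stack$times, areas)
  if (keep_masks) attr(series, "masks") <- masks
  series
}

#' Initial wound width from the first-frame mask
#'
#' The model's length scale b is the distance between the two wound
#' edges at time 0; for a (possibly ragged) vertical wound stripe this
#' is the mean horizontal extent of the mask across rows:
#' `sum(mask) / nrow(mask) * pixel_size`. A full-frame mask gives the
#' frame width.
#'
#' @param mask0 logical (or 0/1) matrix, the wound mask at t = 0; must
#'   contain at least one wound pixel.
#' @param pixel_size physical pixel size (um/pixel).
#' @return Initial wound width b (um).
#' @export
initial_wound_width <- function(mask0, pixel_size) {
  stopifnot(is.matrix(mask0), pixel_size > 0)
  if (sum(mask0) == 0) stop("empty mask: no wound to measure")
  sum(mask0) / nrow(mask0) * pixel_size
}

#' Write a wound time series as CSV
#'
#' Columns `time_h`, `area_um2`, `a_over_a0`.
#'
#' @param series [wound_time_series()].
#' @param path CSV path.
#' @return `path` (write) or a [wound_time_series()] (read).
#' @export
write_wound_series <- function(series, path) {
  stopifnot(inherits(series, "wound_time_series"))
  utils::write.csv(as.data.frame(unclass(series)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wound_series
#' @export
read_wound_series <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_h", "area_um2") %in% names(df)))
  wound_time_series(df$time_h, df$area_um2)
}

#' Write a mask series as multi-frame TIFF (for audit)
#'
#' @param masks list of logical matrices.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(masks, path) {
  tiff::writeTIFF(lapply(masks, function(m) m * 1), path,
                  bits.per.sample = 8L)
  invisible(path)
}
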