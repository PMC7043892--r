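#' Region-of-interest specification
#'
#' Circular or rectangular ROI in pixel coordinates (1-based pixel centres).
#' Rectangles have integer height/width and cover whole pixels; circles
#' include every pixel whose centre lies within `radius_px` of `centre`.
#'
#' @param shape `"circle"` or `"rectangle"`.
#' @param centre `(y, x)` centre in pixels (continuous).
#' @param radius_px circle radius in pixels.
#' @param height_px,width_px rectangle extent in whole pixels.
#' @return An object of class `ww_roi`.
#' @examples
#' r <- roi_spec("circle", centre = c(32, 32), radius_px = 4)
#' sum(roi_mask(r, c(64, 64)))
#' @export
roi_spec <- function(shape = c("circle", "rectangle"), centre,
                     radius_px = NULL, height_px = NULL, width_px = NULL) {
  shape <- match.arg(shape)
  stopifnot(length(centre) == 2, all(is.finite(centre)))
  if (shape == "circle") {
    if (is.null(radius_px) || radius_px <= 0) stop("circle ROI needs radius_px > 0")
    out <- list(shape = shape, centre = as.numeric(centre), radius_px = radius_px)
  } else {
    if (is.null(height_px) || is.null(width_px) || height_px < 1 || width_px < 1)
      stop("rectangle ROI needs height_px, width_px >= 1")
    out <- list(shape = shape, centre = as.numeric(centre),
                height_px = as.integer(round(height_px)),
                width_px = as.integer(round(width_px)))
  }
  class(out) <- "ww_roi"
  out
}

#' Build an ROI of a prescribed physical area
#'
#' Convenience constructor for the ROIs the quantification protocols use
#' (e.g. a 256 um^2 square or an 18 um^2 disc centred at the wound site):
#' converts the requested physical area into pixel dimensions at the given
#' calibration.
#'
#' @param shape `"circle"` or `"rectangle"` (square).
#' @param area_um2 target area in square micrometres.
#' @param centre `(y, x)` centre in pixels.
#' @param pixel_size_um pixel size in micrometres.
#' @export
roi_from_area <- function(shape = c("rectangle", "circle"), area_um2, centre,
                          pixel_size_um) {
  shape <- match.arg(shape)
  stopifnot(area_um2 > 0, pixel_size_um > 0)
  if (shape == "rectangle") {
    side <- max(1L, as.integer(round(sqrt(area_um2) / pixel_size_um)))
    roi_spec("rectangle", centre, height_px = side, width_px = side)
  } else {
    roi_spec("circle", centre, radius_px = sqrt(area_um2 / pi) / pixel_size_um)
  }
}

rect_rows <- function(roi) {
  y0 <- round(roi$centre[1] - (roi$height_px - 1) / 2)
  y0:(y0 + roi$height_px - 1L)
}
rect_cols <- function(roi) {
  x0 <- round(roi$centre[2] - (roi$width_px - 1) / 2)
  x0:(x0 + roi$width_px - 1L)
}

#' Rasterize an ROI to a boolean mask
#'
#' @param roi a [roi_spec()].
#' @param dim frame dimensions `(H, W)`.
#' @return `H x W` logical matrix. The ROI must lie entirely within bounds.
#' @export
roi_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "ww_roi"), length(dim) >= 2)
  H <- dim[1]; W <- dim[2]
  if (roi$shape == "circle") {
    r <- roi$radius_px; cy <- roi$centre[1]; cx <- roi$centre[2]
    if (cy - r < 0.5 || cy + r > H + 0.5 || cx - r < 0.5 || cx + r > W + 0.5)
      stop("ROI extends outside the frame")
    dy <- (seq_len(H) - cy)^2
    dx <- (seq_len(W) - cx)^2
    outer(dy, dx, `+`) <= r^2
  } else {
    rows <- rect_rows(roi); cols <- rect_cols(roi)
    if (min(rows) < 1 || max(rows) > H || min(cols) < 1 || max(cols) > W)
      stop("ROI extends outside the frame")
    mask <- matrix(FALSE, H, W)
    mask[rows, cols] <- TRUE
    mask
  }
}

#' Physical ROI area
#'
#' Pixel count of the rasterized ROI times the pixel area. Within one
#' pixel-perimeter of the analytic area for circles; exact for rectangles.
#'
#' @inheritParams roi_mask
#' @param pixel_size_um pixel size in micrometres.
#' @export
roi_area_um2 <- function(roi, dim, pixel_size_um) {
  sum(roi_mask(roi, dim)) * pixel_size_um^2
}
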