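#' Calibrated time-lapse movie container
#'
#' A movie is a `[y, x, t]` array of non-negative intensities together with
#' its spatial calibration (`pixel_size_um`, micrometres per pixel), temporal
#' calibration (`frame_interval_s`, seconds per frame) and, optionally, the
#' frame index at which the wound was inflicted (`t0_wound`).
#'
#' @param frames numeric array, either `H x W` (single frame) or `H x W x T`.
#' @param pixel_size_um pixel size in micrometres per pixel (> 0).
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param t0_wound frame index of wounding, or `NA` if the movie is unwounded.
#' @return An object of class `ww_movie`: a list with elements `frames`
#'   (always `H x W x T`), `pixel_size_um`, `frame_interval_s`, `t0_wound`.
#' @examples
#' m <- movie(array(1, dim = c(16, 16, 4)), 0.08, 0.3)
#' n_frames(m)
#' @export
movie <- function(frames, pixel_size_um, frame_interval_s, t0_wound = NA_integer_) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 3L)
    stop("`frames` must be an H x W or H x W x T array")
  if (!is.numeric(frames) || !all(is.finite(frames)))
    stop("movie intensities must be finite numbers")
  if (min(frames) < 0)
    stop("movie intensities must be non-negative")
  d <- dim(frames)
  if (d[1] < 8L || d[2] < 8L)
    stop("movie frames must be at least 8 x 8 pixels")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0)
    stop("`frame_interval_s` must be a single positive number")
  structure(list(frames = frames,
                 pixel_size_um = as.numeric(pixel_size_um),
                 frame_interval_s = as.numeric(frame_interval_s),
                 t0_wound = if (is.na(t0_wound)) NA_integer_ else as.integer(t0_wound)),
            class = "ww_movie")
}

#' @export
print.ww_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ww_movie> %d frames of %d x %d px\n", d[3], d[1], d[2]))
  cat(sprintf("  pixel size     : %g um/px\n", x$pixel_size_um))
  cat(sprintf("  frame interval : %g s  (duration %g s)\n",
              x$frame_interval_s, (d[3] - 1) * x$frame_interval_s))
  if (!is.na(x$t0_wound))
    cat(sprintf("  wounded at frame %d (t = %g s)\n", x$t0_wound,
                (x$t0_wound - 1) * x$frame_interval_s))
  cat(sprintf("  intensity range: [%g, %g]\n", min(x$frames), max(x$frames)))
  invisible(x)
}

#' @rdname movie
#' @param m a `ww_movie`.
#' @export
n_frames <- function(m) dim(m$frames)[3]

#' @rdname movie
#' @param t frame index.
#' @export
get_frame <- function(m, t) {
  stopifnot(inherits(m, "ww_movie"), t >= 1, t <= n_frames(m))
  m$frames[, , t]
}

#' Frame times in seconds
#'
#' Times of each frame, in seconds. When the movie carries a wound frame,
#' times are relative to wounding (wound frame = 0 s); otherwise relative to
#' the first frame.
#' @param m a `ww_movie`.
#' @export
frame_times <- function(m) {
  t0 <- if (is.na(m$t0_wound)) 1L else m$t0_wound
  (seq_len(n_frames(m)) - t0) * m$frame_interval_s
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a movie to a multi-page TIFF with a JSON calibration sidecar
#'
#' Integer-valued movies fitting 8 or 16 bits are stored as integer TIFF
#' pages and round-trip bit-exactly. Anything else is stored as 32-bit
#' fixed-point pages holding `intensity / scale` in `[0, 1]`, with the
#' power-of-two scale recorded in the sidecar and restored on read; the
#' round trip is then exact to one part in 2^32 of full scale (a finer
#' quantization than IEEE float32's 24-bit mantissa).
#'
#' @param m a [movie()].
#' @param path output TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @param bits 8, 16 or 32, or `"auto"` (default) to choose from the data.
#' @return `path`, invisibly.
#' @export
write_movie <- function(m, path, bits = "auto") {
  stopifnot(inherits(m, "ww_movie"))
  mx <- max(m$frames)
  is_int <- max(abs(m$frames - round(m$frames))) == 0
  if (identical(bits, "auto")) {
    bits <- if (is_int && mx <= 255) 8L else if (is_int && mx <= 65535) 16L else 32L
  }
  bits <- as.integer(bits)
  scale <- 1
  T <- n_frames(m)
  pages <- vector("list", T)
  if (bits %in% c(8L, 16L)) {
    div <- if (bits == 8L) 255 else 65535
    if (!is_int || mx > div)
      stop("integer TIFF requested for non-integer or out-of-range intensities")
    for (t in seq_len(T)) pages[[t]] <- m$frames[, , t] / div
  } else if (bits == 32L) {
    scale <- 2^ceiling(log2(max(mx, 1)))
    for (t in seq_len(T)) pages[[t]] <- m$frames[, , t] / scale
  } else stop("`bits` must be 8, 16 or 32")
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  side <- list(pixel_size_um = m$pixel_size_um,
               frame_interval_s = m$frame_interval_s,
               t0_wound = if (is.na(m$t0_wound)) NULL else m$t0_wound,
               intensity_scale = scale,
               bits = bits)
  side <- side[!vapply(side, is.null, logical(1))]
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# parse ImageJ-style TIFF description ("finterval=0.3\nunit=micron ...")
parse_imagej_desc <- function(desc) {
  out <- list()
  if (is.null(desc) || !nzchar(desc)) return(out)
  for (line in strsplit(desc, "\n", fixed = TRUE)[[1]]) {
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) out[[kv[1]]] <- kv[2]
  }
  num <- function(k) if (!is.null(out[[k]])) suppressWarnings(as.numeric(out[[k]])) else NULL
  list(frame_interval_s = num("finterval"), pixel_size_um = num("pixelWidth"))
}

#' Load a calibrated movie from a multi-page grayscale TIFF
#'
#' Calibration is resolved in priority order: explicit arguments, then the
#' JSON sidecar written by [write_movie()] (`<path>.json`), then ImageJ-style
#' TIFF description metadata. Missing calibration everywhere is an error.
#'
#' @param path TIFF file path.
#' @inheritParams movie
#' @return A [movie()].
#' @export
load_movie <- function(path, pixel_size_um = NULL, frame_interval_s = NULL,
                       t0_wound = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
    stop("RGB/multi-sample TIFF is not a grayscale movie")
  info <- attributes(pages[[1]])
  bits <- info$bits.per.sample %||% 32L
  side <- list()
  if (file.exists(sidecar_path(path)))
    side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (bits %in% c(8L, 16L)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    scale <- 1
  } else {
    scale <- side$intensity_scale %||% 1
  }
  desc <- parse_imagej_desc(info$description)
  px <- pixel_size_um %||% side$pixel_size_um %||% desc$pixel_size_um
  dt <- frame_interval_s %||% side$frame_interval_s %||% desc$frame_interval_s
  t0 <- t0_wound %||% side$t0_wound %||% NA_integer_
  if (length(t0) != 1) t0 <- NA_integer_
  if (is.null(px) || is.null(dt))
    stop("calibration (pixel_size_um, frame_interval_s) missing: pass it, ",
         "provide a JSON sidecar, or use a TIFF with ImageJ metadata")
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * scale
  movie(arr, px, dt, t0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
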