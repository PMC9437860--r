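#' Intensity image
#'
#' Light container for a 2D nonnegative intensity grid. Pixel coordinates are
#' 0-based with `x` the column and `y` the row; pixel centers sit at integer
#' coordinates, so pixel `(x, y)` maps to matrix element `[y + 1, x + 1]`.
#'
#' @param pixels numeric matrix of nonnegative intensities (rows = y, cols = x).
#' @param pixel_size physical pixel size in micrometres per pixel (default 1).
#' @return an object of class `intensity_image`.
#' @export
intensity_image <- function(pixels, pixel_size = 1.0) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0))
    stop("intensity values must be finite and >= 0", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar", call. = FALSE)
  structure(list(pixels = pixels,
                 height = nrow(pixels), width = ncol(pixels),
                 pixel_size = pixel_size),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image %d x %d px, pixel_size %g um/px, range [%g, %g]>\n",
              x$width, x$height, x$pixel_size, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Time-lapse stack
#'
#' @param frames list of equally sized numeric matrices, or a 3D array with
#'   the third dimension indexing time.
#' @param dt frame interval in seconds.
#' @param pixel_size micrometres per pixel.
#' @return an object of class `time_lapse` with fields `frames` (3D array
#'   rows x cols x time), `n_frames`, `dt`, `pixel_size`.
#' @export
time_lapse <- function(frames, dt = 1.0, pixel_size = 1.0) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must share the same shape", call. = FALSE)
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a list of matrices or a 3D array", call. = FALSE)
  if (dim(frames)[3L] < 2L)
    stop("a time lapse needs at least 2 frames", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  structure(list(frames = frames, n_frames = dim(frames)[3L],
                 height = dim(frames)[1L], width = dim(frames)[2L],
                 dt = dt, pixel_size = pixel_size),
            class = "time_lapse")
}

#' @export
print.time_lapse <- function(x, ...) {
  cat(sprintf("<time_lapse %d frames of %d x %d px, dt %g s, pixel_size %g um/px>\n",
              x$n_frames, x$width, x$height, x$dt, x$pixel_size))
  invisible(x)
}

as_pixel_matrix <- function(image) {
  if (inherits(image, "intensity_image")) image$pixels
  else if (is.matrix(image)) image
  else stop("expected an intensity_image or a matrix", call. = FALSE)
}

#' Bilinear interpolation at subpixel coordinates
#'
#' @param mat numeric matrix.
#' @param x,y 0-based coordinates (x = column, y = row), vectorised.
#' @return interpolated values; coordinates must lie within
#'   `[0, ncol-1] x [0, nrow-1]`.
#' @keywords internal
bilinear <- function(mat, x, y) {
  nr <- nrow(mat); nc <- ncol(mat)
  if (any(x < 0 | x > nc - 1L | y < 0 | y > nr - 1L))
    stop("coordinates outside image bounds", call. = FALSE)
  x0 <- pmin(floor(x), nc - 2L); y0 <- pmin(floor(y), nr - 2L)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * nr + y0 + 1          # [y0+1, x0+1]
  v00 <- mat[i00];        v10 <- mat[i00 + nr]
  v01 <- mat[i00 + 1L];   v11 <- mat[i00 + nr + 1L]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}
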