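# Minimal spot detection and frame-to-frame linking for comet-style track
# statistics. Detection: difference-of-Gaussians band-pass + local maxima with
# center-of-mass subpixel refinement. Linking: greedy nearest-neighbour per
# consecutive frame pair, globally ordered by pair distance, no gap closing.

# Separable Gaussian blur with edge-replicate padding via index clamping.
gaussian_blur <- function(mat, sigma) {
  r <- as.integer(ceiling(3.5 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(mat); nc <- ncol(mat)
  tmp <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    rows <- pmin(pmax(seq_len(nr) + (i - r - 1L), 1L), nr)
    tmp <- tmp + k[i] * mat[rows, , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    cols <- pmin(pmax(seq_len(nc) + (i - r - 1L), 1L), nc)
    out <- out + k[i] * tmp[, cols, drop = FALSE]
  }
  out
}

#' Detect spots by difference of Gaussians
#'
#' The image is band-pass filtered as `blur(sigma_small) - blur(sigma_large)`
#' (removing background), then strict 8-neighbour local maxima above
#' `threshold` are refined to subpixel positions by the intensity-weighted
#' centroid of the (nonnegative) response in a 3x3 window.
#'
#' @param image `intensity_image` or numeric matrix.
#' @param sigma_small,sigma_large Gaussian sigmas in pixels,
#'   `0 < sigma_small < sigma_large`.
#' @param threshold minimum DoG response at the peak.
#' @return data.frame with columns `x`, `y` (0-based subpixel) and
#'   `intensity` (peak DoG response); zero rows if nothing found.
#' @export
detect_spots <- function(image, sigma_small = 1.5, sigma_large = 3,
                         threshold = 0) {
  if (!is.numeric(sigma_small) || !is.numeric(sigma_large) ||
      sigma_small <= 0 || sigma_large <= 0)
    stop("sigmas must be positive", call. = FALSE)
  if (sigma_small >= sigma_large)
    stop("sigma_small must be < sigma_large", call. = FALSE)
  px <- as_pixel_matrix(image)
  dog <- gaussian_blur(px, sigma_small) - gaussian_blur(px, sigma_large)
  nr <- nrow(dog); nc <- ncol(dog)
  if (nr < 3L || nc < 3L)
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  core <- dog[2:(nr - 1L), 2:(nc - 1L)]
  is_max <- core > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- dog[2:(nr - 1L) + dr, 2:(nc - 1L) + dc]
    # strict on the lexicographically earlier neighbour to break plateaus
    if (dr < 0L || (dr == 0L && dc < 0L)) is_max <- is_max & (core > nb)
    else is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  ry <- idx[, 1L] + 1L; cx <- idx[, 2L] + 1L  # back to full-image indices
  n <- length(ry)
  x <- numeric(n); y <- numeric(n); val <- numeric(n)
  for (i in seq_len(n)) {
    w <- pmax(dog[(ry[i] - 1L):(ry[i] + 1L), (cx[i] - 1L):(cx[i] + 1L)], 0)
    sw <- sum(w)
    dx <- sum(w * matrix(-1:1, 3L, 3L, byrow = TRUE)) / sw
    dy <- sum(w * matrix(-1:1, 3L, 3L)) / sw
    x[i] <- (cx[i] - 1L) + dx
    y[i] <- (ry[i] - 1L) + dy
    val[i] <- dog[ry[i], cx[i]]
  }
  ord <- order(y, x)
  data.frame(x = x[ord], y = y[ord], intensity = val[ord])
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour assignment per consecutive frame pair: all
#' candidate pairs within `max_disp` are sorted by ascending distance (ties
#' by lower spot index in the earlier, then later frame) and accepted while
#' both endpoints are unmatched. Unmatched detections start new tracks; a
#' track with no match ends (no gap closing).
#'
#' @param detections list (one element per frame) of data.frames with
#'   columns `x`, `y` (and optionally `intensity`).
#' @param max_disp maximum linking distance in pixels.
#' @return list of `org_track` with `xy` coordinates; ids in order of track
#'   creation.
#' @export
link_spots <- function(detections, max_disp = 5) {
  if (!is.numeric(max_disp) || max_disp <= 0)
    stop("max_disp must be > 0", call. = FALSE)
  n_t <- length(detections)
  if (!n_t) return(list())
  tracks <- list()       # each: frames, xy, active spot pointer
  open_of_spot <- list() # per frame: track index owning each spot
  for (t in seq_len(n_t)) {
    det <- detections[[t]]
    nd <- if (is.null(det)) 0L else nrow(det)
    owner <- rep(NA_integer_, nd)
    if (t > 1L) {
      prev <- detections[[t - 1L]]
      np <- if (is.null(prev)) 0L else nrow(prev)
      if (np && nd) {
        dx <- outer(prev$x, det$x, `-`); dy <- outer(prev$y, det$y, `-`)
        dmat <- sqrt(dx^2 + dy^2)
        cand <- which(dmat <= max_disp, arr.ind = TRUE)
        if (nrow(cand)) {
          ord <- order(dmat[cand], cand[, 1L], cand[, 2L])
          used_p <- logical(np); used_d <- logical(nd)
          for (k in ord) {
            i <- cand[k, 1L]; j <- cand[k, 2L]
            if (used_p[i] || used_d[j]) next
            used_p[i] <- TRUE; used_d[j] <- TRUE
            ti <- open_of_spot[[t - 1L]][i]
            tracks[[ti]]$frames <- c(tracks[[ti]]$frames, t - 1L)
            tracks[[ti]]$xy <- rbind(tracks[[ti]]$xy, c(det$x[j], det$y[j]))
            owner[j] <- ti
          }
        }
      }
    }
    for (j in seq_len(nd)) {
      if (is.na(owner[j])) {
        tracks[[length(tracks) + 1L]] <-
          list(frames = t - 1L, xy = matrix(c(det$x[j], det$y[j]), 1L, 2L))
        owner[j] <- length(tracks)
      }
    }
    open_of_spot[[t]] <- owner
  }
  lapply(seq_along(tracks), function(i)
    org_track(frames = tracks[[i]]$frames, xy = tracks[[i]]$xy, id = i))
}

#' Detect and link across a whole stack
#'
#' @param stack a `time_lapse`.
#' @inheritParams detect_spots
#' @inheritParams link_spots
#' @param min_length minimum frames per track kept for statistics
#'   (default 3); shorter tracks are returned with `kept = FALSE` attribute
#'   dropped from summaries.
#' @return list with `tracks` (all) and `summary` data.frame
#'   (track_id, n_points, duration_s, displacement_um, speed_um_per_s) for
#'   tracks with at least `min_length` points.
#' @export
track_stack <- function(stack, sigma_small = 1.5, sigma_large = 3,
                        threshold = 0, max_disp = 5, min_length = 3) {
  detections <- lapply(seq_len(stack$n_frames), function(t)
    detect_spots(stack$frames[, , t], sigma_small, sigma_large, threshold))
  tracks <- link_spots(detections, max_disp)
  keep <- vapply(tracks, function(tr) length(tr$frames) >= min_length,
                 logical(1L))
  summ <- do.call(rbind, lapply(tracks[keep], function(tr) {
    st <- track_stats(tr, dt = stack$dt, pixel_size = stack$pixel_size)
    data.frame(track_id = tr$id, n_points = length(tr$frames),
               duration_s = st$duration_s,
               displacement_um = st$displacement_um,
               speed_um_per_s = st$speed_um_per_s)
  }))
  if (is.null(summ))
    summ <- data.frame(track_id = integer(0), n_points = integer(0),
                       duration_s = numeric(0), displacement_um = numeric(0),
                       speed_um_per_s = numeric(0))
  list(tracks = tracks, summary = summ)
}
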