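# Kymograph construction along segmented-line paths and transport-event
# counting (anterograde / retrograde / stationary), plus track statistics.

#' Path specification for a kymograph
#'
#' @param vertices n x 2 matrix of ordered (x, y) points (a segmented line,
#'   oriented proximal -> distal; anterograde = increasing path coordinate).
#' @param width perpendicular averaging width in pixels (odd, default 3).
#' @return a `path_spec` with `vertices`, `width` and `length` (arc length
#'   in pixels).
#' @export
path_spec <- function(vertices, width = 3) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L) stop("path needs >= 2 vertices", call. = FALSE)
  seg <- diff(vertices)
  lens <- sqrt(rowSums(seg^2))
  if (sum(lens) <= 0) stop("path has zero length", call. = FALSE)
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  structure(list(vertices = vertices, width = width,
                 seg_len = lens, length = sum(lens)),
            class = "path_spec")
}

# Point and unit normal at arc-length positions s along the path (vectorised).
path_point <- function(path, s) {
  cums <- c(0, cumsum(path$seg_len))
  s <- pmin(pmax(s, 0), path$length)
  seg <- pmin(findInterval(s, cums, rightmost.closed = TRUE),
              length(path$seg_len))
  t <- (s - cums[seg]) / path$seg_len[seg]
  a <- path$vertices[seg, , drop = FALSE]
  b <- path$vertices[seg + 1L, , drop = FALSE]
  p <- a + t * (b - a)
  dir <- (b - a) / path$seg_len[seg]
  list(x = p[, 1L], y = p[, 2L], nx = -dir[, 2L], ny = dir[, 1L])
}

#' Build a kymograph from a time-lapse stack
#'
#' The path is resampled at unit arc-length spacing; for each sample and
#' frame the intensity is the maximum over a perpendicular window of
#' `path$width` pixels, with bilinear interpolation at subpixel coordinates.
#' Rows are positions along the path, columns are time frames.
#'
#' @param stack a `time_lapse`.
#' @param path a `path_spec`; must lie inside the frame bounds (including
#'   the width window).
#' @return a `kymograph` with fields `matrix`, `path_length`, `dt`,
#'   `pixel_size`.
#' @export
build_kymograph <- function(stack, path) {
  if (!inherits(stack, "time_lapse")) stop("stack must be a time_lapse", call. = FALSE)
  if (!inherits(path, "path_spec")) stop("path must be a path_spec", call. = FALSE)
  n_rows <- round(path$length) + 1L
  s <- pmin(seq_len(n_rows) - 1, path$length)
  pp <- path_point(path, s)
  offs <- seq(-(path$width - 1) / 2, (path$width - 1) / 2, by = 1)
  xs <- matrix(pp$x, n_rows, length(offs)) + outer(pp$nx, offs)
  ys <- matrix(pp$y, n_rows, length(offs)) + outer(pp$ny, offs)
  nr <- stack$height; nc <- stack$width
  if (any(xs < 0 | xs > nc - 1 | ys < 0 | ys > nr - 1))
    stop("path (with width window) exits image bounds", call. = FALSE)
  km <- matrix(0, n_rows, stack$n_frames)
  for (t in seq_len(stack$n_frames)) {
    v <- bilinear(stack$frames[, , t], as.vector(xs), as.vector(ys))
    km[, t] <- apply(matrix(v, n_rows, length(offs)), 1L, max)
  }
  structure(list(matrix = km, path_length = path$length,
                 dt = stack$dt, pixel_size = stack$pixel_size),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph %d positions x %d frames, dt %g s, px %g um>\n",
              nrow(x$matrix), ncol(x$matrix), x$dt, x$pixel_size))
  invisible(x)
}

#' Track object
#'
#' @param frames integer frame indices (strictly increasing).
#' @param positions path coordinates (pixels) per frame, or NULL.
#' @param xy n x 2 matrix of image coordinates per frame, or NULL.
#' @param id track identifier.
#' @param observed logical per point; FALSE marks interpolated (coasted)
#'   points from the kymograph tracer.
#' @return an `org_track`.
#' @export
org_track <- function(frames, positions = NULL, xy = NULL, id = NA,
                      observed = NULL) {
  frames <- as.integer(frames)
  if (is.unsorted(frames, strictly = TRUE))
    stop("frame indices must be strictly increasing", call. = FALSE)
  if (is.null(positions) && is.null(xy))
    stop("a track needs positions or xy coordinates", call. = FALSE)
  if (is.null(observed)) observed <- rep(TRUE, length(frames))
  structure(list(id = id, frames = frames, positions = positions,
                 xy = xy, observed = observed),
            class = "org_track")
}

track_net_displacement <- function(track) {
  n <- length(track$frames)
  if (!is.null(track$positions))
    track$positions[n] - track$positions[1L]
  else
    sqrt(sum((track$xy[n, ] - track$xy[1L, ])^2))
}

#' Classify one track as anterograde / retrograde / stationary
#'
#' Net displacement below `stationary_threshold` (absolute value) is
#' stationary; otherwise positive displacement (increasing path coordinate,
#' proximal -> distal, i.e. left-to-right on the kymograph) is anterograde
#' and negative is retrograde.
#'
#' @param track an `org_track` with path positions.
#' @param stationary_threshold pixels (default 2).
#' @return one of "anterograde", "retrograde", "stationary".
#' @export
classify_track <- function(track, stationary_threshold = 2) {
  if (length(track$frames) < 2L)
    stop("track too short to classify (needs >= 2 points)", call. = FALSE)
  d <- track_net_displacement(track)
  if (abs(d) < stationary_threshold) "stationary"
  else if (d > 0) "anterograde"
  else "retrograde"
}

#' Count transport events
#'
#' Tallies [classify_track()] over a list of tracks; one classified track is
#' one event.
#'
#' @param tracks list of `org_track`.
#' @param stationary_threshold pixels (default 2).
#' @param compartment "axon", "dendrite" or "none".
#' @return a `transport_event_counts` with `anterograde`, `retrograde`,
#'   `stationary`, `compartment`.
#' @export
count_events <- function(tracks, stationary_threshold = 2,
                         compartment = c("none", "axon", "dendrite")) {
  compartment <- match.arg(compartment)
  labels <- character(length(tracks))
  for (i in seq_along(tracks)) {
    labels[i] <- tryCatch(classify_track(tracks[[i]], stationary_threshold),
                          error = function(e)
                            stop(sprintf("track %d: %s", i, conditionMessage(e)),
                                 call. = FALSE))
  }
  structure(list(anterograde = sum(labels == "anterograde"),
                 retrograde = sum(labels == "retrograde"),
                 stationary = sum(labels == "stationary"),
                 compartment = compartment),
            class = "transport_event_counts")
}

#' @export
print.transport_event_counts <- function(x, ...) {
  cat(sprintf("<transport events [%s]: %d anterograde, %d retrograde, %d stationary>\n",
              x$compartment, x$anterograde, x$retrograde, x$stationary))
  invisible(x)
}

#' Label neuronal processes as axon or dendrite
#'
#' A process is an axon iff its length is at least 3 times the median length
#' of the remaining processes (the "axon = 3x dendrite" rule, operationalised
#' with the median of the others).
#'
#' @param lengths numeric vector of process lengths (micrometres).
#' @return character vector of "axon" / "dendrite" labels.
#' @export
classify_processes <- function(lengths) {
  if (length(lengths) < 2L)
    stop("need at least 2 processes to classify", call. = FALSE)
  vapply(seq_along(lengths), function(i) {
    if (lengths[i] >= 3 * stats::median(lengths[-i])) "axon" else "dendrite"
  }, character(1L))
}

#' Track statistics: duration, displacement, speed
#'
#' @param track an `org_track` with at least 2 points.
#' @param dt seconds per frame.
#' @param pixel_size micrometres per pixel.
#' @return list with `duration_s`, `displacement_um` (signed for path
#'   tracks, Euclidean for xy tracks) and `speed_um_per_s`.
#' @export
track_stats <- function(track, dt = 1, pixel_size = 1) {
  n <- length(track$frames)
  if (n < 2L) stop("track needs >= 2 points", call. = FALSE)
  duration <- (track$frames[n] - track$frames[1L]) * dt
  if (duration <= 0) stop("degenerate track: zero duration", call. = FALSE)
  disp <- track_net_displacement(track) * pixel_size
  list(duration_s = duration, displacement_um = disp,
       speed_um_per_s = abs(disp) / duration)
}

#' Extract tracks from a kymograph
#'
#' Per-column 1D peak detection (local maxima above `threshold`, subpixel
#' refinement by intensity-weighted centroid over +/-2 px) followed by
#' seeded bidirectional track growing. Candidate seeds are triplets of
#' detections in three consecutive frames with near-constant velocity
#' (|p2 - 2 p1 + p0| <= `accel_tol`); seeds are ranked by that residual and
#' grown greedily, each track extending forward and backward frame by frame
#' to the position predicted by a least-squares velocity fit over its
#' trailing `fit_window` points, claiming the nearest unconsumed detection
#' within `claim_radius` and tolerating up to `max_gap` consecutive missing
#' frames (e.g. while two loci cross and their peaks merge, the
#' earlier-grown track consuming the merged peak). Consumed detections are
#' unavailable to later tracks, so each punctum is traced once. Tracks with
#' fewer than `min_length` observed points are discarded.
#'
#' The tracker assumes locally smooth (piecewise near-linear) motion, which
#' is what kymograph loci of motor-driven cargo look like at a seconds
#' timescale; it is not a general curvilinear tracker.
#'
#' @param kymo a `kymograph`.
#' @param threshold detection threshold; default `median + 5 * mad` of the
#'   kymograph matrix.
#' @param claim_radius maximum distance between predicted and claimed
#'   detection (pixels, default 3).
#' @param v_max maximum speed considered when forming seed triplets
#'   (px/frame, default 5).
#' @param accel_tol maximum second difference within a seed triplet
#'   (pixels, default 1).
#' @param max_gap maximum consecutive frames a track may coast without a
#'   detection (default 5).
#' @param fit_window trailing points used for the velocity fit (default 15).
#' @param min_length minimum observed points per kept track (default 5).
#' @param min_fill minimum fraction of frames within a track's span that
#'   carry a detection (default 0.8); a genuine locus is detected in nearly
#'   every frame (merge sharing covers crossings), so sparse diagonal chains
#'   of leftover detections are spurious and dropped.
#' @return list of `org_track` with path positions.
#' @export
trace_kymograph <- function(kymo, threshold = NULL, claim_radius = 3,
                            v_max = 5, accel_tol = 1, max_gap = 5,
                            fit_window = 15, min_length = 5,
                            min_fill = 0.8) {
  km <- kymo$matrix
  if (is.null(threshold))
    threshold <- stats::median(km) + 5 * stats::mad(km)
  n_pos <- nrow(km); n_t <- ncol(km)
  detections <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    v <- km[, t]
    idx <- which(v > threshold)
    idx <- idx[idx > 1L & idx < n_pos]
    is_max <- v[idx] >= v[idx - 1L] & v[idx] > v[idx + 1L]
    peaks <- idx[is_max]
    detections[[t]] <- if (length(peaks)) {
      vapply(peaks, function(p) {
        # centroid window truncated at local valleys so a neighbouring
        # locus rising inside the +/-2 window does not pull the position
        lo <- p; hi <- p
        while (lo > 1L && p - lo < 2L && v[lo - 1L] < v[lo]) lo <- lo - 1L
        while (hi < n_pos && hi - p < 2L && v[hi + 1L] < v[hi]) hi <- hi + 1L
        w <- lo:hi
        wt <- pmax(v[w] - threshold, 0)
        if (sum(wt) == 0) p - 1 else sum(wt * (w - 1)) / sum(wt)
      }, numeric(1L))
    } else numeric(0)
  }
  # candidate seed triplets over consecutive frames, ranked by |acceleration|
  seeds <- list()
  for (t in seq_len(n_t - 2L)) {
    d0 <- detections[[t]]; d1 <- detections[[t + 1L]]; d2 <- detections[[t + 2L]]
    if (!length(d0) || !length(d1) || !length(d2)) next
    for (i in seq_along(d0)) for (j in seq_along(d1)) {
      if (abs(d1[j] - d0[i]) > v_max) next
      pred2 <- 2 * d1[j] - d0[i]
      res <- abs(d2 - pred2)
      k <- which.min(res)
      if (res[k] <= accel_tol)
        seeds[[length(seeds) + 1L]] <- c(res[k], t, i, j, k)
    }
  }
  if (!length(seeds)) return(list())
  sm <- do.call(rbind, seeds)
  sm <- sm[order(sm[, 1L], sm[, 2L], sm[, 3L]), , drop = FALSE]
  consumed <- lapply(detections, function(d) rep(FALSE, length(d)))
  # predict position at frame t from a trailing/leading window LS fit
  predict_pos <- function(frames, pos, t, lead = FALSE) {
    n <- length(frames)
    if (n < 2L) return(pos[if (lead) 1L else n])
    idx <- if (lead) 1L:min(fit_window, n) else max(1L, n - fit_window + 1L):n
    f <- frames[idx]; p <- pos[idx]
    v <- sum((f - mean(f)) * (p - mean(p))) / sum((f - mean(f))^2)
    mean(p) + v * (t - mean(f))
  }
  grow <- function(frames, pos, solo, from, step) {
    miss <- 0L
    t <- from
    while (miss <= max_gap) {
      t <- t + step
      if (t < 1L || t > n_t) break
      det <- detections[[t]]
      if (length(det)) {
        pred <- predict_pos(frames, pos, t, lead = step < 0L)
        d <- abs(det - pred)
        # prefer an unconsumed detection; fall back to sharing a consumed
        # one (two loci merged into a single peak while crossing)
        avail <- which(!consumed[[t]] & d <= claim_radius)
        k <- if (length(avail)) avail[which.min(d[avail])]
             else if (min(d) <= claim_radius) which.min(d)
             else 0L
        if (k > 0L) {
          was_free <- !consumed[[t]][k]
          consumed[[t]][k] <<- TRUE
          if (step > 0L) {
            frames <- c(frames, t); pos <- c(pos, det[k])
            solo <- c(solo, was_free)
          } else {
            frames <- c(t, frames); pos <- c(det[k], pos)
            solo <- c(was_free, solo)
          }
          miss <- 0L
          next
        }
      }
      miss <- miss + 1L
    }
    list(frames = frames, pos = pos, solo = solo)
  }
  # drop end points inconsistent with the locally fitted motion (typically a
  # merged peak claimed while another locus crossed right at the track end);
  # the prediction window skips a 3-point margin so short runs of
  # contaminated end points are still caught
  trim_tol <- 1.5
  trim_margin <- 5L
  trim_ends <- function(frames, pos, solo) {
    repeat {
      n <- length(frames)
      if (n < trim_margin + 2L) break
      core <- 1L:(n - trim_margin)
      pred_last <- predict_pos(frames[core], pos[core], frames[n])
      if (abs(pos[n] - pred_last) > trim_tol) {
        frames <- frames[-n]; pos <- pos[-n]; solo <- solo[-n]; next
      }
      core <- (trim_margin + 1L):n
      pred_first <- predict_pos(frames[core], pos[core], frames[1L],
                                lead = TRUE)
      if (abs(pos[1L] - pred_first) > trim_tol) {
        frames <- frames[-1L]; pos <- pos[-1L]; solo <- solo[-1L]; next
      }
      break
    }
    list(frames = frames, pos = pos, solo = solo)
  }
  tracks <- list()
  for (q in seq_len(nrow(sm))) {
    t <- sm[q, 2L]; i <- sm[q, 3L]; j <- sm[q, 4L]; k <- sm[q, 5L]
    if (consumed[[t]][i] || consumed[[t + 1L]][j] || consumed[[t + 2L]][k])
      next
    consumed[[t]][i] <- TRUE
    consumed[[t + 1L]][j] <- TRUE
    consumed[[t + 2L]][k] <- TRUE
    frames <- c(t, t + 1L, t + 2L)
    pos <- c(detections[[t]][i], detections[[t + 1L]][j],
             detections[[t + 2L]][k])
    fw <- grow(frames, pos, rep(TRUE, 3L), t + 2L, +1L)
    bw <- grow(fw$frames, fw$pos, fw$solo, t, -1L)
    tr <- trim_ends(bw$frames, bw$pos, bw$solo)
    if (length(tr$frames) < min_length) next
    span <- tr$frames[length(tr$frames)] - tr$frames[1L] + 1L
    if (length(tr$frames) / span < min_fill) next
    # a track fed mostly by detections another track consumed first is a
    # duplicate trace of the same locus (e.g. seeded from a noise-split
    # double peak) shares essentially every detection; a genuine track in a
    # busy corridor still claims a substantial fraction first
    if (mean(tr$solo) < 0.2) next
    tracks[[length(tracks) + 1L]] <-
      org_track(frames = tr$frames - 1L, positions = tr$pos,
                id = length(tracks) + 1L)
  }
  tracks
}
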