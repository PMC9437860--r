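# Polygon geometry shared by segmentation and shell profiling.
# All polygons are m x 2 matrices of (x, y) vertices, implicitly closed.

#' Even-odd point-in-polygon test
#'
#' Crossing-number (even-odd) rule, vectorised over query points.
#'
#' @param px,py query coordinates.
#' @param poly m x 2 matrix of polygon vertices (closed implicitly).
#' @return logical vector, TRUE for points inside the polygon.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    if (yi != yj) {
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Signed polygon area (shoelace)
#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

#' Polygon centroid (area-weighted)
#' @keywords internal
polygon_centroid <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr) / (6 * a), sum((y + ys) * cr) / (6 * a))
}

#' Perimeter of a closed chain
#' @keywords internal
chain_perimeter <- function(pts) {
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  sum(sqrt(rowSums((nxt - pts)^2)))
}

# Distance from points to the segment a-b, vectorised over points.
point_segment_distance <- function(px, py, a, b) {
  abx <- b[1L] - a[1L]; aby <- b[2L] - a[2L]
  len2 <- abx^2 + aby^2
  if (len2 == 0) return(sqrt((px - a[1L])^2 + (py - a[2L])^2))
  t <- pmin(1, pmax(0, ((px - a[1L]) * abx + (py - a[2L]) * aby) / len2))
  sqrt((px - (a[1L] + t * abx))^2 + (py - (a[2L] + t * aby))^2)
}

# Minimum distance from points to the polygon outline.
point_polygon_distance <- function(px, py, poly) {
  n <- nrow(poly)
  d <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- pmin(d, point_segment_distance(px, py, poly[i, ], poly[j, ]))
  }
  d
}

# TRUE if the polygon is star-shaped about `center`: every segment from the
# center to a vertex stays inside the polygon (sampled test).
is_star_shaped <- function(poly, center, n_samples = 12L) {
  fr <- seq_len(n_samples) / (n_samples + 1L)
  for (i in seq_len(nrow(poly))) {
    px <- center[1L] + fr * (poly[i, 1L] - center[1L])
    py <- center[2L] + fr * (poly[i, 2L] - center[2L])
    if (!all(point_in_polygon(px, py, poly))) return(FALSE)
  }
  TRUE
}

# TRUE if the closed polygon self-intersects (any two non-adjacent edges cross).
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(FALSE)
  seg_a <- poly
  seg_b <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE])
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # skip edges adjacent through the closure
    if (!length(js)) next
    o1 <- orient(seg_a[i, 1L], seg_a[i, 2L], seg_b[i, 1L], seg_b[i, 2L],
                 seg_a[js, 1L], seg_a[js, 2L])
    o2 <- orient(seg_a[i, 1L], seg_a[i, 2L], seg_b[i, 1L], seg_b[i, 2L],
                 seg_b[js, 1L], seg_b[js, 2L])
    o3 <- orient(seg_a[js, 1L], seg_a[js, 2L], seg_b[js, 1L], seg_b[js, 2L],
                 seg_a[i, 1L], seg_a[i, 2L])
    o4 <- orient(seg_a[js, 1L], seg_a[js, 2L], seg_b[js, 1L], seg_b[js, 2L],
                 seg_b[i, 1L], seg_b[i, 2L])
    if (any(o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0))
      return(TRUE)
  }
  FALSE
}
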