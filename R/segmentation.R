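# Segmentation front-end: raw cell-channel image (or user mask) -> per-cell
# approximated boundary polygons. Chain of operations: binarize -> erode ->
# label connected components -> patch holes / drop small clusters -> trace the
# outer boundary -> Douglas-Peucker contour approximation.

disk_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2 + 1e-9, , drop = FALSE]
}

# mask[p + (dy, dx)] with out-of-bounds reading as `fill`.
shift_mask <- function(mask, dy, dx, fill = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L - dy):min(nr, nr - dy)
  cs <- max(1L, 1L - dx):min(nc, nc - dx)
  if (length(rs) && length(cs))
    out[rs, cs] <- mask[rs + dy, cs + dx]
  out
}

#' Morphological erosion by a disk
#'
#' Removes thin bridges (e.g. cell processes connecting neighbouring cells)
#' before connected-component clustering. The structuring element is a digital
#' disk of the given radius; pixels beyond the image border count as
#' background, so erosion also peels the image edge.
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels; 0 returns the input unchanged.
#' @return logical matrix, a subset of the input's TRUE pixels.
#' @export
erode_mask <- function(mask, radius = 3) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("radius must be a nonnegative scalar", call. = FALSE)
  if (radius == 0) return(mask)
  offs <- disk_offsets(radius)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs)))
    out <- out & shift_mask(mask, offs$dy[k], offs$dx[k], fill = FALSE)
  out
}

#' Threshold an intensity image to a binary mask
#'
#' `method = "otsu"` searches the threshold maximising between-class variance
#' over a 256-bin histogram; `method = "fixed"` uses the supplied value.
#' A pixel is foreground iff its intensity is strictly greater than the
#' threshold.
#'
#' @param image an `intensity_image` or numeric matrix.
#' @param method "otsu" or "fixed".
#' @param threshold required for `method = "fixed"`.
#' @return logical matrix.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  px <- as_pixel_matrix(image)
  if (method == "fixed") {
    if (is.null(threshold))
      stop("method 'fixed' requires a threshold", call. = FALSE)
    return(px > threshold)
  }
  rng <- range(px)
  if (rng[1L] == rng[2L]) {
    warning("constant image: Otsu threshold is degenerate, returning all-false")
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  thr <- otsu_threshold(px)
  px > thr
}

# Exhaustive 256-bin Otsu; returns a threshold on the intensity scale.
otsu_threshold <- function(px) {
  nbins <- 256L
  rng <- range(px)
  edges <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- tabulate(pmin(findInterval(px, edges, rightmost.closed = TRUE), nbins),
                nbins)
  w <- cumsum(h)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  m <- cumsum(h * mids)
  n <- w[nbins]; mu <- m[nbins]
  w0 <- w[-nbins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nbins - 1L)
  between[valid] <- (mu * w0[valid] / n - m[-nbins][valid])^2 /
    (w0[valid] / n * w1[valid] / n)
  k <- which.max(between)
  edges[k + 1L]
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4L)
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  else
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
}

# Vectorised frontier flood fill from seed linear indices over `open` pixels.
flood_from <- function(open, seeds, offs) {
  nr <- nrow(open); nc <- ncol(open)
  visited <- matrix(FALSE, nr, nc)
  seeds <- seeds[open[seeds] & !visited[seeds]]
  visited[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    r <- ((frontier - 1L) %% nr) + 1L
    c <- ((frontier - 1L) %/% nr) + 1L
    nb <- integer(0)
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1L]; cc <- c + offs[k, 2L]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- c(nb, (cc[ok] - 1L) * nr + rr[ok])
    }
    nb <- unique(nb)
    nb <- nb[open[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

#' Label connected components of a binary mask
#'
#' Groups connected foreground pixels into clusters, sorted by area
#' (descending, ties by first occurrence in column-major scan order) and
#' labelled 1..n in that order.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return list of `cell_cluster` objects, each with fields `label`,
#'   `pixels` (n x 2 matrix of 0-based (x, y)), `area` and `shape`.
#' @export
label_clusters <- function(mask, connectivity = 8) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- neighbor_offsets(connectivity)
  lab <- matrix(0L, nr, nc)
  comp_idx <- list()
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    members <- s
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      nb <- integer(0)
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1L]; cc <- c + offs[k, 2L]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        nb <- c(nb, (cc[ok] - 1L) * nr + rr[ok])
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      members <- c(members, nb)
      frontier <- nb
    }
    comp_idx[[cur]] <- members
  }
  if (cur == 0L) return(list())
  areas <- lengths(comp_idx)
  ord <- order(-areas, seq_along(areas))
  out <- vector("list", cur)
  for (i in seq_along(ord)) {
    idx <- sort(comp_idx[[ord[i]]])
    out[[i]] <- new_cell_cluster(idx, label = i, shape = c(nr, nc),
                                 connectivity = connectivity)
  }
  out
}

new_cell_cluster <- function(linear_idx, label, shape, connectivity = 8L) {
  nr <- shape[1L]
  y <- ((linear_idx - 1L) %% nr)          # 0-based row
  x <- ((linear_idx - 1L) %/% nr)         # 0-based col
  structure(list(label = as.integer(label),
                 pixels = cbind(x = x, y = y),
                 area = length(linear_idx),
                 shape = as.integer(shape),
                 connectivity = as.integer(connectivity)),
            class = "cell_cluster")
}

cluster_mask <- function(cluster) {
  m <- matrix(FALSE, cluster$shape[1L], cluster$shape[2L])
  m[cbind(cluster$pixels[, "y"] + 1L, cluster$pixels[, "x"] + 1L)] <- TRUE
  m
}

#' Patch holes and drop small clusters
#'
#' Interior holes (background pixels not reachable from the image border
#' through the cluster's complement, 4-connectivity) are added to each
#' cluster; clusters whose post-fill area is below `min_area` are removed.
#' Surviving clusters are relabelled 1..n preserving order.
#'
#' @param clusters list of `cell_cluster`.
#' @param min_area minimum pixel area (default 500).
#' @return filtered list of hole-free `cell_cluster` objects.
#' @export
clean_clusters <- function(clusters, min_area = 500) {
  if (min_area < 0) stop("min_area must be >= 0", call. = FALSE)
  out <- list()
  for (cl in clusters) {
    filled <- fill_holes_cluster(cl)
    if (filled$area >= min_area) out[[length(out) + 1L]] <- filled
  }
  for (i in seq_along(out)) out[[i]]$label <- i
  out
}

fill_holes_cluster <- function(cluster) {
  px <- cluster$pixels
  # crop to bounding box with a 1-pixel margin so the border flood sees all
  # outside background as one region
  x0 <- min(px[, "x"]) - 1L; x1 <- max(px[, "x"]) + 1L
  y0 <- min(px[, "y"]) - 1L; y1 <- max(px[, "y"]) + 1L
  nr <- y1 - y0 + 1L; nc <- x1 - x0 + 1L
  m <- matrix(FALSE, nr, nc)
  m[cbind(px[, "y"] - y0 + 1L, px[, "x"] - x0 + 1L)] <- TRUE
  border <- unique(c(which(row(m) == 1L | row(m) == nr),
                     which(col(m) == 1L | col(m) == nc)))
  outside <- flood_from(!m, border, neighbor_offsets(4L))
  filled <- m | (!m & !outside)
  idx <- which(filled)
  y <- ((idx - 1L) %% nr) + y0
  x <- ((idx - 1L) %/% nr) + x0
  structure(list(label = cluster$label,
                 pixels = cbind(x = x, y = y)[order(x, y), , drop = FALSE],
                 area = length(idx),
                 shape = cluster$shape,
                 connectivity = cluster$connectivity),
            class = "cell_cluster")
}

#' Trace the outer boundary of a cluster
#'
#' Moore-neighbour tracing with Jacob's stopping criterion on a hole-free,
#' connected cluster. The returned chain is closed (last point joins the
#' first implicitly) and oriented counter-clockwise with respect to the
#' (x, y) axes (positive shoelace area). One-pixel-wide arms are traversed
#' out and back, so a pixel may appear twice in the chain.
#'
#' @param cluster a `cell_cluster`.
#' @return n x 2 matrix of 0-based (x, y) boundary pixels in order.
#' @export
trace_boundary <- function(cluster) {
  if (cluster$area < 3L)
    stop("cluster too small to trace (area < 3)", call. = FALSE)
  m <- cluster_mask(cluster)
  nr <- nrow(m); nc <- ncol(m)
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && m[r, c]
  # start: topmost row, then leftmost column
  px <- cluster$pixels
  ymin <- min(px[, "y"])
  xmin <- min(px[px[, "y"] == ymin, "x"])
  sr <- ymin + 1L; sc <- xmin + 1L
  # clockwise Moore neighbourhood in image coordinates (row down)
  moore <- cbind(dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
                 dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))
  b0 <- c(sr, sc - 1L)  # backtrack: west of start, background by construction
  chain <- matrix(0L, 0L, 2L)
  p <- c(sr, sc); b <- b0
  first <- TRUE
  max_steps <- 4L * cluster$area + 8L
  for (step in seq_len(max_steps)) {
    if (!first && p[1L] == sr && p[2L] == sc && b[1L] == b0[1L] && b[2L] == b0[2L])
      break
    chain <- rbind(chain, p)
    first <- FALSE
    # index of backtrack within the Moore ring around p
    start_k <- which(moore[, 1L] == b[1L] - p[1L] & moore[, 2L] == b[2L] - p[2L])
    found <- FALSE
    prev <- b
    for (s in 1:8) {
      k <- ((start_k - 1L + s) %% 8L) + 1L
      q <- c(p[1L] + moore[k, 1L], p[2L] + moore[k, 2L])
      if (fg(q[1L], q[2L])) {
        b <- prev; p <- q; found <- TRUE
        break
      }
      prev <- q
    }
    if (!found) break  # isolated pixel (cannot happen for area >= 3 connected)
  }
  out <- cbind(x = chain[, 2L] - 1L, y = chain[, 1L] - 1L)
  rownames(out) <- NULL
  if (nrow(out) >= 3L && polygon_area(out) < 0)
    out <- out[c(1L, nrow(out):2L), , drop = FALSE]
  out
}

#' Douglas-Peucker contour approximation
#'
#' Simplifies a closed boundary chain with tolerance
#' `eps = epsilon_rel * perimeter`. The closed chain is split at its two
#' mutually farthest points (ties broken by lowest index) and each half is
#' simplified by the classic recursive procedure; returned vertices are a
#' subset of the input points and every input point lies within `eps` of the
#' output polygon.
#'
#' @param boundary n x 2 matrix of ordered (x, y) boundary points (closed).
#' @param epsilon_rel tolerance as a fraction of the chain perimeter
#'   (default 0.009).
#' @param source_label cluster label carried into the contour.
#' @return a `cell_contour` with fields `vertices`, `source_label`,
#'   `perimeter` (of the pre-approximation chain).
#' @export
approximate_contour <- function(boundary, epsilon_rel = 0.009,
                                source_label = NA_integer_) {
  boundary <- as.matrix(boundary)
  if (nrow(boundary) < 3L)
    stop("need at least 3 boundary points", call. = FALSE)
  if (!is.numeric(epsilon_rel) || epsilon_rel <= 0)
    stop("epsilon_rel must be > 0", call. = FALSE)
  perim <- chain_perimeter(boundary)
  eps <- epsilon_rel * perim
  keep <- dp_closed(boundary, eps)
  if (length(keep) < 3L)
    stop("degenerate contour: approximation left fewer than 3 vertices",
         call. = FALSE)
  structure(list(vertices = boundary[keep, , drop = FALSE],
                 source_label = source_label,
                 perimeter = perim),
            class = "cell_contour")
}

#' @export
print.cell_contour <- function(x, ...) {
  cat(sprintf("<cell_contour label %s: %d vertices, source perimeter %.1f px>\n",
              x$source_label, nrow(x$vertices), x$perimeter))
  invisible(x)
}

# Closed-chain DP: seed with the two mutually farthest points, simplify the
# two open halves, return sorted indices of kept points.
dp_closed <- function(pts, eps) {
  n <- nrow(pts)
  # farthest pair; ties -> lowest i then lowest j
  best <- c(1L, 2L); bestd <- -1
  for (i in seq_len(n - 1L)) {
    d2 <- (pts[(i + 1L):n, 1L] - pts[i, 1L])^2 +
          (pts[(i + 1L):n, 2L] - pts[i, 2L])^2
    k <- which.max(d2)
    if (d2[k] > bestd) {
      bestd <- d2[k]; best <- c(i, i + k)
    }
  }
  i <- best[1L]; j <- best[2L]
  half1 <- i:j
  half2 <- c(j:n, 1:i)
  keep1 <- half1[dp_open(pts[half1, , drop = FALSE], eps)]
  keep2 <- half2[dp_open(pts[half2, , drop = FALSE], eps)]
  sort(unique(c(keep1, keep2)))
}

# Open-chain recursive DP; returns indices (into pts) of kept points.
dp_open <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2L) return(seq_len(n))
  d <- point_segment_distance(pts[2:(n - 1L), 1L], pts[2:(n - 1L), 2L],
                              pts[1L, ], pts[n, ])
  k <- which.max(d)  # lowest index on ties
  if (d[k] <= eps) return(c(1L, n))
  split <- k + 1L
  left <- dp_open(pts[1:split, , drop = FALSE], eps)
  right <- dp_open(pts[split:n, , drop = FALSE], eps)
  c(left, split + right[-1L] - 1L)
}

#' Segment cells end-to-end
#'
#' Full preprocessing chain: optional binarisation, erosion, connected
#' components, hole patching / small-cluster removal, boundary tracing and
#' contour approximation.
#'
#' @param image `intensity_image` of the cell/shape channel, or NULL if a
#'   `mask` is supplied.
#' @param mask optional logical matrix overriding binarisation.
#' @param config a [default_config()] list; relevant keys: threshold_method,
#'   threshold_value, erosion_radius, connectivity, min_area, epsilon_rel.
#' @return list with `clusters` (post-clean) and `contours` (one
#'   `cell_contour` per cluster).
#' @export
segment_cells <- function(image = NULL, mask = NULL, config = default_config()) {
  config <- validate_config(config)
  if (is.null(mask)) {
    if (is.null(image)) stop("need an image or a mask", call. = FALSE)
    mask <- binarize(image, method = config$threshold_method,
                     threshold = config$threshold_value)
  }
  eroded <- erode_mask(mask, config$erosion_radius)
  clusters <- label_clusters(eroded, config$connectivity)
  clusters <- clean_clusters(clusters, config$min_area)
  contours <- lapply(clusters, function(cl) {
    approximate_contour(trace_boundary(cl), config$epsilon_rel,
                        source_label = cl$label)
  })
  list(clusters = clusters, contours = contours)
}
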