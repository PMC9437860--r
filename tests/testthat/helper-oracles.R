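# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive (explicit loops, no shared code with the package
# internals beyond basic geometry).

# Erosion by explicit structuring-element sweep.
brute_erode <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  r <- ceiling(radius)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 > radius^2 + 1e-9) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj]) {
        ok <- FALSE; break
      }
    }
    out[i, j] <- ok
  }
  out
}

# Connected components by stack-based flood fill; returns label matrix.
brute_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- cur
      i <- ((p - 1L) %% nr) + 1L; j <- ((p - 1L) %/% nr) + 1L
      for (o in offs) {
        ii <- i + o[1L]; jj <- j + o[2L]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L)
          stack <- c(stack, (jj - 1L) * nr + ii)
      }
    }
  }
  lab
}

# Exhaustive enclosed-pixel test: background pixel is a hole iff a flood
# from it (4-connectivity over background) never reaches the border.
brute_fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  stack <- unique(c(which(!mask & (row(mask) == 1 | row(mask) == nr)),
                    which(!mask & (col(mask) == 1 | col(mask) == nc))))
  while (length(stack)) {
    p <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (reach[p]) next
    reach[p] <- TRUE
    i <- ((p - 1L) %% nr) + 1L; j <- ((p - 1L) %/% nr) + 1L
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + o[1L]; jj <- j + o[2L]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          !mask[ii, jj] && !reach[ii, jj])
        stack <- c(stack, (jj - 1L) * nr + ii)
    }
  }
  mask | (!mask & !reach)
}

# Boundary pixel set: true pixels with at least one false 4-neighbour
# (pixels beyond the border count as false).
brute_boundary_set <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    nb_false <- FALSE
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + o[1L]; jj <- j + o[2L]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj]) {
        nb_false <- TRUE; break
      }
    }
    if (nb_false) out <- rbind(out, c(j - 1L, i - 1L))  # (x, y), 0-based
  }
  out
}

# Reference recursive Douglas-Peucker on a closed chain, seeded at the two
# mutually farthest points (ties: lowest index pair). Independent of the
# package implementation; returns the kept row indices, sorted.
ref_dp_closed <- function(pts, eps) {
  n <- nrow(pts)
  seg_dist <- function(p, a, b) {
    ab <- b - a
    L2 <- sum(ab^2)
    if (L2 == 0) return(sqrt(sum((p - a)^2)))
    tt <- max(0, min(1, sum((p - a) * ab) / L2))
    sqrt(sum((p - a - tt * ab)^2))
  }
  rec <- function(idx) {
    m <- length(idx)
    if (m <= 2) return(idx)
    a <- pts[idx[1], ]; b <- pts[idx[m], ]
    dmax <- -1; kmax <- 0
    for (k in 2:(m - 1)) {
      d <- seg_dist(pts[idx[k], ], a, b)
      if (d > dmax) { dmax <- d; kmax <- k }
    }
    if (dmax <= eps) return(c(idx[1], idx[m]))
    c(rec(idx[1:kmax]), rec(idx[kmax:m])[-1])
  }
  best_i <- 1; best_j <- 2; best_d <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sum((pts[i, ] - pts[j, ])^2)
    if (d > best_d) { best_d <- d; best_i <- i; best_j <- j }
  }
  half1 <- best_i:best_j
  half2 <- c(best_j:n, 1:best_i)
  sort(unique(c(rec(half1), rec(half2))))
}

# Random simple closed chain: star-shaped polygon with sorted angles.
random_closed_chain <- function(n, radius = 50, jitter = 0.5) {
  theta <- sort(stats::runif(n, 0, 2 * pi))
  r <- radius * (1 + jitter * (stats::runif(n) - 0.5))
  cbind(x = r * cos(theta), y = r * sin(theta))
}

# Brute per-pixel radial binning for a uniform disk profile.
brute_disk_cumulative <- function(img_mat, cx, cy, R, n_bins = 10) {
  sums <- numeric(n_bins)
  nr <- nrow(img_mat); nc <- ncol(img_mat)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r <- sqrt((j - 1 - cx)^2 + (i - 1 - cy)^2)
    if (r > R) next
    k <- min(n_bins, max(1L, ceiling(r / R * n_bins)))
    sums[k] <- sums[k] + img_mat[i, j]
  }
  cumsum(sums) / sum(sums)
}

# Exhaustive optimal bipartite matching (minimum total distance) for small
# linking problems.
brute_optimal_matching <- function(a, b, max_disp) {
  na <- nrow(a); nb <- nrow(b)
  idx <- seq_len(nb)
  best <- NULL; best_cost <- Inf
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (p in perms(idx)) {
    cost <- 0; ok <- TRUE
    m <- min(na, nb)
    for (i in seq_len(m)) {
      d <- sqrt(sum((a[i, ] - b[p[i], ])^2))
      if (d > max_disp) { ok <- FALSE; break }
      cost <- cost + d
    }
    if (ok && cost < best_cost) { best_cost <- cost; best <- p[seq_len(m)] }
  }
  list(match = best, cost = best_cost)
}

# Build a Gaussian-spot time lapse directly (independent of the synthetic
# module) for tracking tests.
make_spot_stack <- function(n_frames, starts_xy, v_xy, size = c(60, 200),
                            amplitude = 200, sigma = 1.5, background = 10,
                            noise_seed = NULL) {
  frames <- lapply(seq_len(n_frames), function(t) {
    img <- matrix(background, size[1], size[2])
    for (i in seq_len(nrow(starts_xy))) {
      x <- starts_xy[i, 1] + v_xy[i, 1] * (t - 1)
      y <- starts_xy[i, 2] + v_xy[i, 2] * (t - 1)
      xs <- max(0, floor(x - 6)):min(size[2] - 1, ceiling(x + 6))
      ys <- max(0, floor(y - 6)):min(size[1] - 1, ceiling(y + 6))
      img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] +
        amplitude * exp(-outer((ys - y)^2, (xs - x)^2, `+`) / (2 * sigma^2))
    }
    img
  })
  if (!is.null(noise_seed)) {
    set.seed(noise_seed)
    frames <- lapply(frames, function(f)
      pmax(matrix(stats::rpois(length(f), f), nrow(f)) +
             matrix(stats::rnorm(length(f), 0, 3), nrow(f)), 0))
  }
  time_lapse(frames, dt = 1, pixel_size = 0.1)
}

# Circle contour helper.
circle_contour <- function(cx, cy, R, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  verts <- cbind(x = cx + R * cos(th), y = cy + R * sin(th))
  structure(list(vertices = verts, source_label = 1L,
                 perimeter = orgaprof:::chain_perimeter(verts)),
            class = "cell_contour")
}
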