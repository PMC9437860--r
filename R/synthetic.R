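# Seeded generators for star-convex cell images with punctate organelle
# signal (radial placement drawn from a Beta law over normalized radius) and
# for time-lapses of puncta moving along a path in anterograde / retrograde /
# stationary populations. Ground truth is returned alongside every fixture.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic cell image
#'
#' @param image_size side length in pixels (square image).
#' @param mean_radius mean cell radius in pixels (>= 10).
#' @param roughness relative radial roughness of the star-convex outline.
#' @param n_lobes number of angular harmonics in the outline.
#' @param n_puncta number of organelle puncta.
#' @param beta_a,beta_b shape parameters of the Beta law over normalized
#'   radius in `[0, 1]`: `Beta(1, 3)` is perinuclear, `Beta(3, 1)`
#'   peripheral, `Beta(1, 1)` uniform-in-radius.
#' @param amplitude peak punctum amplitude (photons).
#' @param psf_sigma Gaussian PSF sigma in pixels.
#' @param background flat background level (photons).
#' @param shape_level uniform cytoplasmic signal of the shape channel.
#' @param poisson_noise apply Poisson photon noise.
#' @param read_noise Gaussian read-noise sigma (0 disables).
#' @param concave if TRUE, generate a deliberately non-star-convex outline
#'   (for warning-path tests).
#' @param seed RNG seed; identical spec + seed gives bit-identical output.
#' @return a `synthetic_cell_spec` list.
#' @export
synthetic_cell_spec <- function(image_size = 256, mean_radius = 80,
                                roughness = 0.12, n_lobes = 5,
                                n_puncta = 200, beta_a = 1, beta_b = 1,
                                amplitude = 200, psf_sigma = 1.5,
                                background = 100, shape_level = 300,
                                poisson_noise = TRUE, read_noise = 3,
                                concave = FALSE, seed = 1) {
  stopifnot(beta_a > 0, beta_b > 0, n_puncta >= 0, mean_radius >= 10)
  structure(as.list(environment()), class = "synthetic_cell_spec")
}

# Star-convex outline: radius as a truncated Fourier series in the angle.
star_convex_radius <- function(theta, mean_radius, roughness, n_lobes,
                               coefs, phases) {
  s <- rep(0, length(theta))
  for (j in seq_len(n_lobes))
    s <- s + coefs[j] * cos(j * theta + phases[j])
  mean_radius * pmax(0.25, 1 + roughness * s / sqrt(sum(coefs^2) / 2 + 1e-12))
}

add_gaussian_spot <- function(img, x, y, amplitude, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(4 * sigma)
  if (x - r > nc - 1L || x + r < 0 || y - r > nr - 1L || y + r < 0)
    return(img)  # entirely outside the frame
  xs <- max(0L, floor(x - r)):min(nc - 1L, ceiling(x + r))
  ys <- max(0L, floor(y - r)):min(nr - 1L, ceiling(y + r))
  gx <- exp(-(xs - x)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y)^2 / (2 * sigma^2))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + amplitude * outer(gy, gx)
  img
}

apply_noise <- function(img, poisson_noise, read_noise) {
  if (poisson_noise) img <- matrix(stats::rpois(length(img), img),
                                   nrow(img), ncol(img))
  if (read_noise > 0) img <- img + matrix(stats::rnorm(length(img), 0, read_noise),
                                          nrow(img), ncol(img))
  pmax(img, 0)
}

#' Generate one synthetic cell
#'
#' Draws a star-convex outline, places `n_puncta` puncta at normalized radii
#' drawn from `Beta(beta_a, beta_b)` along uniformly random directions from
#' the center (scaled by the outline's boundary distance in that direction),
#' renders them with a Gaussian PSF onto a flat background, and builds a
#' matching uniform-cytoplasm shape channel. Identical spec + seed gives
#' bit-identical output.
#'
#' @param spec a [synthetic_cell_spec()].
#' @return list with `organelle` and `shape` (`intensity_image`), `contour`
#'   (ground-truth `cell_contour`), `center` (x, y) and `truth` (data.frame:
#'   punctum, norm_radius, angle, x, y).
#' @export
generate_cell <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  with_seed(spec$seed, {
    n <- spec$image_size
    center <- c(n, n) / 2 - 0.5
    n_vert <- 72L
    theta <- seq(0, 2 * pi, length.out = n_vert + 1L)[-(n_vert + 1L)]
    coefs <- stats::rnorm(spec$n_lobes)
    phases <- stats::runif(spec$n_lobes, 0, 2 * pi)
    rad <- star_convex_radius(theta, spec$mean_radius, spec$roughness,
                              spec$n_lobes, coefs, phases)
    if (spec$concave) {
      # carve two wide notches, each with a full-radius spike inside: the
      # spike flanks are occluded from off-axis interior points and the two
      # distinct notch axes leave (almost) no common star center
      for (ax in c(pi, pi / 2)) {
        a <- abs(((theta - ax) + pi) %% (2 * pi) - pi)
        rad[a > 0.1 & a <= 0.6] <- rad[a > 0.1 & a <= 0.6] * 0.25
      }
    }
    verts <- cbind(x = center[1L] + rad * cos(theta),
                   y = center[2L] + rad * sin(theta))
    contour <- structure(list(vertices = verts, source_label = 1L,
                              perimeter = chain_perimeter(verts)),
                         class = "cell_contour")
    # puncta: normalized radius ~ Beta(a, b), direction ~ U(0, 2pi)
    u <- if (spec$n_puncta > 0) stats::rbeta(spec$n_puncta, spec$beta_a, spec$beta_b)
         else numeric(0)
    phi <- if (spec$n_puncta > 0) stats::runif(spec$n_puncta, 0, 2 * pi)
           else numeric(0)
    rphi <- star_convex_radius(phi, spec$mean_radius, spec$roughness,
                               spec$n_lobes, coefs, phases)
    if (spec$concave) {
      for (ax in c(pi, pi / 2)) {
        a <- abs(((phi - ax) + pi) %% (2 * pi) - pi)
        rphi[a > 0.1 & a <= 0.6] <- rphi[a > 0.1 & a <= 0.6] * 0.25
      }
    }
    pxs <- center[1L] + u * rphi * cos(phi)
    pys <- center[2L] + u * rphi * sin(phi)
    org <- matrix(spec$background, n, n)
    for (i in seq_len(spec$n_puncta))
      org <- add_gaussian_spot(org, pxs[i], pys[i], spec$amplitude,
                               spec$psf_sigma)
    shape <- matrix(spec$background, n, n)
    g <- expand.grid(x = 0:(n - 1L), y = 0:(n - 1L))
    inside <- point_in_polygon(g$x, g$y, verts)
    shape[cbind(g$y[inside] + 1L, g$x[inside] + 1L)] <-
      spec$background + spec$shape_level
    org <- apply_noise(org, spec$poisson_noise, spec$read_noise)
    shape <- apply_noise(shape, spec$poisson_noise, spec$read_noise)
    list(organelle = intensity_image(org),
         shape = intensity_image(shape),
         contour = contour,
         center = center,
         truth = data.frame(punctum = seq_len(spec$n_puncta),
                            norm_radius = u, angle = phi, x = pxs, y = pys))
  })
}

#' Specification of a synthetic transport time-lapse
#'
#' Defaults mirror a 70-frame, 1 s/frame acquisition.
#'
#' @param n_frames frames (default 70).
#' @param dt seconds per frame (default 1).
#' @param n_antero,n_retro,n_stationary population sizes.
#' @param v_antero,v_retro signed velocities in px/frame along the path
#'   (anterograde positive, retrograde negative).
#' @param amplitude,psf_sigma,background,poisson_noise,read_noise punctum
#'   photophysics as in [synthetic_cell_spec()].
#' @param min_separation minimum initial arc-length separation between
#'   puncta (pixels).
#' @param margin path-end margin no punctum may enter (pixels).
#' @param seed RNG seed.
#' @return a `synthetic_motion_spec` list.
#' @export
synthetic_motion_spec <- function(n_frames = 70, dt = 1,
                                  n_antero = 10, n_retro = 10,
                                  n_stationary = 10,
                                  v_antero = 2, v_retro = -2,
                                  amplitude = 300, psf_sigma = 1.5,
                                  background = 50, poisson_noise = TRUE,
                                  read_noise = 3, min_separation = 5,
                                  margin = 3, seed = 1) {
  stopifnot(n_frames >= 2, dt > 0, v_antero > 0, v_retro < 0)
  structure(as.list(environment()), class = "synthetic_motion_spec")
}

#' Generate a transport time-lapse along a path
#'
#' Each punctum advances at its population velocity along the path and is
#' rendered as a Gaussian spot per frame. Initial arc positions are drawn
#' uniformly from the feasible range (so no punctum exits the path within
#' `n_frames`) with a minimum pairwise separation at t = 0.
#'
#' @param spec a [synthetic_motion_spec()].
#' @param path a `path_spec`.
#' @param image_size c(height, width); default fits the path with a margin.
#' @return list with `stack` (`time_lapse`) and `truth` (data.frame:
#'   punctum, label, velocity, plus per-frame arc positions in
#'   `positions` attribute: matrix puncta x frames).
#' @export
generate_timelapse <- function(spec, path, image_size = NULL) {
  stopifnot(inherits(spec, "synthetic_motion_spec"),
            inherits(path, "path_spec"))
  L <- path$length
  n_total <- spec$n_antero + spec$n_retro + spec$n_stationary
  vels <- c(rep(spec$v_antero, spec$n_antero),
            rep(spec$v_retro, spec$n_retro),
            rep(0, spec$n_stationary))
  labels <- c(rep("anterograde", spec$n_antero),
              rep("retrograde", spec$n_retro),
              rep("stationary", spec$n_stationary))
  span <- vels * (spec$n_frames - 1)
  lo <- spec$margin + pmax(0, -span)
  hi <- L - spec$margin - pmax(0, span)
  bad <- which(hi < lo)
  if (length(bad))
    stop(sprintf("punctum %d (%s) would exit the path: needs %.0f px, have %.0f",
                 bad[1L], labels[bad[1L]], abs(span[bad[1L]]) + 2 * spec$margin, L),
         call. = FALSE)
  if (is.null(image_size)) {
    bb <- apply(path$vertices, 2L, range)
    m <- ceiling(path$width / 2) + 6L
    image_size <- c(ceiling(bb[2L, 2L]) + m + 1L, ceiling(bb[2L, 1L]) + m + 1L)
  }
  with_seed(spec$seed, {
    # rejection-sample starts with minimum pairwise separation at t = 0
    starts <- numeric(0)
    for (i in seq_len(n_total)) {
      ok <- FALSE
      for (attempt in 1:200) {
        s0 <- stats::runif(1, lo[i], hi[i])
        if (!length(starts) || min(abs(starts - s0)) >= spec$min_separation) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf("could not place punctum %d with min_separation %.1f",
                     i, spec$min_separation), call. = FALSE)
      starts <- c(starts, s0)
    }
    positions <- outer(starts, rep(1, spec$n_frames)) +
      outer(vels, 0:(spec$n_frames - 1))
    frames <- vector("list", spec$n_frames)
    for (t in seq_len(spec$n_frames)) {
      img <- matrix(spec$background, image_size[1L], image_size[2L])
      pp <- path_point(path, positions[, t])
      for (i in seq_len(n_total))
        img <- add_gaussian_spot(img, pp$x[i], pp$y[i], spec$amplitude,
                                 spec$psf_sigma)
      frames[[t]] <- apply_noise(img, spec$poisson_noise, spec$read_noise)
    }
    truth <- data.frame(punctum = seq_len(n_total), label = labels,
                        velocity = vels, start = starts)
    attr(truth, "positions") <- positions
    list(stack = time_lapse(frames, dt = spec$dt), truth = truth)
  })
}
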