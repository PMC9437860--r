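square_contour <- function(side = 20, x0 = 5, y0 = 5) {
  verts <- cbind(x = c(x0, x0 + side, x0 + side, x0),
                 y = c(y0, y0, y0 + side, y0 + side))
  structure(list(vertices = verts, source_label = 1L,
                 perimeter = 4 * side), class = "cell_contour")
}

test_that("select_center: centroid, manual validation, pole fallback", {
  sq <- square_contour()
  expect_equal(select_center(sq, "centroid"), c(15, 15))
  expect_equal(select_center(sq, "manual", point = c(12, 18)), c(12, 18))
  expect_error(select_center(sq, "manual", point = c(50, 50)), "outside")

  # thin L-shape whose centroid falls outside the polygon
  L <- structure(list(vertices = cbind(
    x = c(0, 30, 30, 2, 2, 0), y = c(0, 0, 2, 2, 30, 30)),
    source_label = 1L, perimeter = 120), class = "cell_contour")
  centroid <- orgaprof:::polygon_centroid(L$vertices)
  expect_false(point_in_polygon(centroid[1], centroid[2], L$vertices))
  expect_warning(ctr <- select_center(L, "centroid"), "pole")
  expect_true(point_in_polygon(ctr[1], ctr[2], L$vertices))
  # oracle: dense grid search of the pole of inaccessibility
  g <- expand.grid(x = seq(0, 30, by = 0.15), y = seq(0, 30, by = 0.15))
  ins <- point_in_polygon(g$x, g$y, L$vertices)
  dmax <- max(orgaprof:::point_polygon_distance(g$x[ins], g$y[ins], L$vertices))
  dctr <- orgaprof:::point_polygon_distance(ctr[1], ctr[2], L$vertices)
  expect_gt(dctr, 0.85 * dmax)
})

test_that("build_shells implements center + d * (periphery - center)", {
  tri <- structure(list(vertices = cbind(x = c(10, -10, 0), y = c(0, 0, 15)),
                        source_label = 1L, perimeter = 50),
                   class = "cell_contour")
  sh <- build_shells(tri, c(0, 3), n_increments = 10)
  # vertex scaling example: d = 0.3 along the center->vertex vector
  expect_equal(sh$polygons[[3]][1, ],
               c(x = 0 + 0.3 * (10 - 0), y = 3 + 0.3 * (0 - 3)))
  # d = 1 reproduces the contour exactly
  expect_equal(sh$polygons[[10]], tri$vertices, ignore_attr = TRUE)
  expect_equal(sh$fractions, seq(0.1, 1, by = 0.1))

  expect_error(build_shells(tri, c(100, 100)), "outside")
  expect_error(build_shells(tri, c(0, 3), n_increments = 1), "increments")

  # nesting for convex contours: all vertices of polygon(d1) inside polygon(d2)
  sq <- square_contour()
  shs <- build_shells(sq, c(12, 13))
  for (k1 in 1:9) for (k2 in (k1 + 1):10) {
    p1 <- shs$polygons[[k1]]
    expect_true(all(point_in_polygon(p1[, 1] * 0.999 + shs$center[1] * 0.001,
                                     p1[, 2] * 0.999 + shs$center[2] * 0.001,
                                     shs$polygons[[k2]])))
  }
  expect_false(any(shs$self_intersecting))
})

test_that("non-star-convex contours are flagged", {
  cell <- generate_cell(synthetic_cell_spec(seed = 8, concave = TRUE,
                                            image_size = 200, mean_radius = 60,
                                            roughness = 0.05))
  ctr <- select_center(cell$contour, "centroid")
  expect_warning(sh <- build_shells(cell$contour, ctr), "star-shaped")
  p <- cumulative_profile(cell$organelle, sh, cell_id = 1)
  expect_true(p$flagged)
})

test_that("cumulative_profile: delta, zero image, uniform disk law", {
  sq <- square_contour(side = 40, x0 = 10, y0 = 10)
  sh <- build_shells(sq, c(30, 30))
  img <- matrix(0, 60, 60)
  img[31, 31] <- 99
  p <- cumulative_profile(img, sh, cell_id = 1)
  expect_equal(p$cumulative, rep(1, 10))
  expect_equal(profile_auc(p), 1)

  pz <- cumulative_profile(matrix(0, 60, 60), sh)
  expect_false(pz$valid)
  expect_equal(pz$cumulative, rep(0, 10))
  expect_error(profile_auc(pz), "invalid")

  # uniform disk: cumulative[k] ~ d_k^2
  n <- 260; R <- 120; ctr <- (n - 1) / 2
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  img2 <- matrix(0, n, n)
  inside <- (g$x - ctr)^2 + (g$y - ctr)^2 <= R^2
  img2[cbind(g$y[inside] + 1, g$x[inside] + 1)] <- 7
  pd <- cumulative_profile(img2, build_shells(circle_contour(ctr, ctr, R),
                                              c(ctr, ctr)))
  expect_lt(max(abs(pd$cumulative - seq(0.1, 1, 0.1)^2)), 0.02)
  expect_equal(profile_auc(pd), mean(pd$cumulative))
})

test_that("profiles are normalized, scale- and translation-equivariant", {
  for (seed in c(3, 14)) {
    cell <- generate_cell(synthetic_cell_spec(seed = seed, image_size = 180,
                                              mean_radius = 55, n_puncta = 120))
    ctr <- select_center(cell$contour, "centroid")
    sh <- build_shells(cell$contour, ctr)
    p <- cumulative_profile(cell$organelle, sh, cell_id = seed)
    expect_true(p$valid)
    expect_true(all(diff(p$cumulative) >= -1e-12))
    expect_equal(p$cumulative[10], 1, tolerance = 1e-9)
    expect_true(all(p$cumulative >= 0 & p$cumulative <= 1 + 1e-12))

    # scale equivariance
    p2 <- cumulative_profile(cell$organelle$pixels * 37.5, sh)
    expect_equal(p2$cumulative, p$cumulative, tolerance = 1e-12)

    # joint translation equivariance
    dx <- 6L; dy <- 9L
    big <- matrix(0, 180 + dy, 180 + dx)
    big[(dy + 1):(dy + 180), (dx + 1):(dx + 180)] <- cell$organelle$pixels
    shifted <- structure(list(
      vertices = cbind(x = cell$contour$vertices[, 1] + dx,
                       y = cell$contour$vertices[, 2] + dy),
      source_label = 1L, perimeter = cell$contour$perimeter),
      class = "cell_contour")
    p3 <- cumulative_profile(big, build_shells(shifted, ctr + c(dx, dy)))
    expect_equal(p3$cumulative, p$cumulative, tolerance = 1e-12)
  }
})

test_that("in-cell pixels are partitioned exactly once across shells", {
  cell <- generate_cell(synthetic_cell_spec(seed = 6, image_size = 160,
                                            mean_radius = 50, n_puncta = 80))
  ctr <- select_center(cell$contour, "centroid")
  sh <- build_shells(cell$contour, ctr)
  # constant image: shell sums then count pixels; total must equal the
  # brute-force count of pixel centers inside polygon(1.0)
  ones <- matrix(1, 160, 160)
  p <- cumulative_profile(ones, sh)
  g <- expand.grid(x = 0:159, y = 0:159)
  n_inside <- sum(point_in_polygon(g$x, g$y, cell$contour$vertices))
  expect_equal(sum(p$shell_intensity), n_inside)
  expect_equal(p$n_pixels, n_inside)
})

test_that("profile_auc encodes left-shift = perinuclear", {
  mk <- function(cum) structure(list(cell_id = 1, fractions = seq(.1, 1, .1),
                                     shell_intensity = diff(c(0, cum)),
                                     cumulative = cum, valid = TRUE,
                                     flagged = FALSE),
                                class = "radial_profile")
  expect_equal(profile_auc(mk(rep(1, 10))), 1)
  expect_equal(profile_auc(mk(c(rep(0, 9), 1))), 0.1)
})

test_that("compare_groups: degenerate examples and Welch/ANOVA oracles", {
  mk <- function(cum) structure(list(cell_id = 1, fractions = seq(.1, 1, .1),
                                     shell_intensity = diff(c(0, cum)),
                                     cumulative = cum, valid = TRUE,
                                     flagged = FALSE),
                                class = "radial_profile")
  g1 <- list(mk(seq(.1, 1, .1)), mk(seq(.1, 1, .1)))
  cmp0 <- compare_groups(list(a = g1, b = g1))
  expect_equal(cmp0$mean_auc[[1]], cmp0$mean_auc[[2]])
  expect_equal(cmp0$shift, "none")

  hi <- mk(c(rep(0.9, 9), 1)); lo <- mk(c(rep(0.12, 9), 1))
  cmp1 <- compare_groups(list(g1 = list(hi, hi), g2 = list(lo, lo)))
  expect_match(cmp1$shift, "peripheral in g2")

  # Welch statistic against stats::t.test to 1e-10
  set.seed(99)
  a <- lapply(stats::runif(8, .3, .6), function(u) mk(pmin(seq(.1, 1, .1) + u * .2, 1)))
  b <- lapply(stats::runif(9, .2, .5), function(u) mk(pmin(seq(.1, 1, .1) + u * .1, 1)))
  cmp <- compare_groups(list(A = a, B = b), "t_test")
  ta <- vapply(a, profile_auc, numeric(1)); tb <- vapply(b, profile_auc, numeric(1))
  ref <- stats::t.test(ta, tb)
  expect_equal(cmp$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(cmp$df, unname(ref$parameter), tolerance = 1e-8)

  # one-way ANOVA against stats::oneway.test(var.equal = TRUE)
  cc <- lapply(stats::runif(7, .1, .9), function(u) mk(pmin(seq(.1, 1, .1) + u * .15, 1)))
  cmp3 <- compare_groups(list(A = a, B = b, C = cc), "anova")
  tc <- vapply(cc, profile_auc, numeric(1))
  refa <- stats::oneway.test(v ~ g,
    data = data.frame(v = c(ta, tb, tc),
                      g = rep(c("A", "B", "C"), c(8, 9, 7))),
    var.equal = TRUE)
  expect_equal(cmp3$statistic, unname(refa$statistic), tolerance = 1e-10)
  expect_equal(cmp3$p_value, refa$p.value, tolerance = 1e-10)

  expect_error(compare_groups(list(a = g1)), "2 groups")
  expect_error(compare_groups(list(a = g1, b = list(hi))), "2 valid")
  bad <- structure(list(cell_id = 1, fractions = c(.5, 1),
                        shell_intensity = c(1, 1), cumulative = c(.5, 1),
                        valid = TRUE, flagged = FALSE),
                   class = "radial_profile")
  expect_error(compare_groups(list(a = g1, b = list(bad, bad))), "grid")
})
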