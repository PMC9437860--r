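test_that("erode_mask matches definition and brute-force sweep", {
  m <- matrix(TRUE, 10, 10)
  e <- erode_mask(m, 1)
  expect_equal(sum(e), 64)                 # 8x8 interior
  expect_true(all(e[2:9, 2:9]))

  single <- matrix(FALSE, 7, 7); single[4, 4] <- TRUE
  expect_false(any(erode_mask(single, 1)))

  # two 5x5 blocks joined by a 1-px bridge: erosion severs the bridge
  bridge <- matrix(FALSE, 7, 13)
  bridge[2:6, 1:5] <- TRUE; bridge[2:6, 9:13] <- TRUE; bridge[4, 6:8] <- TRUE
  er <- erode_mask(bridge, 1)
  expect_equal(er, brute_erode(bridge, 1))
  expect_equal(max(brute_components(er, 8)), 2)

  expect_equal(erode_mask(m, 0), m)
  expect_error(erode_mask(m, -1), "radius")
})

test_that("erosion is anti-extensive on random masks", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(stats::runif(400) > 0.35, 20, 20)
    e <- erode_mask(m, 2)
    expect_true(all(!e | m))               # output subset of input
    expect_equal(erode_mask(e, 0), e)
    expect_equal(e, brute_erode(m, 2))
  }
})

test_that("binarize: fixed and Otsu thresholds", {
  z <- matrix(0, 4, 4)
  expect_false(any(binarize(z, "fixed", threshold = 0)))  # strict >
  expect_true(all(binarize(matrix(5, 4, 4), "fixed", threshold = 4)))

  two <- matrix(c(rep(10, 30), rep(200, 18)), 6, 8)
  got <- binarize(two, "otsu")
  expect_equal(got, two > 100, ignore_attr = TRUE)

  expect_warning(res <- binarize(matrix(7, 5, 5), "otsu"), "degenerate")
  expect_false(any(res))
  expect_error(binarize(two, "fixed"), "threshold")
})

test_that("label_clusters partitions, sorts by size, honours connectivity", {
  expect_equal(label_clusters(matrix(FALSE, 3, 3)), list())

  diag2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_length(label_clusters(diag2, 4), 2)
  expect_length(label_clusters(diag2, 8), 1)

  m <- matrix(FALSE, 40, 40)
  m[2:11, 2:21] <- TRUE          # 200 px
  m[20:29, 2:6] <- TRUE          # 50 px
  m[35:37, 30:32] <- TRUE        # 9 px
  cl <- label_clusters(m, 8)
  expect_equal(vapply(cl, `[[`, numeric(1), "area"), c(200, 50, 9))
  expect_equal(vapply(cl, `[[`, integer(1), "label"), 1:3)
  # partition: union of pixel sets == true pixels, pairwise disjoint
  all_px <- do.call(rbind, lapply(cl, `[[`, "pixels"))
  expect_equal(nrow(all_px), sum(m))
  expect_equal(nrow(unique(all_px)), nrow(all_px))

  set.seed(21)
  r <- matrix(stats::runif(900) > 0.5, 30, 30)
  for (conn in c(4, 8)) {
    got <- label_clusters(r, conn)
    expect_equal(length(got), max(brute_components(r, conn)))
    expect_equal(sum(vapply(got, `[[`, numeric(1), "area")), sum(r))
  }
  expect_error(label_clusters(m, 6), "connectivity")
})

test_that("clean_clusters patches holes and drops small clusters", {
  # annulus outer radius 10, inner radius 4
  n <- 25; ctr <- 13
  g <- expand.grid(i = 1:n, j = 1:n)
  r <- sqrt((g$i - ctr)^2 + (g$j - ctr)^2)
  ann <- matrix(r <= 10 & r >= 4, n, n)
  disk_area <- sum(matrix(r <= 10, n, n))
  cl <- label_clusters(ann, 8)
  out <- clean_clusters(cl, min_area = 0)
  expect_length(out, 1)
  expect_equal(out[[1]]$area, disk_area)
  # oracle: exhaustive enclosed-pixel test
  expect_equal(out[[1]]$area, sum(brute_fill_holes(ann)))
  # no interior holes remain
  filled <- matrix(FALSE, n, n)
  filled[cbind(out[[1]]$pixels[, "y"] + 1, out[[1]]$pixels[, "x"] + 1)] <- TRUE
  expect_equal(filled, brute_fill_holes(filled))

  small <- label_clusters(matrix(c(rep(TRUE, 40), rep(FALSE, 60)), 10, 10), 8)
  expect_length(clean_clusters(small, min_area = 100), 0)
})

test_that("trace_boundary returns the CCW outer pixel chain", {
  block <- matrix(FALSE, 5, 5); block[2:4, 2:4] <- TRUE
  cl <- label_clusters(block, 8)[[1]]
  b <- trace_boundary(cl)
  expect_equal(nrow(b), 8)
  expect_true(orgaprof:::polygon_area(b) > 0)          # CCW convention
  expect_setequal(paste(b[, 1], b[, 2]),
                  paste(brute_boundary_set(block)[, 1],
                        brute_boundary_set(block)[, 2]))

  line <- matrix(FALSE, 3, 7); line[2, 2:6] <- TRUE
  cl2 <- label_clusters(line, 8)[[1]]
  b2 <- trace_boundary(cl2)
  expect_setequal(paste(unique(b2[, 1]), unique(b2[, 2])[1]),
                  paste(1:5, 1))

  set.seed(5)
  blob <- matrix(stats::runif(2500) > 0.4, 50, 50)
  big <- clean_clusters(label_clusters(blob, 8), 0)[[1]]
  bb <- trace_boundary(big)
  mask <- matrix(FALSE, 50, 50)
  mask[cbind(big$pixels[, "y"] + 1, big$pixels[, "x"] + 1)] <- TRUE
  oracle <- brute_boundary_set(mask)
  expect_setequal(paste(bb[, 1], bb[, 2]), paste(oracle[, 1], oracle[, 2]))

  tiny <- structure(list(label = 1L, pixels = cbind(x = 0:1, y = c(0L, 0L)),
                         area = 2L, shape = c(2L, 3L), connectivity = 8L),
                    class = "cell_cluster")
  expect_error(trace_boundary(tiny), "too small")
})

test_that("approximate_contour: rectangle, circle bound, degenerate error", {
  rect <- matrix(FALSE, 8, 12); rect[2:7, 2:11] <- TRUE
  b <- trace_boundary(label_clusters(rect, 8)[[1]])
  ct <- approximate_contour(b, 0.009)
  expect_equal(nrow(ct$vertices), 4)
  expect_setequal(paste(ct$vertices[, 1], ct$vertices[, 2]),
                  c("1 1", "10 1", "10 6", "1 6"))

  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- cbind(x = 100 * cos(th), y = 100 * sin(th))
  ct2 <- approximate_contour(circ, 0.009)
  eps <- 0.009 * ct2$perimeter
  d <- orgaprof:::point_polygon_distance(circ[, 1], circ[, 2], ct2$vertices)
  expect_lte(max(d), eps + 1e-9)
  expect_true(nrow(ct2$vertices) < 100)   # genuinely simplified

  # zig-zag whose excursions are all below eps collapses below 3 vertices
  zig <- cbind(x = c(seq(0, 10, by = 0.5), seq(10, 0, by = -0.5)),
               y = c(rep(c(0, 0.02), 10), 0, rep(c(1, 1.02), 10), 1))
  expect_error(approximate_contour(zig, 0.2), "degenerate")
  expect_error(approximate_contour(circ[1:2, ], 0.009), "3 boundary")
  expect_error(approximate_contour(circ, 0), "epsilon")
})

test_that("approximate_contour equals reference recursive DP on random chains", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    pts <- random_closed_chain(n)
    perim <- orgaprof:::chain_perimeter(pts)
    ct <- approximate_contour(pts, 0.009)
    keep_ref <- ref_dp_closed(pts, 0.009 * perim)
    expect_equal(ct$vertices, pts[keep_ref, , drop = FALSE],
                 ignore_attr = TRUE)
    d <- orgaprof:::point_polygon_distance(pts[, 1], pts[, 2], ct$vertices)
    expect_lte(max(d), 0.009 * perim + 1e-9)
  }
})

test_that("segment_cells runs the full chain on a synthetic cell", {
  cell <- generate_cell(synthetic_cell_spec(seed = 42, image_size = 200,
                                            mean_radius = 60))
  seg <- segment_cells(image = cell$shape)
  expect_length(seg$clusters, 1)
  expect_length(seg$contours, 1)
  expect_gte(nrow(seg$contours[[1]]$vertices), 3)
  # recovered contour lies close to the generating outline
  d <- orgaprof:::point_polygon_distance(seg$contours[[1]]$vertices[, 1],
                                         seg$contours[[1]]$vertices[, 2],
                                         cell$contour$vertices)
  expect_lt(max(d), 8)  # erosion radius 3 + approximation slack
})
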