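test_that("build_kymograph geometry: static and moving puncta", {
  # static punctum on a horizontal path -> constant bright row
  st <- make_spot_stack(10, cbind(50, 20), cbind(0, 0), size = c(40, 100))
  path <- path_spec(rbind(c(5, 20), c(95, 20)))
  km <- build_kymograph(st, path)
  expect_equal(ncol(km$matrix), 10)
  expect_equal(nrow(km$matrix), round(path$length) + 1)
  rows <- apply(km$matrix, 2, which.max)
  expect_true(all(rows == rows[1]))
  expect_equal(rows[1] - 1, 45)  # 50 - path start x 5

  # punctum moving at v px/frame -> sloped locus recovered by argmax
  v <- 2.5
  st2 <- make_spot_stack(20, cbind(10, 20), cbind(v, 0), size = c(40, 100))
  km2 <- build_kymograph(st2, path)
  trace <- apply(km2$matrix, 2, which.max) - 1
  planted <- (10 - 5) + v * (0:19)
  expect_true(all(abs(trace - planted) <= 0.5))

  # bounds error when the path (plus width window) exits the image
  bad <- path_spec(rbind(c(5, 1), c(95, 1)), width = 5)
  expect_error(build_kymograph(st, bad), "bounds")
})

test_that("70-frame stack gives a 70-column kymograph", {
  path <- path_spec(rbind(c(8, 15), c(178, 15)))
  spec <- synthetic_motion_spec(n_frames = 70, n_antero = 1, n_retro = 1,
                                n_stationary = 1, seed = 2,
                                poisson_noise = FALSE, read_noise = 0)
  sim <- generate_timelapse(spec, path)
  km <- build_kymograph(sim$stack, path)
  expect_equal(ncol(km$matrix), 70)
  expect_equal(km$dt, 1)
})

test_that("classify_track thresholds and scale consistency", {
  mk <- function(p0, p1) org_track(c(0, 5), positions = c(p0, p1))
  expect_equal(classify_track(mk(0, 10), 2), "anterograde")
  expect_equal(classify_track(mk(0, 0), 2), "stationary")
  expect_equal(classify_track(mk(0, -1.5), 2), "stationary")
  expect_equal(classify_track(mk(0, -5), 2), "retrograde")
  expect_error(classify_track(org_track(0L, positions = 1)), "short")

  set.seed(4)
  for (i in 1:20) {
    d <- stats::runif(1, -10, 10); thr <- stats::runif(1, 0.5, 5)
    expect_equal(classify_track(mk(0, d), thr),
                 classify_track(mk(0, 2 * d), 2 * thr))
  }
})

test_that("count_events tallies and propagates track errors", {
  ev0 <- count_events(list())
  expect_equal(c(ev0$anterograde, ev0$retrograde, ev0$stationary), c(0, 0, 0))

  mk <- function(d) org_track(c(0, 9), positions = c(0, d))
  ev <- count_events(lapply(c(5, 7, -6, 0), mk), stationary_threshold = 2)
  expect_equal(ev$anterograde, 2)
  expect_equal(ev$retrograde, 1)
  expect_equal(ev$stationary, 1)
  expect_equal(ev$anterograde + ev$retrograde + ev$stationary, 4)

  bad <- list(mk(3), org_track(0L, positions = 1))
  expect_error(count_events(bad), "track 2")
})

test_that("classify_processes applies the 3x-median rule", {
  expect_equal(classify_processes(c(300, 90, 80, 70)),
               c("axon", "dendrite", "dendrite", "dendrite"))
  expect_equal(classify_processes(c(100, 95)), c("dendrite", "dendrite"))
  expect_equal(classify_processes(c(240, 80, 80)),  # inclusive 3x boundary
               c("axon", "dendrite", "dendrite"))
  expect_error(classify_processes(100), "at least 2")
})

test_that("track_stats arithmetic", {
  tr <- org_track(0:4, positions = seq(0, 8, by = 2))
  st <- track_stats(tr, dt = 1, pixel_size = 0.1)
  expect_equal(st$duration_s, 4)
  expect_equal(st$displacement_um, 0.8)
  expect_equal(st$speed_um_per_s, 0.2)

  flat <- org_track(0:9, positions = rep(5, 10))
  expect_equal(track_stats(flat, 1, 0.1)$speed_um_per_s, 0)
  expect_error(track_stats(org_track(0L, positions = 0), 1, 1), "2 points")
})

test_that("end-to-end transport recovery and orientation swap", {
  L <- 2 * 69 + 40 * 5 + 30
  path <- path_spec(rbind(c(8, 15), c(8 + L, 15)))
  # noiseless: exact recovery
  spec <- synthetic_motion_spec(seed = 1, poisson_noise = FALSE,
                                read_noise = 0)
  sim <- generate_timelapse(spec, path)
  km <- build_kymograph(sim$stack, path)
  ev <- count_events(trace_kymograph(km, threshold = 100), 2)
  expect_equal(c(ev$anterograde, ev$retrograde, ev$stationary), c(10, 10, 10))

  # reversing the path swaps anterograde and retrograde exactly
  rev_path <- path_spec(path$vertices[2:1, ], width = path$width)
  km_r <- build_kymograph(sim$stack, rev_path)
  ev_r <- count_events(trace_kymograph(km_r, threshold = 100), 2)
  expect_equal(ev_r$anterograde, ev$retrograde)
  expect_equal(ev_r$retrograde, ev$anterograde)
  expect_equal(ev_r$stationary, ev$stationary)
})

test_that("single-spot locus traces match planted trajectories +- 0.5 px", {
  # the +-0.5 px bound is for an isolated spot (no merging with crossers)
  path <- path_spec(rbind(c(8, 15), c(308, 15)))
  pops <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (pop in pops) {
    spec <- synthetic_motion_spec(seed = 5, n_antero = pop[1],
                                  n_retro = pop[2], n_stationary = pop[3],
                                  poisson_noise = FALSE, read_noise = 0)
    sim <- generate_timelapse(spec, path)
    km <- build_kymograph(sim$stack, path)
    planted <- attr(sim$truth, "positions")[1, ]
    argmax <- apply(km$matrix, 2, which.max) - 1
    expect_true(all(abs(argmax - planted) <= 0.5))
    tracks <- trace_kymograph(km, threshold = 100)
    expect_length(tracks, 1)
    tr <- tracks[[1]]
    expect_true(all(abs(tr$positions - planted[tr$frames + 1]) <= 0.5))
    expect_equal(classify_track(tr, 2),
                 c("anterograde", "retrograde", "stationary")[which(pop == 1)])
  }
})
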