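test_that("contours close, resample evenly, and match analytic circles", {
  ct <- extract_contour(soft_disk(64, 15), n_points = 128)
  expect_equal(length(ct$x), 128L)
  expect_equal(ct$perimeter, 2 * pi * 15, tolerance = 0.02)
  expect_equal(ct$area, pi * 15^2, tolerance = 0.02)
  kap <- contour_curvature(ct)
  expect_true(all(abs(kap - 1 / 15) / (1 / 15) < 0.05))
  # pixel-size scaling
  ct_um <- extract_contour(soft_disk(64, 15), 128, pixel_size = 0.3)
  expect_equal(ct_um$perimeter, 2 * pi * 15 * 0.3, tolerance = 0.02)
  # open regions (touching the frame) and multi-component inputs fail
  open_m <- matrix(FALSE, 32, 32); open_m[1:16, 10:20] <- TRUE
  expect_error(extract_contour(open_m), "open contour|edge")
  two <- disk_mask(64, 8, cx = 20, cy = 20) | disk_mask(64, 8, cx = 48, cy = 48)
  expect_error(extract_contour(two), "multi-component")
})

test_that("curvature integrates to one full turn on diverse contours", {
  shapes <- list(soft_disk(64, 12),
                 ellipse_mask(2.5, 30, dim = 100),
                 multi_edge_mask(7, 0.5, seed = 2),
                 normalize_mask(basic_shapes()$mask[[7]], c(1, 0)))
  for (m in shapes) {
    ct <- extract_contour(m, 256)
    kap <- contour_curvature(ct)
    ds <- ct$perimeter / 256
    expect_equal(sum(kap * ds), 2 * pi, tolerance = 0.02)
  }
})

test_that("curvature kymograph shows persistent corner bands for a static square", {
  sq <- matrix(FALSE, 64, 64); sq[20:45, 20:45] <- TRUE
  series <- mask_series(rep(list(sq), 6), frame_interval = 5)
  ky <- curvature_kymograph(series, n_points = 128)
  expect_equal(dim(ky$values), c(128L, 6L))
  # the four highest-curvature boundary points sit at fixed coordinates
  peaks <- apply(ky$values, 2, function(v) which(v > quantile(v, 0.9)))
  for (j in 2:6) expect_equal(peaks[, j], peaks[, 1])
  # a static disk gives a near-constant kymograph at 1/R (pixelation of the
  # binary outline limits the pointwise accuracy)
  dser <- mask_series(rep(list(soft_disk(64, 14) >= 0.5), 4), 5)
  kd <- curvature_kymograph(dser, 128, harmonics = 6)
  expect_true(all(abs(kd$values - 1 / 14) < 0.25 / 14))
  expect_equal(mean(kd$values), 1 / 14, tolerance = 0.05)
})

test_that("registration keeps bands fixed under translation, drifts under rotation", {
  # translating rigid shape: after registration the corner bands of the
  # curvature kymograph stay at fixed boundary coordinates
  tri <- morphocell:::make_shape_mask("right_triangle", dim = 200L)
  base <- morphocell:::affine_mask(tri, 0, 0.28, 96L)
  masks <- lapply(0:5, function(i) {
    m <- matrix(FALSE, 96, 96)
    m[(1:96) > i & c(rep(FALSE, i), rep(TRUE, 96 - i))] <- FALSE  # no-op
    rr <- (seq_len(96 - i)); m[rr + i, ] <- base[rr, ]
    m
  })
  series <- mask_series(masks, frame_interval = 1)
  ky <- curvature_kymograph(series, n_points = 180)
  apex <- apply(ky$values, 2, which.max)
  circ_d <- function(a, b, n = 180) { d <- (a - b) %% n; pmin(d, n - d) }
  expect_true(all(circ_d(apex[-1], apex[1]) <= 4))
  # steadily rotating rigid shape: registered offsets drift monotonically
  rot <- lapply(0:8, function(i) {
    morphocell:::affine_mask(tri, angle = i * 6 * pi / 180, scale = 0.28,
                             out_dim = 64L)
  })
  kr <- curvature_kymograph(mask_series(rot, frame_interval = 1), 180)
  dr <- diff((kr$offsets + 90) %% 180)
  expect_true(all(dr >= 0))
  expect_gt(sum(dr), 0)
})

test_that("protrusion speed reads expansion, stasis and translation correctly", {
  # uniformly expanding disk: all speeds = dR/dt
  masks <- lapply(0:5, function(i) soft_disk(80, 12 + i) >= 0.5)
  ky <- protrusion_speed_kymograph(mask_series(masks, frame_interval = 2), 128)
  expect_equal(mean(ky$values[, -1]), 0.5, tolerance = 0.1)
  # pointwise scatter is bounded by the pixelation of the binary outlines
  expect_true(all(abs(ky$values[, -1] - 0.5) < 0.3))
  # static shape: speeds ~ 0
  st <- protrusion_speed_kymograph(
    mask_series(rep(list(soft_disk(64, 14) >= 0.5), 4), 2), 128)
  expect_true(all(abs(st$values) < 1e-6))
  # pure translation: positive at the front, negative at the rear
  tr <- translated_disk_series(6, dr = 2, dc = 0, r = 12, interval = 1)
  kt <- protrusion_speed_kymograph(tr, 128)
  v <- kt$values[, 4]
  ct <- morphocell:::shift_contour(kt$contours[[4]], kt$offsets[4])
  front <- ct$y > mean(ct$y) + 6   # moving toward increasing row
  rear <- ct$y < mean(ct$y) - 6
  expect_gt(mean(v[front]), 1.5)
  expect_lt(mean(v[rear]), -1.5)
  flank <- abs(ct$y - mean(ct$y)) < 3
  expect_lt(mean(abs(v[flank])), 0.7)
})

test_that("MSD handles ballistic, diffusive and persistent random walks", {
  # straight constant-velocity track: MSD = (v dT)^2, no crossover
  tr <- tibble::tibble(time = seq(0, 990, by = 10))
  tr$x <- 0.05 * tr$time; tr$y <- 0.02 * tr$time
  res <- msd_persistence(tr)
  v2 <- 0.05^2 + 0.02^2
  expect_equal(res$msd, v2 * res$lags^2, tolerance = 1e-10)
  expect_equal(res$slope_short, 2, tolerance = 0.01)
  expect_false(res$resolved)
  expect_true(is.na(res$tau0))
  # lattice random walk: long-lag slope ~ 1
  set.seed(21)
  n <- 4000
  steps <- matrix(sample(c(-1, 1), 2 * n, TRUE), ncol = 2)
  rw <- tibble::tibble(time = seq_len(n), x = cumsum(steps[, 1]),
                       y = cumsum(steps[, 2]))
  resrw <- msd_persistence(rw)
  expect_equal(resrw$slope_long, 1, tolerance = 0.1)
  # MSD is invariant to rigid motions of the track
  th <- 0.6
  rot <- tibble::tibble(time = rw$time,
                        x = cos(th) * rw$x - sin(th) * rw$y + 100,
                        y = sin(th) * rw$x + cos(th) * rw$y - 50)
  expect_equal(msd_persistence(rot)$msd, resrw$msd, tolerance = 1e-9)
})

test_that("persistence time is recovered across tau0 of 50, 100 and 200 s", {
  for (tau0 in c(50, 100, 200)) {
    tracks <- lapply(1:12, function(i) {
      run_and_tumble_track(4000, dt = 5, speed = 0.1, tau0 = tau0,
                           seed = 100 * tau0 + i)
    })
    res <- msd_persistence(tracks, max_lag_frac = 0.25)
    expect_true(res$resolved)
    expect_equal(res$tau0, tau0, tolerance = 0.2)
  }
})

test_that("pseudopod events are detected and typed from kymograph fixtures", {
  base <- matrix(0, 64, 40)
  times <- seq(0, 195, by = 5)
  mk_kymo <- function(values) {
    structure(list(values = values, what = "protrusion_speed",
                   contours = NULL, offsets = rep(0L, ncol(values)),
                   times = times[seq_len(ncol(values))], frame_interval = 5,
                   n_points = nrow(values), label = "fixture"),
              class = "kymograph")
  }
  # one isolated burst on a quiescent boundary -> a single de novo event
  v <- base
  v[10:18, 12:20] <- 1
  ev <- detect_pseudopod_events(mk_kymo(v), speed_threshold = 0.5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "de_novo")
  expect_equal(ev$onset_frame, 12L)
  # burst beside a persisting active front (small boundary gap) -> Y split
  v2 <- base
  v2[28:36, 5:30] <- 1           # long-lived parent front
  v2[39:45, 15:24] <- 1          # new protrusion appearing next to it
  ev2 <- detect_pseudopod_events(mk_kymo(v2), speed_threshold = 0.5)
  expect_equal(nrow(ev2), 2L)
  expect_true("y_split" %in% ev2$type)
  # the same new burst after the parent has died -> one-way split
  v3 <- base
  v3[28:36, 5:17] <- 1           # parent stops shortly after the new onset
  v3[39:45, 15:24] <- 1
  ev3 <- detect_pseudopod_events(mk_kymo(v3), speed_threshold = 0.5)
  expect_true("one_way_split" %in% ev3$type)
  # all-quiet kymograph -> no events
  expect_equal(nrow(detect_pseudopod_events(mk_kymo(base),
                                            speed_threshold = 0.5)), 0L)
})

test_that("pseudopod statistics compute fractions and extension angles", {
  # synthetic trajectory: disk translating down (increasing row)
  tr <- translated_disk_series(16, dr = 2, dc = 0, r = 12, interval = 5)
  ky <- protrusion_speed_kymograph(tr, 128)
  events <- tibble::tibble(event = 1:2, onset_time = c(10, 20),
                           onset_frame = c(3L, 5L),
                           boundary_index = c(1L, 1L),
                           boundary_frac = 0, type = c("de_novo", "y_split"),
                           duration = 3L, width_frac = 0.1)
  cent <- tibble::tibble(
    time = (seq_len(16) - 1) * 5,
    x = rep(32, 16),
    y = 32 + 2 * (seq_len(16) - 1))
  st <- pseudopod_statistics(events, ky, cent, extension_window = 10)
  expect_equal(st$fractions$fraction[st$fractions$type == "de_novo"], 0.5)
  expect_equal(sum(st$fractions$n), 2)
  expect_true(all(st$angles$angle >= 0 & st$angles$angle <= 180))
  # an event too near the end of the series is dropped and counted
  late <- events; late$onset_frame <- c(15L, 16L); late$onset_time <- c(70, 75)
  st2 <- pseudopod_statistics(late, ky, cent, extension_window = 100)
  expect_equal(st2$n_dropped, 2L)
})

test_that("mean cell length follows the motion-aligned extent", {
  tr <- translated_disk_series(12, dr = 1.5, dc = 0, r = 10, interval = 5)
  len <- mean_cell_length(tr)
  expect_equal(len, 21, tolerance = 0.06)   # disk of radius 10 px
})
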