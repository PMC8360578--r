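test_that("phase-field binarization keeps the largest component and logs fragments", {
  phi <- soft_disk(64, 12)
  m <- binarize_phase(phi)
  expect_equal(sum(m), sum(phi >= 0.5))
  # two components: a big disk and a small satellite
  two <- disk_mask(64, 11) | disk_mask(64, 3, cx = 58, cy = 58)
  m2 <- binarize_phase(two * 1)
  expect_equal(sum(m2), sum(disk_mask(64, 11)))
  expect_equal(attr(m2, "fragments"), sum(disk_mask(64, 3, cx = 58, cy = 58)))
  expect_error(binarize_phase(matrix(0, 8, 8)), "empty")
  # area of a tanh disk matches the analytic disk area within 3%
  phi5 <- soft_disk(128, 5 / 0.3, width = 1 / 0.3)
  expect_equal(sum(binarize_phase(phi5)), pi * 5^2 / 0.3^2,
               tolerance = 0.03)
})

test_that("mask centroid is the arithmetic mean of foreground pixels", {
  m <- matrix(FALSE, 64, 64)
  m[28:37, 28:37] <- TRUE
  expect_equal(unname(mask_centroid(m)), c(31.5, 31.5))
  m1 <- matrix(FALSE, 16, 16); m1[5, 9] <- TRUE
  expect_equal(unname(mask_centroid(m1)), c(4, 8))
  expect_equal(unname(mask_centroid(disk_mask(65, 20))),
               c(32, 32), tolerance = 0.01)
  expect_error(mask_centroid(matrix(FALSE, 4, 4)), "empty")
})

test_that("migration direction normalizes displacement and rejects jitter", {
  s <- translated_disk_series(12, dr = 1, dc = 0)
  expect_equal(unname(migration_direction(s, 6, 5)), c(1, 0),
               tolerance = 1e-6)
  s2 <- translated_disk_series(12, dr = 0.6, dc = 0.8)
  d <- migration_direction(s2, 11, 5)
  expect_equal(unname(d), c(0.6, 0.8), tolerance = 0.05)
  s3 <- translated_disk_series(12, dr = 0, dc = 0)
  expect_error(migration_direction(s3, 6, 5), "direction undefined",
               class = "morphocell_undefined_direction")
})

test_that("normalization hits the 25-px equivalent-circle diameter in a 64x64 frame", {
  for (mask in list(disk_mask(100, 30), bar_mask(100, 60, 20),
                    ellipse_mask(2, 15, dim = 150))) {
    nm <- normalize_mask(mask, direction = c(1, 0))
    expect_equal(dim(nm), c(64L, 64L))
    deq <- 2 * sqrt(sum(nm) / pi)
    expect_equal(deq, 25, tolerance = 0.4 / 25)
    cen <- mask_centroid(nm)
    expect_lt(max(abs(cen - 31.5)), 0.75)
  }
})

test_that("normalization rotates the migration direction to point down the frame", {
  bar <- bar_mask(100, 60, 16)
  # moving down: already aligned, rotation 0
  nm_down <- normalize_mask(bar, direction = c(1, 0))
  expect_equal(abs(attr(nm_down, "rotation")), 0)
  idx <- which(nm_down, arr.ind = TRUE)
  expect_gt(diff(range(idx[, 1])), diff(range(idx[, 2])))  # long axis vertical
  # moving right: bar must be rotated 90 deg, long axis still vertical after
  nm_right <- normalize_mask(bar, direction = c(0, 1))
  idx2 <- which(nm_right, arr.ind = TRUE)
  expect_gt(diff(range(idx2[, 2])), diff(range(idx2[, 1])))
  # second-moment check: principal axis of the rotated bar is horizontal
  cc <- scale(idx2, scale = FALSE)
  ev <- eigen(crossprod(cc) / nrow(cc))$vectors[, 1]
  expect_gt(abs(ev[2]), abs(ev[1]))
})

test_that("normalization is idempotent and consistent under rotation", {
  m <- ellipse_mask(1.6, 25, dim = 120)
  n1 <- normalize_mask(m, c(1, 0))
  n2 <- normalize_mask(n1, c(1, 0))
  expect_lt(mean(xor(n1, n2)), 0.02 * mean(n1))
  # rotating mask and direction together leaves the result unchanged
  for (th in c(30, 60, 90) * pi / 180) {
    rot_mask <- morphocell:::affine_mask(m, angle = -th, scale = 1,
                                         out_dim = 160L)
    dir <- c(cos(th), sin(th))
    a <- normalize_mask(m, c(1, 0))
    b <- normalize_mask(rot_mask, dir)
    expect_lt(sum(xor(a, b)) / sum(a), 0.06)
  }
})

test_that("series normalization skips unresolvable frames and keeps the rest", {
  s <- translated_disk_series(12, dr = 1.2, dc = 0, r = 8)
  ns <- normalize_series(s, interval_frames = 5)
  expect_s3_class(ns$info, "tbl_df")
  expect_equal(nrow(ns$info), 12)
  expect_equal(sum(ns$info$kept), length(ns$masks))
  expect_true(all(!ns$info$kept[1:5]))
  areas <- vapply(ns$masks, sum, numeric(1))
  expect_true(all(abs(areas - pi * 12.5^2) / (pi * 12.5^2) < 0.015))
})

test_that("mask stacks round-trip through TIFF", {
  s <- translated_disk_series(4, r = 9)
  path <- tempfile(fileext = ".tif")
  write_mask_stack(s, path)
  back <- read_mask_stack(path, frame_interval = 5)
  expect_equal(length(back), 4L)
  expect_identical(back$masks[[2]], unname(s$masks[[2]]))
})
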