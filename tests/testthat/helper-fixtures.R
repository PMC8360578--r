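# programmatic fixtures shared across test files

disk_mask <- function(n = 64L, r = 12, cx = (n + 1) / 2, cy = cx) {
  g <- seq_len(n)
  sqrt(outer((g - cy)^2, (g - cx)^2, `+`)) <= r
}

bar_mask <- function(n = 64L, h = 30L, w = 10L) {
  m <- matrix(FALSE, n, n)
  r0 <- (n - h) %/% 2; c0 <- (n - w) %/% 2
  m[r0 + seq_len(h), c0 + seq_len(w)] <- TRUE
  m
}

# series of a disk translated by (dr, dc) px per frame
translated_disk_series <- function(n_frames = 12L, dr = 1, dc = 0, dim = 64L,
                                   r = 10, interval = 5) {
  masks <- lapply(seq_len(n_frames) - 1L, function(i) {
    disk_mask(dim, r, cx = dim / 2 - 6 + i * dc, cy = dim / 2 - 6 + i * dr)
  })
  mask_series(masks, frame_interval = interval)
}

# smooth anti-aliased disk field (phase-field-like) for sub-pixel contours
soft_disk <- function(n = 64L, r = 15, width = 2) {
  g <- seq_len(n)
  d <- sqrt(outer((g - (n + 1) / 2)^2, (g - (n + 1) / 2)^2, `+`))
  0.5 * (1 - tanh(3 * (d - r) / width))
}

# small fast simulation configuration (small cell, coarse box) for tests
# that exercise the full pipeline rather than the reference conditions
test_sim_config <- function(..., variant = "full") {
  kin <- utils::modifyList(list(W_tot = 29), list(...))
  cell_config(
    grid = grid_spec(64L, 64L, dx = 0.3),
    mech = mech_params(A0 = 28.3, a_W = 2.4),
    kinetics = do.call(kinetic_params, kin),
    variant = variant
  )
}

# one small trained classifier, shared across test files (trained once)
local_classifier_cache <- new.env(parent = emptyenv())

small_classifier <- function() {
  if (is.null(local_classifier_cache$fit)) {
    d <- geometry_proxy_classes(n_per_class = 40L, seed = 11L)
    local_classifier_cache$data <- d
    local_classifier_cache$fit <- train_shape_classifier(
      d, classifier_config(epochs = 5L, lr = 1e-3, batch_size = 32L,
                           seed = 11L))
  }
  local_classifier_cache$fit
}

small_classifier_data <- function() {
  invisible(small_classifier())
  local_classifier_cache$data
}
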