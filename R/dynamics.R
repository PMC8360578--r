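# -- boundary contours -------------------------------------------------------

#' Extract a closed sub-pixel boundary contour
#'
#' Traces the 0.5 level set of a phase field (or of a binary mask converted
#' to 0/1) with `grDevices::contourLines`, keeps the longest closed curve,
#' resamples it to `n_points` equal-arclength points, orients it
#' counter-clockwise (positive signed area in (x = col, y = row)
#' coordinates), and optionally low-pass filters the point series with a
#' truncated Fourier series to suppress pixelation of binary masks.
#'
#' @param x Logical mask or numeric field matrix.
#' @param n_points Number of resampled boundary points (>= 16).
#' @param pixel_size Length per pixel (defaults to 1, i.e. pixel units).
#' @param harmonics Number of Fourier harmonics kept when smoothing;
#'   `Inf` disables smoothing. Default keeps `min(24, n_points %/% 4)`.
#' @return An object of class `boundary_contour`: list with `x`, `y`
#'   (closed, first point not repeated), `n_points`, `perimeter`, `area`,
#'   `time` (NA unless set by callers).
#' @export
extract_contour <- function(x, n_points = 128L, pixel_size = 1,
                            harmonics = NULL) {
  stopifnot(n_points >= 16)
  z <- x
  storage.mode(z) <- "double"
  if (!any(z >= 0.5)) stop("empty input: no region above the 0.5 level")
  lab <- label_components(z >= 0.5)
  if (max(lab) > 1) stop("multi-component input: extract_contour needs a single region")
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (length(cl) == 0) stop("no contour found at the 0.5 level")
  lens <- vapply(cl, function(s) length(s$x), integer(1))
  s <- cl[[which.max(lens)]]
  closed <- abs(s$x[1] - s$x[length(s$x)]) < 1e-9 &&
    abs(s$y[1] - s$y[length(s$y)]) < 1e-9
  if (!closed) stop("open contour: region touches the frame edge")
  # s$x follows rows, s$y follows cols; work in (x = col, y = row)
  px <- s$y[-length(s$y)]
  py <- s$x[-length(s$x)]
  # counter-clockwise: positive signed area
  a2 <- sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)
  if (a2 < 0) { px <- rev(px); py <- rev(py); a2 <- -a2 }
  # equal-arclength resampling
  dx <- diff(c(px, px[1])); dy <- diff(c(py, py[1]))
  seg <- sqrt(dx^2 + dy^2)
  cum <- c(0, cumsum(seg))
  per <- cum[length(cum)]
  ss <- seq(0, per, length.out = n_points + 1L)[-(n_points + 1L)]
  rx <- stats::approx(cum, c(px, px[1]), xout = ss)$y
  ry <- stats::approx(cum, c(py, py[1]), xout = ss)$y
  if (is.null(harmonics)) harmonics <- min(16L, n_points %/% 8L)
  if (is.finite(harmonics) && harmonics < n_points %/% 2) {
    rx <- fourier_smooth(rx, harmonics)
    ry <- fourier_smooth(ry, harmonics)
    # smoothing perturbs point spacing; restore equal arclength so that
    # windowed curvature telescopes to one full turn
    dx <- diff(c(rx, rx[1])); dy <- diff(c(ry, ry[1]))
    cum2 <- c(0, cumsum(sqrt(dx^2 + dy^2)))
    ss2 <- seq(0, cum2[length(cum2)], length.out = n_points + 1L)
    ss2 <- ss2[-(n_points + 1L)]
    rx <- stats::approx(cum2, c(rx, rx[1]), xout = ss2)$y
    ry <- stats::approx(cum2, c(ry, ry[1]), xout = ss2)$y
  }
  dx <- diff(c(rx, rx[1])); dy <- diff(c(ry, ry[1]))
  structure(list(x = rx * pixel_size, y = ry * pixel_size,
                 n_points = n_points,
                 perimeter = sum(sqrt(dx^2 + dy^2)) * pixel_size,
                 area = abs(sum(rx * c(ry[-1], ry[1]) -
                                  c(rx[-1], rx[1]) * ry)) / 2 * pixel_size^2,
                 time = NA_real_),
            class = "boundary_contour")
}

fourier_smooth <- function(v, harmonics) {
  n <- length(v)
  f <- stats::fft(v)
  keep <- c(seq_len(harmonics + 1L), seq(n - harmonics + 1L, n))
  f[setdiff(seq_len(n), keep)] <- 0
  Re(stats::fft(f, inverse = TRUE)) / n
}

contour_perimeter <- function(ct) ct$perimeter

#' Signed curvature along a closed contour
#'
#' Curvature is the circular finite difference of the unwrapped tangent
#' angle divided by arclength, so that the turning-number identity
#' `sum(kappa * ds) = 2 pi` holds by construction for a counter-clockwise
#' simple contour.
#'
#' @param ct A `boundary_contour`.
#' @return Numeric vector of curvatures (1/length unit) at each point.
#' @export
contour_curvature <- function(ct, window = NULL) {
  x <- ct$x; y <- ct$y; n <- length(x)
  nx <- c(x[-1], x[1]); ny <- c(y[-1], y[1])
  dx <- nx - x; dy <- ny - y
  theta <- atan2(dy, dx)
  dth <- diff(c(theta, theta[1]))
  dth <- dth - 2 * pi * round(dth / (2 * pi))
  ds <- sqrt(dx^2 + dy^2)
  # unwrapped tangent angle and cumulative arclength, extended circularly
  thu <- cumsum(c(theta[1], dth[-n]))
  su <- cumsum(c(0, ds[-n]))
  if (is.null(window)) window <- max(1L, n %/% 32L)
  w <- window
  idx <- seq_len(n)
  up <- ((idx - 1 + w) %% n) + 1
  dn <- ((idx - 1 - w) %% n) + 1
  wrap_up <- (idx + w) > n
  wrap_dn <- (idx - w) < 1
  dtheta <- thu[up] + 2 * pi * wrap_up - (thu[dn] - 2 * pi * wrap_dn)
  dsarc <- su[up] + ct$perimeter * wrap_up - (su[dn] - ct$perimeter * wrap_dn)
  dtheta / dsarc
}

contour_normals <- function(ct) {
  x <- ct$x; y <- ct$y; n <- length(x)
  tx <- c(x[-1], x[1]) - c(x[n], x[-n])
  ty <- c(y[-1], y[1]) - c(y[n], y[-n])
  len <- sqrt(tx^2 + ty^2)
  cbind(ty / len, -tx / len)  # outward for CCW orientation
}

# cyclic offset registering contour q to contour p (same n); returns offset k
# minimizing sum |p_i - q_{i+k}|^2, via FFT cross-correlation
register_offset <- function(p, q) {
  n <- p$n_points
  # sum |p_i - q_{i+k}|^2 = const - 2 sum_i (p_i . q_{i+k})
  cross <- function(a, b) Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)),
                                        inverse = TRUE)) / length(a)
  corr <- cross(q$x, p$x) + cross(q$y, p$y)
  which.max(corr) - 1L
}

cyc_shift <- function(v, k) {
  n <- length(v)
  v[((seq_len(n) - 1L + k) %% n) + 1L]
}

# -- kymographs ---------------------------------------------------------------

contour_list_from_series <- function(series, n_points, harmonics = NULL) {
  px <- if (is.na(series$pixel_size)) 1 else series$pixel_size
  out <- vector("list", length(series$masks))
  kept <- logical(length(out))
  for (i in seq_along(out)) {
    ct <- try(extract_contour(series$masks[[i]], n_points, px, harmonics),
              silent = TRUE)
    if (!inherits(ct, "try-error")) {
      ct$time <- (i - 1) * series$frame_interval
      out[[i]] <- ct
      kept[i] <- TRUE
    }
  }
  if (sum(kept) < 2) stop("fewer than 2 frames yielded a contour")
  list(contours = out[kept], kept = which(kept))
}

new_kymograph <- function(values, what, contours, offsets, times, series) {
  structure(list(values = values, what = what, contours = contours,
                 offsets = offsets, times = times,
                 frame_interval = series$frame_interval,
                 n_points = nrow(values), label = series$label),
            class = "kymograph")
}

#' Boundary curvature kymograph
#'
#' Extracts contours for every frame, registers consecutive frames by the
#' cyclic-offset nearest-point rule (offset minimizing the summed squared
#' point displacement, accumulated so all columns share frame 1's boundary
#' parameterization) and reports signed curvature per boundary point and
#' frame. Frames whose contour extraction fails are dropped and logged.
#'
#' @param series A [mask_series()] (or a `cell_trajectory`, whose phase
#'   fields are binarized first).
#' @param n_points Boundary points per frame.
#' @param harmonics Contour smoothing (see [extract_contour()]).
#' @return An object of class `kymograph` with a `n_points x n_frames`
#'   `values` matrix (1/length units), the registered contours, offsets and
#'   frame times.
#' @export
curvature_kymograph <- function(series, n_points = 128L, harmonics = NULL) {
  if (inherits(series, "cell_trajectory")) series <- trajectory_masks(series)
  cl <- contour_list_from_series(series, n_points, harmonics)
  cts <- cl$contours
  nf <- length(cts)
  offsets <- integer(nf)
  for (i in 2:nf) {
    # the previous contour is already in frame-1 parameterization, so the
    # registered offset of the current contour is absolute
    offsets[i] <- register_offset(shift_contour(cts[[i - 1]], offsets[i - 1]),
                                  cts[[i]]) %% n_points
  }
  vals <- vapply(seq_len(nf), function(i) {
    cyc_shift(contour_curvature(cts[[i]]), offsets[i])
  }, numeric(n_points))
  new_kymograph(vals, "curvature", cts, offsets,
                vapply(cts, `[[`, numeric(1), "time"), series)
}

shift_contour <- function(ct, k) {
  ct$x <- cyc_shift(ct$x, k); ct$y <- cyc_shift(ct$y, k)
  ct
}

#' Protrusion-speed kymograph
#'
#' Signed normal displacement between consecutive registered contours
#' divided by the frame interval; positive values are outward motion.
#'
#' @inheritParams curvature_kymograph
#' @return A `kymograph` whose `values` are speeds (length unit / s); the
#'   first column (no preceding frame) repeats the second.
#' @export
protrusion_speed_kymograph <- function(series, n_points = 128L,
                                       harmonics = NULL) {
  if (inherits(series, "cell_trajectory")) series <- trajectory_masks(series)
  cl <- contour_list_from_series(series, n_points, harmonics)
  cts <- cl$contours
  nf <- length(cts)
  offsets <- integer(nf)
  vals <- matrix(NA_real_, n_points, nf)
  for (i in 2:nf) {
    prev <- shift_contour(cts[[i - 1]], offsets[i - 1])
    offsets[i] <- register_offset(prev, cts[[i]]) %% n_points
    cur <- shift_contour(cts[[i]], offsets[i])
    nrm <- contour_normals(prev)
    dt <- cts[[i]]$time - cts[[i - 1]]$time
    vals[, i] <- ((cur$x - prev$x) * nrm[, 1] + (cur$y - prev$y) * nrm[, 2]) / dt
  }
  vals[, 1] <- vals[, 2]
  new_kymograph(vals, "protrusion_speed", cts, offsets,
                vapply(cts, `[[`, numeric(1), "time"), series)
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %s: %d boundary points x %d frames (%.0f s)\n",
              x$what, nrow(x$values), ncol(x$values), max(x$times)))
  invisible(x)
}

#' @method tidy kymograph
#' @export
tidy.kymograph <- function(x, ...) {
  tibble::tibble(
    boundary = rep(seq_len(nrow(x$values)) / nrow(x$values), ncol(x$values)),
    time = rep(x$times, each = nrow(x$values)),
    value = as.vector(x$values))
}

# -- MSD / persistence --------------------------------------------------------

#' Mean-square displacement with ballistic/diffusive crossover
#'
#' Computes the time-averaged MSD of a centroid track over lags up to
#' `max_lag_frac` of the series, fits (i) a free-slope line to log(MSD) vs
#' log(lag) over the shortest `short_frac` of lags and the longest
#' `long_frac`, and (ii) the two fixed-slope reference lines (slope 2
#' ballistic, slope 1 diffusive) whose intersection defines the persistence
#' time `tau0`; `X0 = sqrt(MSD(tau0)) / cell_length` is the persistence
#' length in cell lengths. The fixed-slope fit windows are re-centered on
#' the current `tau0` estimate (short: lag <= tau0/2, long: lag >= 2 tau0)
#' for a few iterations, because windows tied to the maximum lag bias the
#' crossover when the track is much longer than the persistence time. If no
#' crossover lies within the observed lag range, `tau0` is reported as `NA`
#' ("unresolved") rather than an error.
#'
#' @param track A tibble/data.frame with columns `time`, `x`, `y` (or a
#'   `cell_trajectory`, whose centroid table is used), or a list of such
#'   tracks whose MSD curves are averaged before fitting.
#' @param cell_length Mean cell length used to normalize `X0`; default 1.
#' @param max_lag_frac Largest lag as a fraction of the series duration.
#' @param short_frac,long_frac Fractions of the lag range used for the
#'   initial short- and long-lag fits.
#' @param iterations Window re-centering iterations for the fixed-slope fit.
#' @return An object of class `msd_result`.
#' @export
msd_persistence <- function(track, cell_length = 1, max_lag_frac = 0.25,
                            short_frac = 0.2, long_frac = 0.5,
                            iterations = 3L) {
  if (inherits(track, "cell_trajectory")) track <- track$centroid
  tracks <- if (is.data.frame(track)) list(track) else track
  for (tr in tracks) {
    stopifnot(all(c("time", "x", "y") %in% names(tr)))
    if (nrow(tr) < 50) stop("track too short: need >= 50 frames")
  }
  n <- min(vapply(tracks, nrow, integer(1)))
  dt <- stats::median(diff(tracks[[1]]$time))
  max_lag <- max(2L, floor((n - 1) * max_lag_frac))
  lags <- seq_len(max_lag)
  one_msd <- function(tr) {
    m <- nrow(tr)
    x <- tr$x; y <- tr$y
    vapply(lags, function(k) {
      mean((x[(1 + k):m] - x[1:(m - k)])^2 + (y[(1 + k):m] - y[1:(m - k)])^2)
    }, numeric(1))
  }
  msd <- Reduce(`+`, lapply(tracks, one_msd)) / length(tracks)
  tau <- lags * dt
  ok <- msd > 0
  lt <- log(tau[ok]); lm_ <- log(msd[ok])

  fit_free <- function(sel) {
    if (sum(sel) < 3) return(c(NA_real_, NA_real_))
    stats::coef(stats::lm(lm_[sel] ~ lt[sel]))[c(2, 1)]
  }
  short_sel <- lt <= log(tau[ok][1]) + short_frac * diff(range(lt))
  long_sel <- lt >= log(tau[ok][1]) + long_frac * diff(range(lt))
  # guarantee enough points for a fit on short series
  short_sel <- short_sel | seq_along(lt) <= 3
  long_sel <- long_sel | seq_along(lt) > length(lt) - 3
  slope_short <- fit_free(short_sel)[[1]]
  slope_long <- fit_free(long_sel)[[1]]

  # fixed-slope two-line construction
  b2 <- mean(lm_[short_sel] - 2 * lt[short_sel])  # ballistic intercept
  b1 <- mean(lm_[long_sel] - 1 * lt[long_sel])    # diffusive intercept
  tau0 <- exp(b1 - b2)
  for (it in seq_len(iterations)) {
    s2 <- tau[ok] <= tau0 / 2
    s1 <- tau[ok] >= 2 * tau0
    if (sum(s2) < 2 || sum(s1) < 2) break
    b2 <- mean(lm_[s2] - 2 * lt[s2])
    b1 <- mean(lm_[s1] - 1 * lt[s1])
    tau0 <- exp(b1 - b2)
  }
  # a crossover is only reported when the long-lag regime is genuinely
  # sub-ballistic (a straight track has slope 2 throughout: no crossover)
  resolved <- is.finite(tau0) && tau0 >= tau[1] && tau0 <= max(tau) &&
    is.finite(slope_long) && slope_long < 1.5
  X0 <- if (resolved) sqrt(exp(b2 + 2 * log(tau0))) / cell_length else NA_real_
  structure(list(
    lags = tau, msd = msd,
    tau0 = if (resolved) tau0 else NA_real_,
    X0 = X0,
    slope_short = slope_short, slope_long = slope_long,
    ballistic_intercept = b2, diffusive_intercept = b1,
    cell_length = cell_length, resolved = resolved),
    class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf(
    "<msd_result> %d lags; short-lag slope %.2f; tau0 = %s s; X0 = %s\n",
    length(x$lags), x$slope_short,
    if (x$resolved) sprintf("%.1f", x$tau0) else "unresolved",
    if (x$resolved) sprintf("%.2f cell lengths", x$X0) else "-"))
  invisible(x)
}

#' @method tidy msd_result
#' @export
tidy.msd_result <- function(x, ...) {
  tibble::tibble(lag = x$lags, msd = x$msd)
}

#' @method glance msd_result
#' @export
glance.msd_result <- function(x, ...) {
  tibble::tibble(tau0 = x$tau0, X0 = x$X0, slope_short = x$slope_short,
                 slope_long = x$slope_long, resolved = x$resolved)
}

#' Synthetic run-and-tumble track
#'
#' Constant-speed motion whose direction is fully randomized at Poisson
#' tumble events. The `tau0` parameter is the persistence time defined as
#' the lag where the analytic MSD asymptotes cross: with tumble rate
#' `lambda`, the velocity autocorrelation is `exp(-lambda t)` and
#' `MSD(t) = 2 v^2 (t/lambda - (1 - exp(-lambda t))/lambda^2)`, whose
#' ballistic and diffusive asymptotes intersect at `t = 2/lambda`; the
#' sampler therefore uses `lambda = 2/tau0`.
#'
#' @param duration Track duration (s).
#' @param dt Sampling interval (s).
#' @param speed Speed (length/s).
#' @param tau0 Persistence time (s), the MSD crossover lag.
#' @param seed Integer seed.
#' @return A tibble with `time`, `x`, `y`.
#' @export
run_and_tumble_track <- function(duration, dt, speed, tau0, seed = 1L) {
  set.seed(seed)
  n <- floor(duration / dt)
  lambda <- 2 / tau0
  tumble <- stats::runif(n) < (1 - exp(-lambda * dt))
  ang <- stats::runif(n, 0, 2 * pi)
  theta <- numeric(n)
  theta[1] <- ang[1]
  for (i in 2:n) theta[i] <- if (tumble[i]) ang[i] else theta[i - 1]
  tibble::tibble(time = (0:n) * dt,
                 x = c(0, cumsum(speed * dt * cos(theta))),
                 y = c(0, cumsum(speed * dt * sin(theta))))
}

#' Mean cell length along the instantaneous motion direction
#'
#' Time-average of the mask extent along the unit vector of centroid motion
#' at each frame (frames with sub-threshold displacement are skipped).
#'
#' @param series A [mask_series()] (or `cell_trajectory`).
#' @param interval_frames Displacement lookback for the motion vector.
#' @return Scalar length (pixel units times `pixel_size` when set).
#' @export
mean_cell_length <- function(series, interval_frames = 5L) {
  if (inherits(series, "cell_trajectory")) series <- trajectory_masks(series)
  px <- if (is.na(series$pixel_size)) 1 else series$pixel_size
  n <- length(series$masks)
  vals <- c()
  for (i in seq((interval_frames + 1), n)) {
    dir <- tryCatch(migration_direction(series, i, interval_frames),
                    error = function(e) NULL)
    if (is.null(dir)) next
    idx <- which(series$masks[[i]], arr.ind = TRUE)
    proj <- idx[, 1] * dir[[1]] + idx[, 2] * dir[[2]]
    vals <- c(vals, (max(proj) - min(proj) + 1) * px)
  }
  if (!length(vals)) stop("no frame had a resolvable motion direction")
  mean(vals)
}

# -- pseudopod events ---------------------------------------------------------

# label connected regions of a logical (boundary x time) matrix, with the
# boundary dimension cyclic: label via EBImage then merge across the seam
label_cyclic <- function(act) {
  lab <- label_components(act)
  n <- nrow(act)
  for (j in seq_len(ncol(act))) {
    a <- lab[1, j]; b <- lab[n, j]
    if (a > 0 && b > 0 && a != b) lab[lab == b] <- a
  }
  lab
}

#' Detect pseudopod events on a protrusion-speed kymograph
#'
#' Automated stand-in for by-eye scoring. Protrusive regions are connected
#' components (cyclic in the boundary coordinate) of the kymograph above a
#' speed threshold that persist at least `min_duration` frames and span at
#' least `min_width_frac` of the boundary. An event is `de_novo` when its
#' onset boundary interval (dilated by `dilate` points) does not overlap any
#' protrusive activity within the preceding `lookback` frames; otherwise it
#' is a split: `y_split` if the parent region is still active outside the
#' new region `min_duration` frames after onset, `one_way_split` if the
#' parent has drifted into the new region.
#'
#' @param kymo A protrusion-speed `kymograph`.
#' @param speed_quantile Threshold quantile of positive speeds (default 0.8).
#' @param speed_threshold Absolute threshold; overrides the quantile.
#' @param min_duration Minimum duration (frames).
#' @param min_width_frac Minimum boundary width (fraction of perimeter).
#' @param lookback Preceding window (frames) used for the de novo test.
#' @param dilate Boundary dilation (points) when testing overlap.
#' @return A tibble: `event`, `onset_time`, `onset_frame`, `boundary_index`,
#'   `boundary_frac`, `type`, `duration`, `width_frac`.
#' @export
detect_pseudopod_events <- function(kymo, speed_quantile = 0.8,
                                    speed_threshold = NULL,
                                    min_duration = 3L, min_width_frac = 0.05,
                                    lookback = 3L, dilate = 3L) {
  stopifnot(inherits(kymo, "kymograph"))
  v <- kymo$values
  if (is.null(speed_threshold)) {
    pos <- v[v > 0 & is.finite(v)]
    if (!length(pos)) return(empty_event_table())
    speed_threshold <- stats::quantile(pos, speed_quantile, names = FALSE)
  }
  act <- is.finite(v) & (v > speed_threshold)
  if (!any(act)) return(empty_event_table())
  lab <- label_cyclic(act)
  n <- nrow(v)
  ids <- sort(unique(lab[lab > 0]))
  rows <- list()
  dil <- function(idx) unique(((rep(idx, each = 2 * dilate + 1) +
                                  (-dilate):dilate) - 1) %% n + 1)
  for (id in ids) {
    cells <- which(lab == id, arr.ind = TRUE)
    cols <- sort(unique(cells[, 2]))
    widths <- tabulate(cells[, 2], ncol(v))
    if (length(cols) < min_duration) next
    if (max(widths) < min_width_frac * n) next
    t0 <- cols[1]
    onset_rows <- cells[cells[, 2] == t0, 1]
    onset_dil <- dil(onset_rows)
    pre_cols <- seq(max(1, t0 - lookback), t0 - 1)
    type <- "de_novo"
    if (length(pre_cols) > 0) {
      pre <- lab[, pre_cols, drop = FALSE]
      parent_ids <- setdiff(unique(pre[onset_dil, , drop = FALSE]), c(0, id))
      if (length(parent_ids) > 0) {
        t1 <- min(t0 + min_duration, ncol(v))
        parent_alive <- FALSE
        for (pid in parent_ids) {
          pc <- which(lab == pid, arr.ind = TRUE)
          later <- pc[pc[, 2] >= t1, 1]
          if (length(setdiff(later, dil(onset_rows)))) parent_alive <- TRUE
        }
        type <- if (parent_alive) "y_split" else "one_way_split"
      }
    }
    bi <- round(circ_mean_index(onset_rows, n))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      onset_time = kymo$times[t0], onset_frame = t0,
      boundary_index = bi, boundary_frac = bi / n, type = type,
      duration = length(cols), width_frac = max(widths) / n)
  }
  if (!length(rows)) return(empty_event_table())
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$onset_time)
  dplyr::mutate(out, event = dplyr::row_number(), .before = 1)
}

empty_event_table <- function() {
  tibble::tibble(event = integer(), onset_time = double(),
                 onset_frame = integer(), boundary_index = integer(),
                 boundary_frac = double(), type = character(),
                 duration = integer(), width_frac = double())
}

circ_mean_index <- function(idx, n) {
  th <- 2 * pi * (idx - 0.5) / n
  ((atan2(mean(sin(th)), mean(cos(th))) / (2 * pi)) %% 1) * n + 0.5
}

#' Pseudopod fractions and extension-angle histogram
#'
#' Computes the de novo fraction of all events and, for events with a
#' resolvable window, the unsigned angle between the pseudopod extension
#' vector (displacement of the registered onset boundary point over
#' `extension_window` seconds after onset) and the centroid velocity over
#' the same window. Events too close to the end of the series are dropped
#' and counted in `n_dropped`.
#'
#' @param events Event table from [detect_pseudopod_events()].
#' @param kymo The `kymograph` the events came from.
#' @param centroid Tibble with `time`, `x`, `y` (e.g. a trajectory's
#'   centroid table); coordinates in the same length unit as the contours.
#' @param extension_window Seconds after onset used for the extension vector.
#' @return A list: `fractions` (tibble type/n/fraction), `angles` (tibble
#'   event/type/angle in degrees), `n_dropped`.
#' @export
pseudopod_statistics <- function(events, kymo, centroid,
                                 extension_window = 10) {
  frac <- events |>
    dplyr::count(.data$type) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  nframes <- length(kymo$times)
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(events))) {
    f0 <- events$onset_frame[i]
    t_target <- kymo$times[f0] + extension_window
    f1 <- which(kymo$times >= t_target)[1]
    if (is.na(f1) || f1 > nframes) { dropped <- dropped + 1L; next }
    bi <- events$boundary_index[i]
    c0 <- shift_contour(kymo$contours[[f0]], kymo$offsets[f0])
    c1 <- shift_contour(kymo$contours[[f1]], kymo$offsets[f1])
    ext <- c(c1$x[bi] - c0$x[bi], c1$y[bi] - c0$y[bi])
    ci0 <- which.min(abs(centroid$time - kymo$times[f0]))
    ci1 <- which.min(abs(centroid$time - kymo$times[f1]))
    vel <- c(centroid$x[ci1] - centroid$x[ci0],
             centroid$y[ci1] - centroid$y[ci0])
    if (sum(ext^2) == 0 || sum(vel^2) == 0) { dropped <- dropped + 1L; next }
    ang <- acos(pmin(1, pmax(-1, sum(ext * vel) /
                               sqrt(sum(ext^2) * sum(vel^2))))) * 180 / pi
    rows[[length(rows) + 1L]] <- tibble::tibble(
      event = events$event[i], type = events$type[i], angle = ang)
  }
  list(fractions = frac,
       angles = if (length(rows)) dplyr::bind_rows(rows) else
         tibble::tibble(event = integer(), type = character(),
                        angle = double()),
       n_dropped = dropped)
}
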