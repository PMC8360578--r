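#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# connected-component labeling of a logical matrix (4-connectivity)
label_components <- function(mask) {
  storage.mode(mask) <- "double"
  # EBImage images are column-major x,y; a plain matrix works transparently
  EBImage::bwlabel(mask)
}

#' Binarize a phase field into a single-component mask
#'
#' Thresholds the field at the 0.5 level set, keeps the largest connected
#' component and reports any discarded fragment areas (in pixels) as an
#' attribute `fragments`.
#'
#' @param phi Numeric matrix (finite).
#' @param threshold Level-set threshold, default 0.5.
#' @return Logical matrix of class `mask_frame`.
#' @export
binarize_phase <- function(phi, threshold = 0.5) {
  if (!all(is.finite(phi))) stop("phase field contains non-finite values")
  m <- phi >= threshold
  if (!any(m)) stop("degenerate input: empty mask after thresholding")
  lab <- label_components(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  out <- lab == keep
  frag <- sizes[-keep]
  structure(out, class = c("mask_frame", class(out)),
            fragments = if (length(frag)) frag else numeric(0))
}

#' Centroid of a binary mask
#'
#' Arithmetic mean of the foreground pixel coordinates, in 0-based pixel
#' centers `(row, col)`.
#'
#' @param mask Logical matrix.
#' @return Numeric `c(row, col)`.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no centroid")
  c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1)
}

#' Ordered series of binary masks
#'
#' @param masks List of logical matrices (identical dimensions) or a 3D
#'   logical array with frames along the third dimension.
#' @param frame_interval Time between frames (s).
#' @param pixel_size Pixel size (um/px), optional.
#' @param label Source label.
#' @return An object of class `mask_series`.
#' @export
mask_series <- function(masks, frame_interval, pixel_size = NA_real_,
                        label = "series") {
  if (is.array(masks) && length(dim(masks)) == 3) {
    masks <- lapply(seq_len(dim(masks)[3]), function(i) masks[, , i])
  }
  stopifnot(is.list(masks), length(masks) >= 1, frame_interval > 0)
  d <- dim(masks[[1]])
  ok <- vapply(masks, function(m) is.matrix(m) && all(dim(m) == d), logical(1))
  if (!all(ok)) stop("all masks must be matrices of identical dimensions")
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "logical"
    m
  })
  structure(list(masks = masks, frame_interval = frame_interval,
                 pixel_size = pixel_size, label = label),
            class = "mask_series")
}

#' @export
print.mask_series <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("<mask_series> '%s': %d frames of %d x %d @ %g s\n",
              x$label, length(x$masks), d[1], d[2], x$frame_interval))
  invisible(x)
}

#' @export
length.mask_series <- function(x) length(x$masks)

#' Extract the binarized mask series of a simulated trajectory
#'
#' @param trajectory A `cell_trajectory`.
#' @param threshold Level-set threshold for the phase field.
#' @return A [mask_series()] with the grid spacing as pixel size.
#' @export
trajectory_masks <- function(trajectory, threshold = 0.5) {
  masks <- lapply(trajectory$frames, function(fr) {
    unclass(binarize_phase(fr$phi, threshold))
  })
  mask_series(masks, frame_interval = trajectory$sample_interval,
              pixel_size = trajectory$config$grid$dx,
              label = paste0("sim-seed", trajectory$seed))
}

#' Migration direction at a frame
#'
#' Unit vector (drow, dcol) of the centroid displacement between frame
#' `index` and frame `index - interval_frames` (1-based frame indices).
#' Displacements below `min_displacement` pixels are reported as an error of
#' class `morphocell_undefined_direction` so that callers can skip the
#' frame.
#'
#' @param series A [mask_series()].
#' @param index Frame index (1-based).
#' @param interval_frames Lookback interval in frames (default 5).
#' @param min_displacement Minimum displacement magnitude (px).
#' @return Unit vector `c(drow, dcol)`.
#' @export
migration_direction <- function(series, index, interval_frames = 5L,
                                min_displacement = 0.25) {
  stopifnot(index - interval_frames >= 1)
  d <- mask_centroid(series$masks[[index]]) -
    mask_centroid(series$masks[[index - interval_frames]])
  n <- sqrt(sum(d^2))
  if (n < min_displacement) {
    stop(structure(class = c("morphocell_undefined_direction", "error",
                             "condition"),
                   list(message = sprintf(
                     "displacement %.3g px below %.3g px: direction undefined",
                     n, min_displacement), call = sys.call(-1))))
  }
  c(drow = d[[1]] / n, dcol = d[[2]] / n)
}

# inverse-mapped affine resampling of a mask with bilinear interpolation.
# The output pixel grid is rotated by `angle` (radians, counter-clockwise in
# row/col space) and scaled by `scale` about the mask centroid, which is
# mapped to the center of the out_dim frame.
affine_mask <- function(mask, angle = 0, scale = 1, out_dim = 64L,
                        center = NULL, rebinarize = TRUE, supersample = 2L) {
  m <- mask
  storage.mode(m) <- "double"
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(center)) center <- mask_centroid(mask)
  oc <- (out_dim - 1) / 2
  ca <- cos(angle); sa <- sin(angle)
  pick <- function(ri, ci) {
    ok <- ri >= 0 & ri <= nr - 1 & ci >= 0 & ci <= nc - 1
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok] + 1, ci[ok] + 1)]
    v
  }
  base <- seq_len(out_dim) - 1 - oc
  sample_at <- function(dr, dc) {
    rr <- matrix(rep(base + dr, out_dim), out_dim, out_dim)
    cc <- t(matrix(rep(base + dc, out_dim), out_dim, out_dim))
    # inverse map: rotate by -angle, scale by 1/scale, shift to centroid
    sr <- (ca * rr + sa * cc) / scale + center[[1]]
    sc <- (-sa * rr + ca * cc) / scale + center[[2]]
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    (1 - fr) * (1 - fc) * pick(r0, c0) +
      (1 - fr) * fc * pick(r0, c0 + 1) +
      fr * (1 - fc) * pick(r0 + 1, c0) +
      fr * fc * pick(r0 + 1, c0 + 1)
  }
  # average the interpolant over a sub-pixel grid so the foreground area
  # responds smoothly to small changes in scale and angle
  offs <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  v <- 0
  for (dr in offs) for (dc in offs) v <- v + sample_at(dr, dc)
  out <- matrix(v / supersample^2, out_dim, out_dim)
  if (rebinarize) out >= 0.5 else out
}

#' Normalize a mask to the standard frame
#'
#' Implements the preprocessing used before feature extraction: the mask is
#' rescaled so its area equals that of a circle of 25 px diameter
#' (`pi * 12.5^2` px^2), rotated so the migration direction points down the
#' image (increasing row index), and embedded centered in a 64 x 64 frame.
#' Scaling is applied before rotation in a single continuous-space bilinear
#' resampling of the binary mask followed by re-thresholding at 0.5.
#'
#' @param mask Logical matrix (single foreground component).
#' @param direction Unit vector `c(drow, dcol)` of migration.
#' @param out_dim Output frame size (px), default 64.
#' @param target_diameter Equivalent-circle diameter (px), default 25.
#' @return Logical `out_dim x out_dim` matrix of class `normalized_mask`
#'   with attributes `rotation` (deg) and `scale`.
#' @export
normalize_mask <- function(mask, direction = c(1, 0), out_dim = 64L,
                           target_diameter = 25) {
  a <- sum(mask)
  if (a == 0) stop("empty mask cannot be normalized")
  target_area <- pi * (target_diameter / 2)^2
  scale <- sqrt(target_area / a)
  # rotation taking `direction` to (1, 0) (down the image) in row/col space:
  # direction angle relative to +row axis
  ang <- atan2(direction[[2]], direction[[1]])
  v <- affine_mask(mask, angle = ang, scale = scale, out_dim = out_dim,
                   rebinarize = FALSE)
  # binarize by occupancy rank rather than a fixed 0.5 cut: a fixed cut
  # quantizes the area of axis-aligned shapes in large coherent jumps,
  # while taking the k most-occupied pixels pins the area to the target
  k <- round(target_area)
  pos <- which(v > 0.05)
  k <- min(k, length(pos))
  out <- matrix(FALSE, out_dim, out_dim)
  out[pos[order(v[pos], decreasing = TRUE)[seq_len(k)]]] <- TRUE
  if (!any(out)) stop("normalization produced an empty mask")
  # clipping check: foreground touching the frame border means the scaled
  # bounding box exceeded the frame
  idx <- which(out, arr.ind = TRUE)
  if (min(idx) == 1 || max(idx[, 1]) == out_dim || max(idx[, 2]) == out_dim) {
    stop("normalized mask clipped by the ", out_dim, " px frame")
  }
  structure(out, class = c("normalized_mask", class(out)),
            rotation = -ang * 180 / pi, scale = scale)
}

#' Normalize a whole mask series
#'
#' Applies [migration_direction()] and [normalize_mask()] to every frame
#' with a resolvable direction. Frames whose centroid displacement is below
#' the threshold (or whose normalized mask would clip) are skipped and
#' reported in the returned table.
#'
#' @param series A [mask_series()].
#' @param interval_frames Direction lookback (frames), default 5.
#' @param out_dim,target_diameter Passed to [normalize_mask()].
#' @param min_displacement Passed to [migration_direction()].
#' @return A list of class `normalized_series`: `masks` (list of
#'   `normalized_mask`), `info` (tibble: frame, time, centroid, direction,
#'   rotation, scale, kept flag and skip reason), `frame_interval`, `label`.
#' @export
normalize_series <- function(series, interval_frames = 5L, out_dim = 64L,
                             target_diameter = 25, min_displacement = 0.25) {
  n <- length(series$masks)
  if (n < interval_frames + 1) {
    stop("series too short for a ", interval_frames, "-frame direction interval")
  }
  masks <- list()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t_i <- (i - 1) * series$frame_interval
    if (i <= interval_frames) {
      rows[[i]] <- tibble::tibble(frame = i, time = t_i, kept = FALSE,
                                  reason = "before first direction interval",
                                  drow = NA_real_, dcol = NA_real_,
                                  rotation = NA_real_, scale = NA_real_)
      next
    }
    res <- tryCatch({
      dir <- migration_direction(series, i, interval_frames, min_displacement)
      nm <- normalize_mask(series$masks[[i]], dir, out_dim, target_diameter)
      list(dir = dir, nm = nm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- tibble::tibble(frame = i, time = t_i, kept = FALSE,
                                  reason = conditionMessage(res),
                                  drow = NA_real_, dcol = NA_real_,
                                  rotation = NA_real_, scale = NA_real_)
    } else {
      masks[[length(masks) + 1L]] <- res$nm
      rows[[i]] <- tibble::tibble(frame = i, time = t_i, kept = TRUE,
                                  reason = NA_character_,
                                  drow = res$dir[[1]], dcol = res$dir[[2]],
                                  rotation = attr(res$nm, "rotation"),
                                  scale = attr(res$nm, "scale"))
    }
  }
  structure(list(masks = masks, info = dplyr::bind_rows(rows),
                 frame_interval = series$frame_interval, label = series$label),
            class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  cat(sprintf("<normalized_series> '%s': %d/%d frames normalized\n",
              x$label, length(x$masks), nrow(x$info)))
  invisible(x)
}

#' Read and write mask stacks
#'
#' `read_mask_stack()` reads a multi-page TIFF or a set of PNG files into a
#' [mask_series()] (nonzero pixels are foreground). `write_mask_stack()`
#' writes a list of masks (or a `normalized_series`) as a multi-page TIFF.
#'
#' @param path File path (TIFF) or character vector of PNG paths.
#' @param frame_interval,pixel_size,label Passed to [mask_series()].
#' @return A [mask_series()] for the reader; the path, invisibly, for the
#'   writer.
#' @export
read_mask_stack <- function(path, frame_interval = 1, pixel_size = NA_real_,
                            label = "stack") {
  as_mask <- function(img) {
    if (length(dim(img)) == 3) img <- img[, , 1]
    img > 0
  }
  if (length(path) == 1 && grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    masks <- lapply(pages, as_mask)
  } else {
    masks <- lapply(path, function(p) as_mask(png::readPNG(p)))
  }
  mask_series(masks, frame_interval, pixel_size, label)
}

#' @rdname read_mask_stack
#' @param masks A list of logical matrices, a [mask_series()] or a
#'   `normalized_series`.
#' @export
write_mask_stack <- function(masks, path) {
  if (inherits(masks, c("mask_series", "normalized_series"))) masks <- masks$masks
  imgs <- lapply(masks, function(m) {
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(imgs, path)
  invisible(path)
}
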