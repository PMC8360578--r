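#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_path geom_abline scale_fill_gradient2 scale_fill_viridis_c labs
#'   theme_minimal coord_equal scale_x_log10 scale_y_log10
#' @export
ggplot2::autoplot

#' Plot a kymograph
#'
#' Boundary coordinate (fraction of perimeter) against time, colored by
#' curvature or protrusion speed with a diverging palette centered at zero.
#'
#' @param object A `kymograph`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kymograph
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$time, y = .data$boundary, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(name = object$what) +
    labs(x = "time (s)", y = "boundary position (fraction of perimeter)",
         title = paste0(object$label, ": ", object$what)) +
    theme_minimal()
}

#' Plot an MSD curve with its fitted regimes
#'
#' Log-log MSD against lag with the ballistic (slope-2) and diffusive
#' (slope-1) reference lines and the crossover `tau0` when resolved.
#'
#' @param object An `msd_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot msd_result
#' @export
autoplot.msd_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$lag, y = .data$msd)) +
    geom_point(size = 0.8) +
    scale_x_log10() + scale_y_log10() +
    geom_abline(slope = 2, intercept = object$ballistic_intercept / log(10),
                color = "magenta") +
    geom_abline(slope = 1, intercept = object$diffusive_intercept / log(10),
                color = "red") +
    labs(x = "lag (s)", y = "MSD", title = "centroid mean-square displacement") +
    theme_minimal()
  if (isTRUE(object$resolved)) {
    p <- p + geom_point(data = data.frame(
      lag = object$tau0,
      msd = exp(object$ballistic_intercept + 2 * log(object$tau0))),
      color = "blue", size = 3, shape = 4)
  }
  p
}

#' Plot a trajectory's centroid track
#'
#' @param object A `cell_trajectory`.
#' @param ... Unused.
#' @return A ggplot of the unwrapped centroid path in um, colored by time.
#' @method autoplot cell_trajectory
#' @export
autoplot.cell_trajectory <- function(object, ...) {
  ggplot(object$centroid, aes(x = .data$x, y = .data$y,
                              color = .data$time)) +
    geom_path() +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)", color = "time (s)",
         title = "centroid trajectory") +
    theme_minimal()
}

#' Plot feature vectors in the PCA shape space
#'
#' @param features A tibble with `PC1`, `PC2` columns (see
#'   [project_features()]) and optionally a `class`/`predicted` column used
#'   for color.
#' @param color Column name used for point color (default auto-detected).
#' @return A ggplot.
#' @export
plot_shape_space <- function(features, color = NULL) {
  stopifnot(all(c("PC1", "PC2") %in% names(features)))
  if (is.null(color)) {
    color <- intersect(c("class", "predicted", "series"), names(features))[1]
  }
  p <- ggplot(features, aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.na(color) && !is.null(color)) {
    p + geom_point(aes(color = .data[[color]]))
  } else {
    p + geom_point()
  }
  p + labs(title = "shape space") + theme_minimal()
}

#' Plot a mask or field matrix
#'
#' Small convenience for visual inspection of masks, phase fields and
#' normalized frames.
#'
#' @param m Logical or numeric matrix.
#' @return A ggplot raster.
#' @export
plot_mask <- function(m) {
  storage.mode(m) <- "double"
  df <- data.frame(row = as.vector(row(m)), col = as.vector(col(m)),
                   value = as.vector(m))
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    theme_minimal() +
    labs(x = NULL, y = NULL)
}
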