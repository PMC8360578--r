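# rasterize a polygon (vertices in unit-ish coordinates, (x, y) with y up)
# onto a dim x dim mask. Vertices are centered and scaled to fill `fill` of
# the frame. Row index increases downward, so y is flipped.
rasterize_polygon <- function(xy, dim = 200L, fill = 0.8) {
  xy <- sweep(xy, 2, colMeans(xy))
  span <- max(abs(xy))
  xy <- xy / span * (fill * dim / 2)
  cx <- (dim + 1) / 2
  px <- xy[, 1] + cx
  py <- cx - xy[, 2]  # flip y -> row
  gr <- seq_len(dim)
  inside <- matrix(FALSE, dim, dim)
  # even-odd rule, vectorized over grid columns per edge pair
  n <- nrow(xy)
  xs <- px; ys <- py
  j <- c(n, seq_len(n - 1))
  rowc <- matrix(rep(gr, dim), dim, dim)          # row coordinate (y)
  colc <- t(rowc)                                  # col coordinate (x)
  for (e in seq_len(n)) {
    y1 <- ys[e]; y2 <- ys[j[e]]; x1 <- xs[e]; x2 <- xs[j[e]]
    crosses <- ((y1 > rowc) != (y2 > rowc))
    xint <- x1 + (rowc - y1) / (y2 - y1) * (x2 - x1)
    inside <- xor(inside, crosses & (colc < xint))
  }
  # scanline ties at vertices can leave single-pixel specks
  lab <- label_components(inside)
  if (max(lab) > 1) {
    keep <- which.max(tabulate(lab[lab > 0]))
    inside <- lab == keep
  }
  inside
}

raster_ellipse <- function(a, b, rotation = 0, dim = 200L, fill = 0.8) {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  xy <- cbind(a * cos(th), b * sin(th))
  rot <- rotation * pi / 180
  xy <- xy %*% rbind(c(cos(rot), sin(rot)), c(-sin(rot), cos(rot)))
  rasterize_polygon(xy, dim, fill)
}

# canonical vertex sets (x right, y up; "up" orientation as drawn)
shape_vertices <- function(category) {
  switch(category,
    circle = {
      th <- seq(0, 2 * pi, length.out = 181)[-181]
      cbind(cos(th), sin(th))
    },
    isosceles_triangle = cbind(c(0, -0.7, 0.7), c(1, -0.8, -0.8)),
    right_triangle = cbind(c(-0.8, -0.8, 0.9), c(1, -0.9, -0.9)),
    rectangle = cbind(c(-0.65, 0.65, 0.65, -0.65), c(1, 1, -1, -1)),
    rhombus = cbind(c(0, 0.7, 0, -0.7), c(1, 0, -1, 0)),
    pentagon = {
      th <- pi / 2 + 2 * pi * (0:4) / 5
      cbind(cos(th), sin(th))
    },
    star = {
      th <- pi / 2 + pi * (0:9) / 5
      r <- rep(c(1, 0.5), 5)
      cbind(r * cos(th), r * sin(th))
    },
    stop("unknown shape category: ", category)
  )
}

geometry_row <- function(name, category, flip, aspect, mask) {
  tibble::tibble(name = name, category = category, flip = flip,
                 aspect = aspect, mask = list(mask))
}

make_shape_mask <- function(category, flip = FALSE, aspect = "1:1",
                            dim = 200L) {
  xy <- shape_vertices(category)
  if (flip) xy[, 2] <- -xy[, 2]
  sc <- switch(aspect, "1:1" = c(1, 1), "1:2" = c(2, 1), "2:1" = c(1, 2),
               stop("aspect must be one of 1:1, 1:2, 2:1"))
  xy <- sweep(xy, 2, sc, `*`)
  rasterize_polygon(xy, dim)
}

#' The 11 basic probe shapes
#'
#' Seven well-defined objects (circle, isosceles triangle, right triangle,
#' rectangle, rhombus, pentagon, star) plus vertical flips of the isosceles
#' triangle, right triangle, pentagon and star: 11 entries in a fixed,
#' deterministic order. Vertex proportions are frozen canonical choices
#' (e.g. a 5-point star with inner/outer radius ratio 0.5); only the
#' relative placement of shapes in feature space matters downstream.
#'
#' @param dim Raster size of the generated masks (px).
#' @return A tibble with columns `name`, `category`, `flip`, `aspect` and a
#'   list-column `mask` of logical matrices.
#' @export
basic_shapes <- function(dim = 200L) {
  cats <- c("circle", "isosceles_triangle", "right_triangle", "rectangle",
            "rhombus", "pentagon", "star")
  flipped <- c("isosceles_triangle", "right_triangle", "pentagon", "star")
  base <- purrr::map_dfr(cats, function(ca) {
    geometry_row(ca, ca, FALSE, "1:1", make_shape_mask(ca, dim = dim))
  })
  flips <- purrr::map_dfr(flipped, function(ca) {
    geometry_row(paste0(ca, "_flipped"), ca, TRUE, "1:1",
                 make_shape_mask(ca, flip = TRUE, dim = dim))
  })
  dplyr::bind_rows(base, flips)
}

#' The 33-shape expanded library
#'
#' Each of the 11 basic objects at aspect variants 1:1, 1:2 (laterally
#' elongated, i.e. stretched along the horizontal axis) and 2:1 (vertically
#' elongated along the notional moving direction).
#'
#' @inheritParams basic_shapes
#' @return A tibble of 33 rows with the same columns as [basic_shapes()].
#' @export
expanded_library <- function(dim = 200L) {
  b <- basic_shapes(dim)
  purrr::map_dfr(c("1:1", "1:2", "2:1"), function(asp) {
    purrr::map_dfr(seq_len(nrow(b)), function(i) {
      geometry_row(
        name = if (asp == "1:1") b$name[i] else paste0(b$name[i], "_", asp),
        category = b$category[i], flip = b$flip[i], aspect = asp,
        mask = if (asp == "1:1") b$mask[[i]] else
          make_shape_mask(b$category[i], b$flip[i], asp, dim))
    })
  })
}

#' Filled ellipse mask
#'
#' @param aspect Aspect ratio x:y as a single number (width / height); e.g.
#'   3 gives a 3:1 laterally elongated ellipse, 1/3 a 1:3 vertical one.
#' @param rotation Rotation in degrees (counter-clockwise).
#' @param dim Raster size (px).
#' @return Logical matrix.
#' @export
ellipse_mask <- function(aspect, rotation = 0, dim = 200L) {
  stopifnot(aspect > 0)
  raster_ellipse(a = sqrt(aspect), b = 1 / sqrt(aspect), rotation, dim)
}

#' The ellipse aspect-ratio series
#'
#' The nine aspect ratios (x:y) 1:3, 2:5, 1:2, 2:3, 1:1, 3:2, 2:1, 5:2 and
#' 3:1 used to probe the feature space.
#'
#' @param rotation Rotation in degrees applied to every ellipse.
#' @param dim Raster size (px).
#' @return A tibble with `name`, `aspect` (numeric x/y) and `mask`.
#' @export
ellipse_series <- function(rotation = 0, dim = 200L) {
  asp <- c(`1:3` = 1 / 3, `2:5` = 2 / 5, `1:2` = 1 / 2, `2:3` = 2 / 3,
           `1:1` = 1, `3:2` = 3 / 2, `2:1` = 2, `5:2` = 5 / 2, `3:1` = 3)
  purrr::map_dfr(seq_along(asp), function(i) {
    tibble::tibble(name = paste0("ellipse_", names(asp)[i]),
                   aspect = asp[[i]], rotation = rotation,
                   mask = list(ellipse_mask(asp[[i]], rotation, dim)))
  })
}

#' Multi-edge asymmetric star-like mask
#'
#' A star-like polygon with `n_edges` protrusions whose lengths and angular
#' positions are jittered by `asymmetry` (0 = regular star, 1 = strongly
#' irregular), deterministically per seed. Emulates multi-edged amoeboid
#' probe shapes.
#'
#' @param n_edges Number of protrusions (>= 3).
#' @param asymmetry Jitter amplitude in `[0, 1]`.
#' @param seed Integer seed.
#' @param inner Inner/outer radius ratio of the underlying star.
#' @param dim Raster size (px).
#' @return Logical matrix.
#' @export
multi_edge_mask <- function(n_edges, asymmetry = 0.5, seed = 1L,
                            inner = 0.5, dim = 200L) {
  stopifnot(n_edges >= 3, asymmetry >= 0, asymmetry <= 1)
  rng <- local({
    set.seed(seed)
    list(len = stats::runif(n_edges, -1, 1), ang = stats::runif(n_edges, -1, 1))
  })
  base_th <- pi / 2 + 2 * pi * (0:(n_edges - 1)) / n_edges
  tip_th <- base_th + rng$ang * asymmetry * pi / n_edges
  tip_r <- 1 + rng$len * asymmetry * 0.4
  xy <- matrix(NA_real_, 2 * n_edges, 2)
  for (k in seq_len(n_edges)) {
    xy[2 * k - 1, ] <- tip_r[k] * c(cos(tip_th[k]), sin(tip_th[k]))
    nxt <- tip_th[if (k == n_edges) 1 else k + 1]
    gap <- (nxt - tip_th[k]) %% (2 * pi)   # forward angular gap to next tip
    mid <- tip_th[k] + gap / 2
    xy[2 * k, ] <- inner * c(cos(mid), sin(mid))
  }
  rasterize_polygon(xy, dim)
}

#' Normalize a geometry table through the standard pipeline
#'
#' Runs every mask of a geometry tibble through [normalize_mask()] with the
#' downward direction (the shapes are generated already oriented), replacing
#' the `mask` column with 64 x 64 normalized masks.
#'
#' @param shapes A tibble with a `mask` list-column (from [basic_shapes()],
#'   [expanded_library()], [ellipse_series()], ...).
#' @param ... Passed to [normalize_mask()].
#' @return The tibble with normalized masks.
#' @export
normalize_shapes <- function(shapes, ...) {
  shapes$mask <- lapply(shapes$mask, normalize_mask, direction = c(1, 0), ...)
  shapes
}
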