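#' Derivative of the double-well potential
#'
#' The interfacial free energy uses the Landau double well
#' `G(phi) = 18 phi^2 (1 - phi)^2`, whose derivative
#' `G'(phi) = 36 phi (1 - phi)(1 - 2 phi)` vanishes at the two bulk states
#' (0 and 1) and at the unstable midpoint 0.5.
#'
#' @param phi Numeric scalar, vector or matrix.
#' @return `G'(phi)`, same shape as `phi`.
#' @export
double_well_derivative <- function(phi) {
  36 * phi * (1 - phi) * (1 - 2 * phi)
}

#' Steady states of the bistable polarity reaction
#'
#' Roots of `-rho W^3 + rho W* W^2 - W = 0`: W = 0 always, plus the two
#' nonzero roots `(rho W* +/- sqrt(rho^2 W*^2 - 4 rho)) / (2 rho)` when they
#' are real. The system is bistable iff `W*^2 > 4 / rho`.
#'
#' @param rho Autocatalysis strength (> 0).
#' @param wstar Reciprocal-pool concentration.
#' @return A list with `roots` (sorted numeric vector including 0) and
#'   `bistable` (logical).
#' @export
polarity_steady_states <- function(rho, wstar) {
  stopifnot(rho > 0)
  disc <- rho^2 * wstar^2 - 4 * rho
  if (disc < 0) {
    return(list(roots = 0, bistable = FALSE))
  }
  r <- (rho * wstar + c(-1, 1) * sqrt(disc)) / (2 * rho)
  list(roots = sort(unique(c(0, r))), bistable = wstar^2 > 4 / rho)
}

#' Reciprocal (well-mixed) polarity pool
#'
#' The total protrusive capacity `W_tot` is shared between membrane-bound W
#' and a fast-diffusing reciprocal pool W* that is uniform in space:
#' `W* = (W_tot - integral(phi W)) / integral(phi)`. A negative value is
#' reported with a warning (the pool is overdrawn but the dynamics remain
#' defined); an empty cell is an error.
#'
#' @param state A `field_state` (or a list with `phi`, `W` matrices and a
#'   `grid`).
#' @param W_tot Conserved total capacity.
#' @return Scalar W*.
#' @export
reciprocal_pool <- function(state, W_tot) {
  dx2 <- state$grid$dx^2
  a <- sum(state$phi) * dx2
  if (!is.finite(a) || a < 1e-8) {
    stop("degenerate state: integrated phase field is (near) zero")
  }
  wstar <- (W_tot - sum(state$phi * state$W) * dx2) / a
  if (wstar < 0) warning("reciprocal pool W* is negative (", signif(wstar, 3), ")")
  wstar
}

#' One Ornstein-Uhlenbeck update of the noise field
#'
#' Each lattice site evolves independently with correlation time `theta` and
#' stationary standard deviation `sigma`, using the exact discretization
#' `N <- N exp(-dt/theta) + sigma sqrt(1 - exp(-2 dt/theta)) Z`, which
#' preserves the stationary law for any `dt` and reduces to an identically
#' zero field when `sigma = 0`.
#'
#' @param noise Matrix of current noise values.
#' @param params A [noise_params()].
#' @param dt Time step (simulation time units).
#' @return Updated matrix.
#' @export
ou_noise_update <- function(noise, params, dt) {
  if (params$sigma == 0) return(noise * exp(-dt / params$theta))
  decay <- exp(-dt / params$theta)
  noise * decay + params$sigma * sqrt(1 - decay^2) *
    matrix(stats::rnorm(length(noise)), nrow(noise), ncol(noise))
}

# -- discrete operators (periodic) -------------------------------------------

lap5 <- function(m, g) {
  (m[g$iu, ] + m[g$id, ] + m[, g$jr] + m[, g$jl] - 4 * m) / g$dx^2
}

grad_mag <- function(m, g) {
  gx <- (m[, g$jr] - m[, g$jl]) / (2 * g$dx)
  gy <- (m[g$iu, ] - m[g$id, ]) / (2 * g$dx)
  sqrt(gx^2 + gy^2)
}

# conservative stencil for div(phi grad X)
div_phi_grad <- function(phi, x, g) {
  fr <- (phi[, g$jr] + phi) * (x[, g$jr] - x)
  fl <- (phi + phi[, g$jl]) * (x - x[, g$jl])
  fu <- (phi[g$iu, ] + phi) * (x[g$iu, ] - x)
  fd <- (phi + phi[g$id, ]) * (x - x[g$id, ])
  0.5 * (fr - fl + fu - fd) / g$dx^2
}

# recover a concentration from the evolved product phi * X: exact division
# in the bulk, damped below phi = eps, zeroed in the far exterior so that
# interface residue cannot creep outward through the diffusion stencil
recover_conc <- function(p, phi, eps) {
  x <- p / pmax(phi, eps)
  x[phi < 1e-3] <- 0
  x
}

# polarized initial W: a sector at the upper bistable root whose area is
# the wave-pinning equilibrium (reciprocal pool just inside the bistable
# band), pointing in a random direction drawn from the caller's RNG stream
init_patch_W <- function(g, m, k) {
  wstar_c <- 1.05 * sqrt(4 / k$rho)   # just inside the bistable band
  roots <- polarity_steady_states(k$rho, wstar_c)$roots
  w_up <- max(roots)
  W <- matrix(0, g$ny, g$nx)
  if (w_up <= 0) return(W)
  area_patch <- (k$W_tot - wstar_c * m$A0) / w_up
  if (area_patch <= 0) return(W)
  area_patch <- min(area_patch, m$A0)
  theta0 <- stats::runif(1, 0, 2 * pi)
  half <- pi * area_patch / m$A0
  x <- (seq_len(g$nx) - 0.5) * g$dx - g$nx * g$dx / 2
  y <- (seq_len(g$ny) - 0.5) * g$dx - g$ny * g$dx / 2
  ang <- outer(y, x, function(yy, xx) atan2(yy, xx))
  dang <- (ang - theta0 + pi) %% (2 * pi) - pi
  W[abs(dang) <= half] <- w_up
  W
}

#' Initial field state
#'
#' Builds the standard initial condition: a tanh-profile disk of radius
#' `sqrt(A0 / pi)` centered in the box (the equilibrium interface profile of
#' the double well has width `epsilon`), U at its rest value `s / gamma`,
#' V = 0, and W according to `config$init_W` (by default a polarized sector
#' patch at a seeded random orientation; see [cell_config()]).
#'
#' @param config A [cell_config()].
#' @return An object of class `field_state` with matrices `phi`, `U`, `V`,
#'   `W`, `noise`, scalar `wstar` and time `t = 0`.
#' @export
init_state <- function(config) {
  g <- config$grid; m <- config$mech; k <- config$kinetics
  x <- (seq_len(g$nx) - 0.5) * g$dx
  y <- (seq_len(g$ny) - 0.5) * g$dx
  cx <- g$nx * g$dx / 2; cy <- g$ny * g$dx / 2
  r <- sqrt(outer((y - cy)^2, (x - cx)^2, `+`))
  r0 <- sqrt(m$A0 / pi)
  phi <- 0.5 * (1 - tanh(3 * (r - r0) / m$epsilon))
  W <- switch(config$init_W,
    zero = matrix(0, g$ny, g$nx),
    uniform = matrix(k$W_tot / m$A0, g$ny, g$nx),
    step = {
      w <- matrix(0, g$ny, g$nx)
      roots <- polarity_steady_states(k$rho, k$W_tot / m$A0)$roots
      w[, x > cx] <- max(roots)
      w
    },
    patch = init_patch_W(g, m, k))
  st <- structure(
    list(phi = phi,
         U = matrix(k$s / k$gamma, g$ny, g$nx) * (phi > 0),
         V = matrix(0, g$ny, g$nx),
         W = W,
         noise = matrix(0, g$ny, g$nx),
         wstar = NA_real_, t = 0, grid = g),
    class = "field_state")
  st$wstar <- suppressWarnings(reciprocal_pool(st, k$W_tot))
  st
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> t = %.3f, area = %.2f um^2, W* = %.4f\n",
              x$t, sum(x$phi) * x$grid$dx^2, x$wstar))
  invisible(x)
}

#' Advance the coupled fields by one explicit time step
#'
#' One forward-Euler step of the phase field (interfacial mechanics with
#' area restoration and the protrusive force) and of the three signaling
#' fields evolved as products `phi * X` (excitable U <-> V conversion with
#' global-mean saturation, basal supply/decay, edge-restricted noise,
#' boundary flux of U, bistable W reaction with the V coupling, and
#' conservative `div(phi grad X)` diffusion). After the update the
#' reciprocal pool W* is recomputed from the new fields so that the
#' conservation identity holds exactly at every step.
#'
#' @param state A `field_state`.
#' @param config A [cell_config()].
#' @param dt Time step; defaults to [stable_dt()] of the configuration.
#' @return The advanced `field_state`.
#' @export
step_fields <- function(state, config, dt = NULL) {
  g <- config$grid; mech <- config$mech; k <- config$kinetics
  tp <- config$tau_prime
  if (is.null(dt)) dt <- if (!is.null(g$dt)) g$dt else stable_dt(config)
  phi <- state$phi; U <- state$U; V <- state$V; W <- state$W
  dx2 <- g$dx^2
  area <- sum(phi) * dx2

  gmag <- grad_mag(phi, g)
  variant <- config$variant

  # --- phase field -----------------------------------------------------------
  if (!config$freeze_phi) {
    fprot <- switch(variant,
      full = mech$a_W * W,
      one_variable = mech$a_W * W,
      two_variable = mech$a_W * V)
    dphi <- (mech$eta * (lap5(phi, g) -
                           double_well_derivative(phi) / mech$epsilon^2) -
               mech$M * (area - mech$A0) * gmag + fprot * gmag) / mech$tau
    phi_new <- phi + dt * dphi
  } else {
    phi_new <- phi
  }

  # --- signaling -------------------------------------------------------------
  U_new <- U; V_new <- V; W_new <- W; noise_new <- state$noise
  eps2 <- config$phi_eps

  if (variant != "one_variable") {
    noise_new <- ou_noise_update(state$noise, config$noise, dt)
    mean_pvw <- sum(phi * V * W) * dx2 / area
    mean_pu <- sum(phi * U) * dx2 / area
    wgate <- if (variant == "two_variable") 1 else W
    conv_fwd <- k$alpha * U * V * wgate / (k$K_k + mean_pvw)
    conv_bwd <- k$beta * U * V / (k$K_p + mean_pu)
    ig <- sum(gmag^2) * dx2
    sinkU <- if (k$chi_U > 0 && ig > 0) k$chi_U * U * gmag^2 / ig else 0
    # edge fluctuations: the noise drive is restricted to the interface band
    ew <- pmax(4 * phi * (1 - phi), 0)
    RU <- phi * (-conv_fwd + conv_bwd + k$s - k$gamma * U) +
      k$D_U * div_phi_grad(phi, U, g) - ew * state$noise - sinkU
    RV <- phi * (conv_fwd - conv_bwd - k$mu * V) +
      k$D_V * div_phi_grad(phi, V, g) + ew * state$noise
    pU <- phi * U + dt * RU / tp
    pV <- phi * V + dt * RV / tp
    # concentrations are non-negative; the bilinear U-V conversion is
    # unstable to sign changes, so negative excursions (noise) are clipped
    U_new <- pmax(recover_conc(pU, phi_new, eps2), 0)
    V_new <- pmax(recover_conc(pV, phi_new, eps2), 0)
  }

  if (variant != "two_variable") {
    RW <- phi * (k$k_W1 * (-k$rho * W^3 + k$rho * W^2 * state$wstar - W) +
                   k$zeta * V) + k$D_W * div_phi_grad(phi, W, g)
    pW <- phi * W + dt * RW / tp
    W_new <- recover_conc(pW, phi_new, eps2)
  }

  if (!all(is.finite(phi_new)) || !all(is.finite(U_new)) ||
      !all(is.finite(V_new)) || !all(is.finite(W_new))) {
    stop("numerical instability: non-finite field values at t = ",
         signif(state$t, 6), "; dt = ", signif(dt, 4),
         " exceeds a stability bound (stable_dt(config) = ",
         signif(stable_dt(config), 4), ")")
  }
  if (min(phi_new) < -0.05 || max(phi_new) > 1.05) {
    stop("numerical instability: phase field left [-0.05, 1.05] at t = ",
         signif(state$t, 6), " (range ", signif(min(phi_new), 3), " .. ",
         signif(max(phi_new), 3), "); reduce dt (stable_dt(config) = ",
         signif(stable_dt(config), 4), ")")
  }

  out <- state
  out$phi <- phi_new; out$U <- U_new; out$V <- V_new; out$W <- W_new
  out$noise <- noise_new
  out$t <- state$t + dt
  out$wstar <- suppressWarnings(reciprocal_pool(out, k$W_tot))
  out
}

# torus-aware centroid of a weight field, in um (x, y)
torus_centroid <- function(w, g) {
  tot <- sum(w)
  circ <- function(idx_weights, n) {
    th <- 2 * pi * (seq_len(n) - 0.5) / n
    ang <- atan2(sum(idx_weights * sin(th)), sum(idx_weights * cos(th)))
    ((ang / (2 * pi)) %% 1) * n
  }
  cx <- circ(colSums(w) / tot, g$nx) * g$dx
  cy <- circ(rowSums(w) / tot, g$ny) * g$dx
  c(x = cx, y = cy)
}

# integer circular shift placing the centroid at the box center
recenter_field <- function(m, centroid, g) {
  sx <- round(g$nx / 2 - centroid[["x"]] / g$dx)
  sy <- round(g$ny / 2 - centroid[["y"]] / g$dx)
  m[((seq_len(g$ny) - 1 - sy) %% g$ny) + 1, ((seq_len(g$nx) - 1 - sx) %% g$nx) + 1]
}

#' Run a full simulation
#'
#' Integrates the model from the standard initial condition and samples the
#' state at a fixed interval. Times are reported in real seconds
#' (`tau_prime` x simulation time). Each sampled frame is recentered on the
#' torus so the cell never straddles the periodic boundary; the centroid
#' series is unwrapped to a continuous trajectory in um. Fragmentation
#' events (the phase field splitting into more than one connected component
#' above a threshold area) are logged per frame.
#'
#' @param config A [cell_config()].
#' @param duration Total simulated real time (s).
#' @param sample_interval Sampling interval (s).
#' @param seed Integer seed (all randomness derives from it).
#' @param store_fields Character subset of `c("phi", "U", "V", "W")` to
#'   retain per sampled frame (recentered). `phi` is always stored.
#' @param fragment_min_area Minimum area (um^2) for a secondary component to
#'   be logged as a fragment.
#' @param progress Print a progress line every so many samples (0 = quiet).
#' @return A `cell_trajectory`: list with `frames` (list of recentered field
#'   matrices), `centroid` (tibble: frame, time, x, y, area, wstar),
#'   `fragments` (tibble log), `config`, `seed`, `sample_interval`.
#' @export
run_simulation <- function(config, duration, sample_interval, seed = 1L,
                           store_fields = "phi", fragment_min_area = 0.5,
                           progress = 0) {
  stopifnot(duration >= sample_interval, sample_interval > 0)
  store_fields <- union("phi", store_fields)
  set.seed(seed)
  g <- config$grid
  dt <- if (!is.null(g$dt)) g$dt else stable_dt(config)
  tp <- config$tau_prime
  n_samples <- floor(duration / sample_interval)
  steps_per_sample <- max(1L, round(sample_interval / tp / dt))
  dt <- sample_interval / tp / steps_per_sample  # land exactly on sample times

  state <- init_state(config)
  frames <- vector("list", n_samples + 1L)
  cent_raw <- matrix(NA_real_, n_samples + 1L, 2L)
  rows <- vector("list", n_samples + 1L)
  frag_rows <- list()

  record <- function(i, state) {
    cen <- torus_centroid(state$phi, g)
    cent_raw[i, ] <<- cen
    fr <- lapply(state[store_fields], recenter_field, centroid = cen, g = g)
    frames[[i]] <<- fr
    comp <- label_components(fr$phi >= 0.5)
    areas <- sort(tabulate(comp[comp > 0]) * g$dx^2, decreasing = TRUE)
    if (length(areas) > 1L) {
      extra <- areas[-1L][areas[-1L] >= fragment_min_area]
      if (length(extra)) {
        frag_rows[[length(frag_rows) + 1L]] <<- tibble::tibble(
          frame = i - 1L, time = state$t * tp, n_fragments = length(extra),
          fragment_area = sum(extra))
      }
    }
    rows[[i]] <<- c(time = state$t * tp, area = sum(state$phi) * g$dx^2,
                    wstar = state$wstar)
  }

  record(1L, state)
  for (i in seq_len(n_samples)) {
    for (s in seq_len(steps_per_sample)) state <- step_fields(state, config, dt)
    record(i + 1L, state)
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("t = %.0f s / %.0f s", state$t * tp, duration))
    }
  }

  # unwrap the torus centroid to a continuous track
  L <- c(g$nx * g$dx, g$ny * g$dx)
  cent <- cent_raw
  for (j in 1:2) {
    d <- diff(cent_raw[, j])
    d <- d - round(d / L[j]) * L[j]
    cent[, j] <- cent_raw[1, j] + c(0, cumsum(d))
  }
  info <- do.call(rbind, rows)
  centroid <- tibble::tibble(
    frame = 0:n_samples, time = info[, "time"],
    x = cent[, 1], y = cent[, 2],
    area = info[, "area"], wstar = info[, "wstar"])

  structure(
    list(frames = frames, centroid = centroid,
         fragments = if (length(frag_rows)) dplyr::bind_rows(frag_rows) else
           tibble::tibble(frame = integer(), time = double(),
                          n_fragments = integer(), fragment_area = double()),
         config = config, seed = seed, sample_interval = sample_interval,
         store_fields = store_fields),
    class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cell_trajectory> %d frames @ %g s, %d x %d grid, variant '%s'\n",
    length(x$frames), x$sample_interval, x$config$grid$nx, x$config$grid$ny,
    x$config$variant))
  cat(sprintf("  duration %.0f s, mean area %.2f um^2, %d fragmentation events\n",
              max(x$centroid$time), mean(x$centroid$area), nrow(x$fragments)))
  invisible(x)
}

#' Per-frame summary of a trajectory
#'
#' @param x A `cell_trajectory`.
#' @param ... Unused.
#' @return A tibble with one row per sampled frame: time, centroid,
#'   integrated area, reciprocal pool, circularity (4 pi A / P^2) and
#'   motion-aligned aspect ratio of the binarized mask.
#' @method tidy cell_trajectory
#' @export
tidy.cell_trajectory <- function(x, ...) {
  shapes <- purrr::map_dfr(seq_along(x$frames), function(i) {
    msk <- x$frames[[i]]$phi >= 0.5
    tibble::tibble(circularity = mask_circularity(msk),
                   aspect = mask_aspect(msk))
  })
  dplyr::bind_cols(x$centroid, shapes)
}

#' @method glance cell_trajectory
#' @export
glance.cell_trajectory <- function(x, ...) {
  td <- tidy(x)
  n <- nrow(td)
  tail3 <- td[td$frame >= n %/% 3, ]
  tibble::tibble(
    n_frames = n,
    duration = max(td$time),
    mean_area = mean(td$area),
    mean_area_final_two_thirds = mean(tail3$area),
    mean_circularity = mean(td$circularity, na.rm = TRUE),
    mean_aspect = mean(td$aspect, na.rm = TRUE),
    net_displacement = sqrt((td$x[n] - td$x[1])^2 + (td$y[n] - td$y[1])^2),
    n_fragment_events = nrow(x$fragments))
}

# mask helpers shared with the shape pipeline --------------------------------

mask_circularity <- function(mask) {
  a <- sum(mask)
  if (a == 0) return(NA_real_)
  ct <- try(extract_contour(mask, n_points = 256L), silent = TRUE)
  if (inherits(ct, "try-error")) return(NA_real_)
  p <- contour_perimeter(ct)
  4 * pi * a / p^2
}

# aspect ratio from the second-moment tensor (major / minor axis)
mask_aspect <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 4) return(NA_real_)
  cc <- scale(idx, scale = FALSE)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$values
  if (ev[2] <= 0) return(NA_real_)
  sqrt(ev[1] / ev[2])
}
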