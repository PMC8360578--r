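#' Simulation grid specification
#'
#' Defines the periodic square lattice on which all fields live. The default
#' 128 x 128 grid at `dx = 0.3` um gives a 38.4 um periodic box in which a
#' 5-um-radius cell spans roughly 33 grid points.
#'
#' If `dt` is not supplied it is derived from the tightest of three explicit
#' stability bounds (diffusive, interfacial-mechanics, and bistable-reaction)
#' scaled by `safety`; see [stable_dt()].
#'
#' @param nx,ny Number of grid cells in x and y (>= 32).
#' @param dx Grid spacing in um.
#' @param dt Time step in simulation time units, or `NULL` to derive it.
#' @param safety Fraction of the tightest stability bound used when deriving
#'   `dt`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nx = 128L, ny = 128L, dx = 0.3, dt = NULL, safety = 0.8) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 32L, ny >= 32L, dx > 0, safety > 0, safety <= 1)
  if (!is.null(dt)) stopifnot(dt > 0)
  structure(
    list(
      nx = nx, ny = ny, dx = dx, dt = dt, safety = safety,
      boundary = "periodic",
      # precomputed periodic shift indices (rows = y, cols = x)
      iu = c(2:ny, 1L), id = c(ny, 1:(ny - 1L)),
      jr = c(2:nx, 1L), jl = c(nx, 1:(nx - 1L))
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d periodic, dx = %g um, dt = %s\n",
              x$nx, x$ny, x$dx,
              if (is.null(x$dt)) "auto" else format(x$dt)))
  invisible(x)
}

#' Mechanical (phase-field) parameters
#'
#' Parameters of the interfacial mechanics: viscous friction, surface
#' tension, interface width, area-constraint strength, target area, and the
#' protrusive-force coefficient that converts the local polarity field into
#' an outward normal force.
#'
#' @param tau Friction coefficient (pN s/um^2).
#' @param eta Surface tension (pN).
#' @param epsilon Interface width (um).
#' @param M Area-constraint strength (pN/um^3).
#' @param A0 Target cell area (um^2); the default corresponds to a circle of
#'   radius ~5 um.
#' @param a_W Protrusive-force coefficient (pN/um per unit of the polarity
#'   field). Values outside the explored band `[0.8, 5.6]` are accepted with
#'   a warning.
#' @return An object of class `mech_params`.
#' @export
mech_params <- function(tau = 0.83, eta = 1.0, epsilon = 1.0, M = 0.5,
                        A0 = 78.83, a_W = 2.4) {
  vals <- c(tau = tau, eta = eta, epsilon = epsilon, M = M, A0 = A0)
  if (any(vals <= 0)) stop("all mechanical parameters must be strictly positive")
  if (a_W < 0) stop("a_W must be non-negative")
  if (a_W > 0 && (a_W < 0.8 || a_W > 5.6)) {
    warning("a_W = ", a_W, " lies outside the explored band [0.8, 5.6]")
  }
  structure(list(tau = tau, eta = eta, epsilon = epsilon, M = M, A0 = A0,
                 a_W = a_W), class = "mech_params")
}

#' Signaling (reaction-diffusion) parameters
#'
#' Kinetic constants of the coupled excitable/bistable network. `alpha` and
#' `beta` are the U -> V and V -> U conversion rates with saturation
#' constants `K_k` and `K_p` acting on the two global-mean Michaelis terms;
#' `s` and `gamma` are the basal supply and decay of U; `mu` the decay of V;
#' `k_W1`, `rho` set the strength and autocatalysis of the bistable polarity
#' reaction; `zeta` couples V into W; `W_tot` is the conserved total
#' protrusive capacity shared between membrane-bound W and the well-mixed
#' reciprocal pool; `D_U`, `D_V`, `D_W` are diffusivities (um^2 per
#' simulation time unit) and `chi_U` the boundary-flux coefficient that
#' drains U at the interface.
#'
#' Defaults combine a reference migratory parameter set (`chi_U`, `k_W1`,
#' `mu`, `rho`, `gamma`, `D_W`, `W_tot`) with excitable-loop constants chosen
#' so that the rest state (U = s/gamma, V = 0) is stable and noise-driven V
#' pulses are gated by the local polarity level; see the methods vignette.
#'
#' @param alpha,beta Conversion rates U <-> V.
#' @param K_k,K_p Saturation constants of the global-mean Michaelis terms.
#' @param s Basal U supply. @param gamma U decay rate. @param mu V decay rate.
#' @param k_W1 Bistable reaction strength. @param rho Autocatalysis strength.
#' @param zeta V -> W coupling. @param W_tot Conserved protrusive capacity.
#' @param D_U,D_V,D_W Diffusivities. @param chi_U Boundary-flux coefficient.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(alpha = 1.5, beta = 0.3, K_k = 0.3, K_p = 1.0,
                           s = 0.1, gamma = 0.1, mu = 0.5,
                           k_W1 = 90, rho = 5.5556, zeta = 20,
                           W_tot = 80, D_U = 0.5, D_V = 0.5, D_W = 3,
                           chi_U = 50) {
  vals <- c(alpha = alpha, beta = beta, K_k = K_k, K_p = K_p, s = s,
            gamma = gamma, mu = mu, k_W1 = k_W1, rho = rho, zeta = zeta,
            W_tot = W_tot, D_U = D_U, D_V = D_V, D_W = D_W, chi_U = chi_U)
  if (any(vals < 0)) stop("kinetic parameters must be non-negative")
  if (k_W1 > 0 && rho <= 0) stop("rho must be > 0 when k_W1 > 0")
  structure(as.list(vals), class = "kinetic_params")
}

#' Edge-fluctuation noise parameters
#'
#' Per-site independent Ornstein-Uhlenbeck noise with correlation time
#' `theta` and stationary standard deviation `sigma`, in simulation time
#' units. The noise enters the U equation with a minus sign and the V
#' equation with a plus sign so that it conserves U + V.
#'
#' @param theta Correlation time (> 0).
#' @param sigma Stationary standard deviation (>= 0).
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(theta = 1.4, sigma = 0.075) {
  stopifnot(theta > 0, sigma >= 0)
  structure(list(theta = theta, sigma = sigma), class = "noise_params")
}

#' Full simulation configuration
#'
#' Bundles grid, mechanical, kinetic and noise parameters with the model
#' variant and the time-scale factor `tau_prime` that (i) multiplies the
#' signaling time derivatives and (ii) converts simulation time to seconds
#' when trajectories are reported.
#'
#' @param grid A [grid_spec()].
#' @param mech A [mech_params()].
#' @param kinetics A [kinetic_params()].
#' @param noise A [noise_params()].
#' @param tau_prime Time-scale factor (> 0), default 10.
#' @param variant Model variant: `"full"` (3-variable), `"one_variable"`
#'   (W only; U, V frozen at rest), or `"two_variable"` (U, V only; the
#'   protrusive force is sourced from V).
#' @param freeze_phi If `TRUE` the phase field is held fixed (used for
#'   reaction-diffusion analyses on a frozen domain).
#' @param init_W Initial condition for W: `"patch"` (a sector of the cell
#'   at the upper bistable root, sized to the wave-pinning equilibrium and
#'   oriented at a seeded uniform random angle; when `W_tot` is too small
#'   for bistability the patch is empty and W starts at 0), `"uniform"`
#'   (all capacity membrane-bound), `"zero"` (all capacity in the
#'   reciprocal pool), or `"step"` (half the domain at the upper bistable
#'   root; used for wave-pinning analyses).
#' @param phi_eps Regularization used when recovering a concentration X from
#'   the evolved product phi*X.
#' @return An object of class `cell_config`.
#' @export
cell_config <- function(grid = grid_spec(), mech = mech_params(),
                        kinetics = kinetic_params(), noise = noise_params(),
                        tau_prime = 10,
                        variant = c("full", "one_variable", "two_variable"),
                        freeze_phi = FALSE,
                        init_W = c("patch", "uniform", "zero", "step"),
                        phi_eps = 0.1) {
  variant <- match.arg(variant)
  init_W <- match.arg(init_W)
  stopifnot(inherits(grid, "grid_spec"), inherits(mech, "mech_params"),
            inherits(kinetics, "kinetic_params"), inherits(noise, "noise_params"),
            tau_prime > 0, phi_eps > 0)
  structure(list(grid = grid, mech = mech, kinetics = kinetics, noise = noise,
                 tau_prime = tau_prime, variant = variant,
                 freeze_phi = isTRUE(freeze_phi), init_W = init_W,
                 phi_eps = phi_eps),
            class = "cell_config")
}

#' Stable explicit time step for a configuration
#'
#' Returns the explicit-Euler time step derived from three bounds: the
#' diffusive bound `dx^2 * tau_prime / (4 * D_max)` for the signaling fields
#' (whose time derivatives carry the factor `tau_prime`), the interfacial
#' mechanics bound `tau * dx^2 * epsilon^2 / (4 * eta * d)` with `d = 2`
#' dimensions, and a bistable-reaction bound `tau_prime / (6 * k_W1 * rho)`,
#' multiplied by the grid's safety factor.
#'
#' @param config A [cell_config()].
#' @return Time step (simulation time units).
#' @export
stable_dt <- function(config) {
  g <- config$grid; k <- config$kinetics; m <- config$mech
  dmax <- max(k$D_U, k$D_V, k$D_W, 1e-12)
  b_diff <- g$dx^2 * config$tau_prime / (4 * dmax)
  b_mech <- m$tau * g$dx^2 * m$epsilon^2 / (4 * m$eta * 2)
  b_reac <- if (k$k_W1 > 0) config$tau_prime / (6 * k$k_W1 * max(k$rho, 1)) else Inf
  g$safety * min(b_diff, b_mech, b_reac)
}

#' Read/write a flat key-value simulation configuration
#'
#' The on-disk format is flat YAML whose keys mirror the parameter
#' constructors (for example `a_W`, `W_tot`, `theta`, `nx`, `variant`).
#' Unknown keys raise an error naming the key.
#'
#' @param path File path.
#' @param config A [cell_config()] (for writing).
#' @return `read_cell_config()` returns a [cell_config()].
#' @export
read_cell_config <- function(path) {
  kv <- yaml::read_yaml(path)
  config_from_list(kv)
}

#' @rdname read_cell_config
#' @export
write_cell_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

config_to_list <- function(config) {
  g <- config$grid
  c(list(nx = g$nx, ny = g$ny, dx = g$dx, dt = g$dt, safety = g$safety),
    unclass(config$mech), unclass(config$kinetics), unclass(config$noise),
    list(tau_prime = config$tau_prime, variant = config$variant,
         freeze_phi = config$freeze_phi, init_W = config$init_W,
         phi_eps = config$phi_eps))
}

config_from_list <- function(kv) {
  known <- list(
    grid = c("nx", "ny", "dx", "dt", "safety"),
    mech = names(formals(mech_params)),
    kinetics = names(formals(kinetic_params)),
    noise = c("theta", "sigma"),
    top = c("tau_prime", "variant", "freeze_phi", "init_W", "phi_eps")
  )
  bad <- setdiff(names(kv), unlist(known))
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  take <- function(keys) kv[intersect(keys, names(kv))]
  args <- take(known$top)
  args$grid <- do.call(grid_spec, take(known$grid))
  args$mech <- do.call(mech_params, take(known$mech))
  args$kinetics <- do.call(kinetic_params, take(known$kinetics))
  args$noise <- do.call(noise_params, take(known$noise))
  do.call(cell_config, args)
}

#' Update a configuration with flat parameter overrides
#'
#' Convenience used by parameter sweeps: accepts a named list whose entries
#' may refer to any flat key of the configuration (e.g. `a_W`, `W_tot`,
#' `sigma`) and returns a rebuilt, validated configuration.
#'
#' @param config A [cell_config()].
#' @param ... Named flat overrides (or a single named list).
#' @return A [cell_config()].
#' @export
update_config <- function(config, ...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1L]])) {
    dots <- dots[[1L]]
  }
  if (length(dots) == 0L) return(config)
  if (is.null(names(dots)) || any(names(dots) == "")) {
    stop("all overrides must be named")
  }
  kv <- config_to_list(config)
  kv <- kv[!vapply(kv, is.null, logical(1))]
  kv[names(dots)] <- dots
  config_from_list(kv)
}
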