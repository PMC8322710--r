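#' Per-vertex wall speed history during a saccade
#'
#' The chamber rotates rigidly about the saccade axis, so a wall point at
#' perpendicular distance d from the axis moves tangentially with speed
#' U(x, t) = omega(t) d(x). Distances are converted to metres so speeds are
#' in m/s.
#'
#' @param geom An `eye_geometry`.
#' @param wave A [saccade_wave()].
#' @param times Sample times, s, within `[0, 2*duration]`.
#' @return List with `U` (n_vertex x n_time speed matrix, m/s), `d_m`
#'   (axis distances, m), `dir` (n x 3 unit tangential directions; zero rows
#'   on the axis) and `times`.
#' @export
wall_velocity_series <- function(geom, wave, times) {
  ax <- wave$rotation_axis
  v <- geom$vertices * 1e-3                    # mm -> m
  axpos <- c(v %*% ax)
  perp <- v - outer(axpos, ax)
  d <- sqrt(rowSums(perp^2))
  tang <- cbind(ax[2] * v[, 3] - ax[3] * v[, 2],
                ax[3] * v[, 1] - ax[1] * v[, 3],
                ax[1] * v[, 2] - ax[2] * v[, 1])   # axis x position
  nt <- sqrt(rowSums(tang^2))
  dir <- tang / ifelse(nt > 1e-15, nt, 1)
  dir[nt <= 1e-15, ] <- 0
  om <- saccade_omega(wave, times) * pi / 180  # rad/s
  list(U = outer(d, om), d_m = d, dir = dir, times = times)
}

#' Unsteady Stokes-layer wall shear from a wall speed history
#'
#' Treats the fluid adjacent to each wall point as a semi-infinite Newtonian
#' half-space dragged by the impulsively accelerating wall (Rayleigh/Stokes
#' first problem). By Duhamel superposition over the acceleration history,
#'
#'   tau(t) = sqrt(rho mu / pi) * integral_0^t U'(s) / sqrt(t - s) ds.
#'
#' The convolution is evaluated with a product-integration rule: U is taken
#' piecewise linear on the (uniform) grid, so U' is piecewise constant and
#' the weakly singular kernel integrates exactly on each step,
#' integral = 2 (sqrt(t_n - t_{k-1}) - sqrt(t_n - t_k)). This reproduces the
#' step and oscillatory closed forms to discretization accuracy.
#'
#' The returned value is the signed shear felt by the fluid in the direction
#' of wall motion; the traction exerted on the wall is its negative.
#'
#' @param U Wall speed history, m/s, sampled at `times` (U[1] must be 0).
#' @param times Uniform time grid, s.
#' @param mu Dynamic viscosity, Pa.s.
#' @param rho Density, kg/m^3.
#' @param on_nonuniform `"error"` (default) or `"resample"`: what to do when
#'   the grid is not uniform (resampling interpolates linearly onto a uniform
#'   grid of the same length).
#' @return Numeric vector of shear values, Pa, at `times`.
#' @export
stokes_wall_stress <- function(U, times, mu, rho,
                               on_nonuniform = c("error", "resample")) {
  stopifnot(length(U) == length(times), length(times) >= 2, mu > 0, rho > 0)
  on_nonuniform <- match.arg(on_nonuniform)
  dt <- diff(times)
  if (diff(range(dt)) > 1e-9 * mean(dt)) {
    if (on_nonuniform == "error")
      stop("time grid must be uniform (or set on_nonuniform = 'resample')",
           call. = FALSE)
    tu <- seq(times[1], times[length(times)], length.out = length(times))
    U <- stats::approx(times, U, xout = tu)$y
    times <- tu
  }
  sqrt(rho * mu / pi) * duhamel_sqrt_convolution(U, times)
}

## Product-integration convolution of dU/dt against 1/sqrt(t - s).
duhamel_sqrt_convolution <- function(U, times) {
  n <- length(times)
  dU <- diff(U)
  dt <- diff(times)
  out <- numeric(n)
  for (i in 2:n) {
    k <- seq_len(i - 1L)
    w <- 2 * (sqrt(times[i] - times[k]) - sqrt(times[i] - times[k + 1L]))
    out[i] <- sum((dU[k] / dt[k]) * w)
  }
  out
}

#' Saccadic wall-shear simulation on a tamponade equilibrium
#'
#' Runs the Stokes-layer model at every wall vertex with the fluid assigned
#' from the static equilibrium wetting map (oil where wet, aqueous where
#' dry), the assignment being frozen for the duration of the saccade. Because
#' the wall speed is separable, U(x, t) = d(x) omega(t), a single unit
#' convolution per fluid gives the full traction field. The traction vector
#' at a vertex is the (signed) magnitude times the unit wall-velocity
#' direction; it opposes the wall motion while the eye accelerates and
#' persists after the stop as the fluid's momentum drags the wall.
#'
#' @param geom Segmented `eye_geometry` the equilibrium was solved on.
#' @param state An `equilibrium_state` for the same geometry.
#' @param fluids A [fluid_pair()] (oil viscosity in mPa.s selects the grade).
#' @param wave A [saccade_wave()].
#' @param dt Time step, s (uniform grid over `[0, 2*duration]`).
#' @return A `traction_series`: `times` (s), `magnitude` (n_vertex x n_time
#'   signed traction along `dir`, Pa), `dir` (unit directions), `viscosity`
#'   and `density` per vertex (Pa.s, kg/m^3), `wet` assignment.
#' @export
simulate_saccade_shear <- function(geom, state, fluids, wave, dt = 1e-3) {
  stopifnot(inherits(state, "equilibrium_state"),
            inherits(fluids, "fluid_pair"))
  if (length(state$wet) != nrow(geom$vertices) ||
      (!is.null(state$geom_signature) &&
       !isTRUE(all.equal(state$geom_signature, geom_signature(geom)))))
    stop("equilibrium state does not match the geometry", call. = FALSE)
  times <- seq(0, 2 * wave$duration, by = dt)
  wv <- wall_velocity_series(geom, wave, times)
  om <- saccade_omega(wave, times) * pi / 180
  conv <- duhamel_sqrt_convolution(om, times)   # per unit axis distance
  mu <- ifelse(state$wet, fluids$oil_viscosity, fluids$aqueous_viscosity) * 1e-3
  rho <- ifelse(state$wet, fluids$oil_density, fluids$aqueous_density)
  ## traction on the wall = -sqrt(rho mu / pi) * d * conv, along dir
  mag <- outer(-sqrt(rho * mu / pi) * wv$d_m, conv)
  structure(list(
    times = times, magnitude = mag, dir = wv$dir,
    viscosity = mu, density = rho, wet = state$wet,
    n_vertices = nrow(geom$vertices),
    wave = wave, posture = state$posture, fill = state$fill,
    oil_viscosity_mPas = fluids$oil_viscosity
  ), class = "traction_series")
}

#' @export
print.traction_series <- function(x, ...) {
  cat(sprintf(
    "traction_series: %d vertices x %d samples over [0, %.3f] s\n",
    nrow(x$magnitude), length(x$times), max(x$times)))
  cat(sprintf("  oil %g mPa.s, fill %.2f, posture %s; peak |traction| %.2f Pa\n",
              x$oil_viscosity_mPas, x$fill,
              if (!is.null(x$posture)) x$posture$name else "?",
              max(abs(x$magnitude))))
  invisible(x)
}
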