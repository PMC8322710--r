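#' Seeded synthetic fixtures with built-in oracles
#'
#' Generators for inputs with analytically known structure, so that every
#' stage of the pipeline can be tested without external data. Each generator
#' is deterministic under a fixed seed and returns its own closed-form
#' expected values alongside the data.
#'
#' `separable_traction_fixture()` builds a traction series with exactly
#' separable space-time structure tau(x, t) = A(x) b(t) along the tangential
#' direction field of the rotation axis, emulating the structure of saccadic
#' wall shear. The amplitude field A is a seeded low-order spherical-harmonic
#' combination (smooth, so its extrema are stable under meshing), made
#' non-negative by construction. All five shear metrics then have closed
#' forms, returned in `$expected`.
#'
#' @param geom A segmented `eye_geometry`.
#' @param seed Integer seed.
#' @param times Time grid, s.
#' @param profile `"two_bumps"` (default; two Gaussian bumps, the bimodality
#'   harness), `"constant"`, or a function of time returning b(t) >= 0.
#' @param degree Spherical-harmonic degree of the amplitude field (1 or 2).
#' @param viscosity Uniform viscosity attached to the series, Pa.s.
#' @return List with `series` (a `traction_series`), `A`, `b`, and `expected`
#'   (closed-form imss/arss/imsr per requested region plus pmss/vass fields).
#' @export
separable_traction_fixture <- function(geom, seed = 1,
                                       times = seq(0, 0.274, by = 1e-3),
                                       profile = "two_bumps",
                                       degree = 2, viscosity = 1) {
  set.seed(seed)
  n <- nrow(geom$vertices)
  nrm <- geom$vertices / sqrt(rowSums(geom$vertices^2))
  ## smooth positive amplitude: |low-order harmonic| + offset
  co <- stats::rnorm(3)
  A <- co[1] * nrm[, 1] + co[2] * nrm[, 2] + co[3] * nrm[, 3]
  if (degree >= 2) {
    cq <- stats::rnorm(6, sd = 0.5)
    A <- A + cq[1] * nrm[, 1] * nrm[, 2] + cq[2] * nrm[, 2] * nrm[, 3] +
      cq[3] * nrm[, 1] * nrm[, 3] + cq[4] * (nrm[, 1]^2 - nrm[, 3]^2) +
      cq[5] * (nrm[, 2]^2 - nrm[, 3]^2) + cq[6]
  }
  A <- abs(A) + 0.1
  b <- if (is.function(profile)) profile(times)
  else switch(profile,
              constant = rep(1, length(times)),
              two_bumps = exp(-((times - 0.03) / 0.012)^2) +
                0.8 * exp(-((times - 0.137) / 0.012)^2),
              stop("unknown profile", call. = FALSE))
  stopifnot(all(b >= 0))
  ## tangential direction field about the superior axis
  ax <- c(0, 1, 0)
  tang <- cbind(ax[2] * nrm[, 3] - ax[3] * nrm[, 2],
                ax[3] * nrm[, 1] - ax[1] * nrm[, 3],
                ax[1] * nrm[, 2] - ax[2] * nrm[, 1])
  nt <- sqrt(rowSums(tang^2))
  dir <- tang / ifelse(nt > 1e-12, nt, 1)
  dir[nt <= 1e-12, ] <- 0

  series <- structure(list(
    times = times, magnitude = outer(A, b), dir = dir,
    viscosity = rep(viscosity, n), density = rep(1000, n),
    wet = rep(TRUE, n), n_vertices = n,
    wave = NULL, posture = posture("standing"), fill = NA_real_,
    oil_viscosity_mPas = viscosity * 1e3
  ), class = "traction_series")

  w <- vertex_areas(geom)
  up <- c(0, 1, 0)
  vcomp <- c(dir %*% up)
  expected_region <- function(region, hemisphere = "both") {
    m <- region_vertex_mask(geom, region, hemisphere)
    list(imss = max(A[m]) * b,
         arss = sum(A[m] * w[m]) / sum(w[m]) * b,
         imsr = max(A[m]) * b / viscosity)
  }
  list(series = series, A = A, b = b,
       expected = list(
         retina = expected_region("retina"),
         wall = expected_region("wall"),
         pmss = A * max(b),
         vass = A * mean(b) * vcomp))
}

#' Closed-form flat-interface coverage table
#'
#' For a lens-free spherical chamber and a flat interface, the covered wall
#' fraction at fill f is x/2 where x solves x^2 (3 - x) = 4 f; the interface
#' plane sits at height R (x - 1) above the centre. Used as the oracle for
#' the equilibrium solvers.
#'
#' @param fills Fill fractions in (0, 1).
#' @param eye_radius Chamber radius, mm.
#' @return data.frame with `fill`, `plane_height_mm`, `coverage`.
#' @export
analytic_cap_fixture <- function(fills = c(0.80, 0.85, 0.90, 0.95),
                                 eye_radius = 12) {
  stopifnot(all(fills > 0 & fills < 1))
  x <- vapply(fills, function(f)
    stats::uniroot(function(x) x^2 * (3 - x) - 4 * f, c(0, 2),
                   tol = 1e-12)$root, 0)
  data.frame(fill = fills,
             plane_height_mm = eye_radius * (x - 1),
             coverage = x / 2)
}

#' The full experimental configuration grid
#'
#' Cartesian product of 2 oil grades x 5 fill fractions (80-100% in 5%
#' steps) x 3 postures = 30 dynamic configurations; the static-equilibrium
#' subgrid (viscosity dropped) has 15 unique members.
#'
#' @param oils Oil viscosities, mPa.s.
#' @param fills Fill fractions.
#' @param postures Posture names.
#' @return data.frame with columns `oil_mPas`, `fill`, `posture`.
#' @export
posture_sweep_fixture <- function(oils = c(1000, 5000),
                                  fills = seq(0.80, 1.00, by = 0.05),
                                  postures = c("standing", "tilt45",
                                               "supine")) {
  out <- expand.grid(oil_mPas = oils, fill = fills, posture = postures,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$posture, out$fill, out$oil_mPas), , drop = FALSE]
  rownames(out) <- NULL
  out
}
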