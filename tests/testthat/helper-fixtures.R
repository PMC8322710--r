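# Shared coarse geometries: coarse enough to keep the suite fast, fine enough
# for the stated tolerances. Built once per test run.
coarse_sphere <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- segment_regions(
      build_chamber_mesh(lens_radius = NA, resolution = 1.6))
    g
  }
})

coarse_chamber <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- segment_regions(build_chamber_mesh(resolution = 1.6))
    g
  }
})

medium_sphere <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- segment_regions(
      build_chamber_mesh(lens_radius = NA, resolution = 0.8))
    g
  }
})

fine_sphere <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- segment_regions(
      build_chamber_mesh(lens_radius = NA, resolution = 0.4))
    g
  }
})

medium_chamber <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- segment_regions(build_chamber_mesh(resolution = 0.8))
    g
  }
})

# closed-form volume of the intersection of two spheres (radius R and r,
# centre distance d), the "lens" deducted from the chamber
two_sphere_intersection_volume <- function(R, r, d) {
  pi * (R + r - d)^2 *
    (d^2 + 2 * d * r - 3 * r^2 + 2 * d * R + 6 * r * R - 3 * R^2) / (12 * d)
}

# independent cubic-root oracle for flat-interface coverage (polynomial roots,
# not the package's uniroot path)
coverage_from_cubic <- function(fill) {
  r <- polyroot(c(-4 * fill, 0, 3, -1))
  x <- Re(r[abs(Im(r)) < 1e-9])
  x <- x[x > 0 & x < 2][1]
  x / 2
}
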