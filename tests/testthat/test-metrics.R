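test_that("all five metrics match the separable fixture closed forms", {
  g <- coarse_sphere()
  fx <- separable_traction_fixture(g, seed = 11)
  ser <- fx$series
  for (rg in c("retina", "wall")) {
    expect_equal(imss(ser, g, rg), fx$expected[[rg]]$imss, tolerance = 1e-12)
    expect_equal(arss(ser, g, rg), fx$expected[[rg]]$arss, tolerance = 1e-12)
    expect_equal(imsr(ser, g, rg), fx$expected[[rg]]$imsr, tolerance = 1e-12)
  }
  expect_equal(pmss(ser), fx$expected$pmss, tolerance = 1e-12)
  expect_equal(vass(ser, c(0, 1, 0)), fx$expected$vass, tolerance = 1e-12)
})

test_that("imss of a union is the max of the parts; arss <= imss", {
  g <- coarse_sphere()
  fx <- separable_traction_fixture(g, seed = 3)
  ser <- fx$series
  parts <- pmax(pmax(imss(ser, g, "macula"), imss(ser, g, "postequatorial")),
                imss(ser, g, "preequatorial"))
  expect_equal(imss(ser, g, "retina"), parts, tolerance = 1e-12)
  expect_true(all(arss(ser, g, "retina") <= imss(ser, g, "retina") + 1e-12))
})

test_that("pmss is invariant under time reordering; single sample works", {
  g <- coarse_sphere()
  fx <- separable_traction_fixture(g, seed = 5)
  ser <- fx$series
  perm <- sample(length(ser$times))
  ser2 <- ser
  ser2$magnitude <- ser$magnitude[, perm]
  ser2$times <- ser$times
  expect_equal(pmss(ser2), pmss(ser))
  ser1 <- ser
  ser1$times <- ser$times[1]
  ser1$magnitude <- ser$magnitude[, 1, drop = FALSE]
  expect_equal(pmss(ser1), abs(ser$magnitude[, 1]))
})

test_that("vass handles the documented simple cases", {
  g <- coarse_sphere()
  n <- nrow(g$vertices)
  base <- separable_traction_fixture(g, seed = 2)$series
  ## purely horizontal tractions: zero vertical mean
  flat <- base
  flat$dir <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  expect_equal(vass(flat, c(0, 1, 0)), rep(0, n))
  ## constant +2 Pa vertical traction
  up <- base
  up$dir <- matrix(rep(c(0, 1, 0), each = n), n, 3)
  up$magnitude <- matrix(2, n, length(base$times))
  expect_equal(vass(up, c(0, 1, 0)), rep(2, n))
  ## antisymmetric-in-time vertical traction cancels
  anti <- up
  anti$magnitude <- outer(rep(2, n), c(seq(-1, 1, length.out =
                                             length(base$times))))
  expect_equal(vass(anti, c(0, 1, 0)), rep(0, n), tolerance = 1e-12)
})

test_that("shear-rate convention and viscosity scaling", {
  g <- coarse_sphere()
  fx <- separable_traction_fixture(g, seed = 9, viscosity = 1)
  ser1 <- fx$series
  ser5 <- ser1
  ser5$viscosity <- rep(5, nrow(g$vertices))
  expect_equal(imsr(ser1, g, "retina"), imss(ser1, g, "retina"))
  expect_equal(imsr(ser1, g, "retina") / imsr(ser5, g, "retina"),
               rep(5, length(ser1$times)),
               tolerance = 1e-12)
  expect_equal(imsr(ser1, g, "retina", rate_convention_factor = 2),
               imss(ser1, g, "retina") / 2)
  ser0 <- ser1
  ser0$viscosity <- rep(0, nrow(g$vertices))
  expect_error(imsr(ser0, g, "retina"), "viscosity")
})

test_that("empty regions error and masks partition the wall", {
  g <- coarse_sphere()   # no lens -> empty lens region
  fx <- separable_traction_fixture(g, seed = 1)
  expect_error(imss(fx$series, g, "lens"), "empty region")
  m <- oculotamp:::region_vertex_mask(g, "retina") +
    oculotamp:::region_vertex_mask(g, "ora")
  expect_true(all(m == 1))   # retina + ora partition the lens-free wall
})

test_that("vertex areas sum to the mesh area", {
  g <- coarse_chamber()
  expect_equal(sum(vertex_areas(g)), mesh_area(g), tolerance = 1e-12)
})

test_that("dominant-maxima counter identifies constructed bimodality", {
  tt <- seq(0, 0.274, by = 1e-3)
  two <- exp(-((tt - 0.03) / 0.01)^2) + 0.7 * exp(-((tt - 0.14) / 0.01)^2)
  one <- exp(-((tt - 0.1) / 0.03)^2)
  expect_identical(count_dominant_maxima(two), 2L)
  expect_identical(count_dominant_maxima(one), 1L)
  expect_identical(count_dominant_maxima(rep(0, 10)), 0L)
})
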