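test_that("wall velocity is omega times axis distance, tangential", {
  g <- coarse_sphere()
  w <- saccade_wave()
  times <- seq(0, 2 * w$duration, by = 1e-3)
  wv <- wall_velocity_series(g, w, times)
  expect_equal(wv$U[, 1], rep(0, nrow(g$vertices)))      # omega(0) = 0
  ## equatorial vertex at maximal axis distance at peak omega
  i <- which.max(wv$d_m)
  pk <- saccade_peak_velocity(w)
  expect_equal(max(wv$U[i, ]), pk$omega_peak * pi / 180 * wv$d_m[i],
               tolerance = 1e-3)
  expect_equal(max(wv$U), 547 * pi / 180 * 0.012, tolerance = 0.01)
  ## vertices on the axis do not move
  on_axis <- wv$d_m < 1e-4
  if (any(on_axis)) expect_true(all(abs(wv$U[on_axis, ]) < 1e-12))
  ## direction tangential to the sphere and orthogonal to the axis
  dd <- rowSums(wv$dir * g$vertices)
  expect_lt(max(abs(dd[!on_axis])), 1e-9)
  expect_lt(max(abs(wv$dir %*% w$rotation_axis)), 1e-12)
})

test_that("Stokes stress reproduces the step (Rayleigh) closed form", {
  times <- seq(0, 0.1, by = 1e-3)
  U0 <- 0.1
  U <- c(0, rep(U0, length(times) - 1))
  tau <- stokes_wall_stress(U, times, mu = 1, rho = 980)
  oracle <- U0 * sqrt(980 * 1 / (pi * 0.1))
  expect_equal(tau[length(tau)], oracle, tolerance = 0.01)
  expect_equal(oracle, 5.59, tolerance = 0.01)
  expect_identical(stokes_wall_stress(rep(0, length(times)), times, 1, 980),
                   rep(0, length(times)))
})

test_that("Stokes stress reproduces the oscillating-plate closed form", {
  om <- 2 * pi * 50
  times <- seq(0, 0.4, by = 1e-5)
  U0 <- 0.1
  tau <- stokes_wall_stress(U0 * sin(om * times), times, mu = 0.01,
                            rho = 1000)
  late <- times > 0.3
  expect_equal(max(abs(tau[late])), U0 * sqrt(1000 * 0.01 * om),
               tolerance = 0.01)
  ## 45 degree phase lead of stress over velocity
  i <- which(late)[which.max(tau[late])]
  expect_equal(sin(om * times[i]), sin(pi / 4), tolerance = 0.05)
})

test_that("non-uniform grids are rejected or resampled", {
  times <- c(0, 0.001, 0.003, 0.004)
  expect_error(stokes_wall_stress(c(0, 1, 1, 1), times, 1, 1000), "uniform")
  out <- stokes_wall_stress(c(0, 1, 1, 1), times, 1, 1000,
                            on_nonuniform = "resample")
  expect_length(out, 4)
})

test_that("convolution converges: dt and dt/2 peaks differ by < 1%", {
  w <- saccade_wave()
  om <- function(dt) saccade_omega(w, seq(0, 2 * w$duration, by = dt)) *
    pi / 180
  tau1 <- stokes_wall_stress(0.012 * om(1e-3), seq(0, 2 * w$duration, 1e-3),
                             mu = 1, rho = 980)
  tau2 <- stokes_wall_stress(0.012 * om(5e-4), seq(0, 2 * w$duration, 5e-4),
                             mu = 1, rho = 980)
  expect_equal(max(abs(tau1)), max(abs(tau2)), tolerance = 0.01)
})

test_that("saccadic traction is bimodal and scales as sqrt(rho mu)", {
  g <- coarse_chamber()
  w <- saccade_wave()
  st <- solve_flat_interface(g, 0.9, posture("standing"))
  s1 <- simulate_saccade_shear(g, st, fluid_pair(1000), w)
  s5 <- simulate_saccade_shear(g, st, fluid_pair(5000), w)
  ## pointwise viscosity ordering, everywhere and at all times
  expect_true(all(abs(s5$magnitude) >= abs(s1$magnitude) - 1e-12))
  ## the sqrt(5) ratio at oil-wetted vertices
  i <- which(st$wet & pmss(s1) > 0)[1]
  expect_equal(abs(s5$magnitude[i, -1]) / abs(s1$magnitude[i, -1]),
               rep(sqrt(5), ncol(s1$magnitude) - 1), tolerance = 1e-9)
  ## bimodal region maxima
  expect_identical(count_dominant_maxima(imss(s1, g, "retina")), 2L)
  expect_identical(count_dominant_maxima(imss(s5, g, "wall")), 2L)
  ## traction opposes the wall motion at the first sample after onset
  wv <- wall_velocity_series(g, w, s1$times)
  moving <- wv$U[, 3] > 0
  expect_true(all(s1$magnitude[moving, 3] < 0))
})

test_that("aqueous-assigned vertices carry negligible traction", {
  g <- coarse_chamber()
  w <- saccade_wave()
  st <- solve_flat_interface(g, 0.85, posture("standing"))
  ser <- simulate_saccade_shear(g, st, fluid_pair(1000), w)
  pm <- pmss(ser)
  expect_lt(max(pm[!st$wet]), 0.05 * max(pm[st$wet]))
})

test_that("simulation validates geometry/equilibrium consistency", {
  g <- coarse_chamber()
  g2 <- coarse_sphere()
  st <- solve_flat_interface(g, 0.9, posture("standing"))
  expect_error(simulate_saccade_shear(g2, st, fluid_pair(), saccade_wave()),
               "match")
})
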