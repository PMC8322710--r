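test_that("flat interface halves the sphere at 50% fill in any posture", {
  g <- coarse_sphere()
  for (p in c("standing", "tilt45", "supine")) {
    st <- solve_flat_interface(g, 0.5, posture(p))
    expect_equal(st$interface$h, 0, tolerance = 1e-6)
    cf <- contact_fractions(st, g)
    expect_equal(cf$fraction[cf$region == "wall"], 0.5, tolerance = 1e-3)
  }
})

test_that("flat coverage matches the cubic-root oracle at 90% fill", {
  g <- medium_sphere()
  st <- solve_flat_interface(g, 0.9, posture("supine"))
  cf <- contact_fractions(st, g)
  expect_equal(cf$fraction[cf$region == "wall"], coverage_from_cubic(0.9),
               tolerance = 1e-3)
  expect_equal(st$fill_achieved, 0.9, tolerance = 1e-4)
})

test_that("full fill wets everything and fill is validated", {
  g <- coarse_sphere()
  st <- solve_flat_interface(g, 1, posture("standing"))
  expect_true(all(st$wet))
  cf <- contact_fractions(st, g)
  expect_true(all(cf$fraction[!is.na(cf$fraction)] == 1))
  expect_error(solve_flat_interface(g, 0, posture("standing")), "fill")
  expect_error(solve_flat_interface(g, 1.2, posture("standing")), "fill")
})

test_that("capillary solution reduces to the flat one as sigma -> 0", {
  g <- coarse_sphere()
  fl0 <- fluid_pair(interfacial_tension = 1e-9)
  for (p in c("standing", "supine")) {
    stc <- solve_capillary_interface(g, 0.9, posture(p), fl0)
    stf <- solve_flat_interface(g, 0.9, posture(p))
    cfc <- contact_fractions(stc, g)
    cff <- contact_fractions(stf, g)
    ok <- !is.na(cfc$fraction)
    expect_lt(max(abs(cfc$fraction[ok] - cff$fraction[ok])), 0.01)
  }
})

test_that("supine capillary coverage tracks the axisymmetric oracle", {
  g <- medium_sphere()
  ## at matched densities (zero Bond number) the energy minimum is the
  ## contact-angle cap, which is exactly what the closed form describes
  fl0 <- fluid_pair(oil_density = 999.99)
  st0 <- solve_capillary_interface(g, 0.9, posture("supine"), fl0)
  cf0 <- contact_fractions(st0, g)
  expect_equal(cf0$fraction[cf0$region == "wall"],
               analytic_supine_coverage(0.9, contact_angle = 16.2),
               tolerance = 0.015)
  ## with the physical density difference gravity tilts the solution towards
  ## the flat member: the gap to the zero-Bond oracle is positive and shrinks
  ## as fill grows (less aqueous, less gravitational energy at stake)
  fl <- fluid_pair()
  gaps <- vapply(c(0.8, 0.9), function(f) {
    st <- solve_capillary_interface(g, f, posture("supine"), fl)
    cf <- contact_fractions(st, g)
    cf$fraction[cf$region == "wall"] -
      analytic_supine_coverage(f, contact_angle = 16.2)
  }, 0)
  expect_true(all(gaps >= 0))
  expect_lt(gaps[2], gaps[1])
})

test_that("analytic supine coverage has the documented limits", {
  expect_equal(analytic_supine_coverage(0.5, mode = "flat"), 0.5,
               tolerance = 1e-9)
  expect_equal(analytic_supine_coverage(0.9, mode = "flat"),
               coverage_from_cubic(0.9), tolerance = 1e-9)
  expect_equal(analytic_supine_coverage(0.8, mode = "flat"),
               coverage_from_cubic(0.8), tolerance = 1e-9)
  ## wetting (small angle through the aqueous) always lowers coverage
  for (f in c(0.8, 0.85, 0.9, 0.95))
    expect_lt(analytic_supine_coverage(f, contact_angle = 16.2),
              analytic_supine_coverage(f, mode = "flat"))
  ## coverage grows with the contact angle (weaker aqueous wetting)
  expect_lt(analytic_supine_coverage(0.9, contact_angle = 16.2),
            analytic_supine_coverage(0.9, contact_angle = 35))
  ## the capillary cap degenerates to the flat plane when the contact angle
  ## equals the flat rim colatitude (interface meets the wall untilted)
  flat_cov <- analytic_supine_coverage(0.9, mode = "flat")
  beta_flat <- acos(2 * flat_cov - 1) * 180 / pi
  expect_equal(analytic_supine_coverage(0.9, contact_angle = beta_flat),
               flat_cov, tolerance = 1e-4)
})

test_that("contact fractions are viscosity-independent", {
  g <- coarse_sphere()
  st1 <- solve_capillary_interface(g, 0.85, posture("tilt45"),
                                   fluid_pair(1000))
  st2 <- solve_capillary_interface(g, 0.85, posture("tilt45"),
                                   fluid_pair(5000))
  expect_equal(contact_fractions(st1, g)$fraction,
               contact_fractions(st2, g)$fraction)
})

test_that("contact fractions are monotone in fill", {
  g <- coarse_chamber()
  fl <- fluid_pair()
  for (p in c("standing", "supine")) {
    prev <- NULL
    for (f in c(0.8, 0.85, 0.9, 0.95)) {
      st <- solve_capillary_interface(g, f, posture(p), fl)
      cur <- contact_fractions(st, g)$fraction
      if (!is.null(prev)) {
        ok <- !is.na(cur) & !is.na(prev)
        expect_true(all(cur[ok] - prev[ok] > -0.005))
      }
      prev <- cur
    }
  }
})

test_that("superior retina keeps better contact when upright or tilted", {
  g <- coarse_chamber()
  fl <- fluid_pair()
  for (p in c("standing", "tilt45")) for (f in c(0.8, 0.9)) {
    st <- solve_capillary_interface(g, f, posture(p), fl)
    cf <- contact_fractions(st, g)
    expect_gte(contact_value(cf, "retina", "superior") + 1e-9,
               contact_value(cf, "retina", "inferior"))
  }
})

test_that("supine posture leaves the macula out of contact up to 95% fill", {
  g <- coarse_chamber()
  fl <- fluid_pair()
  for (f in c(0.9, 0.95)) {
    st <- solve_capillary_interface(g, f, posture("supine"), fl)
    cf <- contact_fractions(st, g)
    expect_equal(contact_value(cf, "macula"), 0, tolerance = 1e-6)
  }
})

test_that("the oil pocket holds the anti-gravity pole", {
  g <- coarse_chamber()
  fl <- fluid_pair()
  for (p in c("standing", "tilt45", "supine")) {
    up <- -posture(p)$gravity
    st <- solve_capillary_interface(g, 0.85, posture(p), fl)
    zeta <- c(g$vertices %*% up)
    expect_true(st$wet[which.max(zeta)])
    expect_false(st$wet[which.min(zeta)])
    expect_equal(st$fill_achieved, 0.85, tolerance = 1e-3)
  }
})

test_that("fluid_pair validates its invariants", {
  expect_error(fluid_pair(oil_density = 1100))
  expect_error(fluid_pair(static_contact_angle = 25)) # above advancing
  fl <- fluid_pair(5000)
  expect_equal(fl$oil_viscosity, 5000)
  expect_lte(fl$receding_contact_angle, fl$static_contact_angle)
})
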