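test_that("lens-free chamber reproduces sphere volume and area", {
  g <- coarse_sphere()
  expect_equal(mesh_volume(g), 4 / 3 * pi * 12^3, tolerance = 0.01)
  expect_equal(mesh_area(g), 4 * pi * 12^2, tolerance = 0.01)
})

test_that("lens indentation removes the two-sphere intersection volume", {
  g <- medium_chamber()
  oracle <- 4 / 3 * pi * 12^3 - two_sphere_intersection_volume(12, 5.5, 13)
  expect_equal(mesh_volume(g), oracle, tolerance = 0.01)
})

test_that("every vertex lies on the eye sphere or the lens sphere", {
  g <- coarse_chamber()
  r_eye <- sqrt(rowSums(g$vertices^2))
  lens_c <- g$lens_center_offset * g$anterior_axis
  r_lens <- sqrt(rowSums((g$vertices -
                            matrix(lens_c, nrow(g$vertices), 3,
                                   byrow = TRUE))^2))
  on_eye <- abs(r_eye - g$eye_radius) < 1e-9
  on_lens <- abs(r_lens - g$lens_radius) < 1e-9
  expect_true(all(on_eye | on_lens))
  expect_true(all(xor(on_eye[g$on_lens], on_lens[g$on_lens]) |
                    on_lens[g$on_lens]))
})

test_that("invalid lens configurations are rejected", {
  expect_error(build_chamber_mesh(lens_radius = 0.5, lens_center_offset = 30),
               "intersect")
  expect_error(build_chamber_mesh(lens_radius = 40, lens_center_offset = 1),
               "intersect")
})

test_that("mesh is watertight: outward normal areas sum to zero", {
  for (g in list(coarse_sphere(), coarse_chamber())) {
    p1 <- g$vertices[g$triangles[, 1], ]
    p2 <- g$vertices[g$triangles[, 2], ]
    p3 <- g$vertices[g$triangles[, 3], ]
    n <- cbind((p2 - p1)[, 2] * (p3 - p1)[, 3] - (p2 - p1)[, 3] * (p3 - p1)[, 2],
               (p2 - p1)[, 3] * (p3 - p1)[, 1] - (p2 - p1)[, 1] * (p3 - p1)[, 3],
               (p2 - p1)[, 1] * (p3 - p1)[, 2] - (p2 - p1)[, 2] * (p3 - p1)[, 1])
    expect_lt(max(abs(colSums(n))), 1e-9 * sum(triangle_areas(g)))
    ## and every edge is shared by exactly two triangles
    e <- rbind(g$triangles[, 1:2], g$triangles[, 2:3], g$triangles[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_true(all(table(key) == 2))
  }
})

test_that("segmentation follows the polar-angle definitions", {
  g <- medium_sphere()
  ang <- acos(pmin(1, pmax(-1, g$vertices[, 3] / 12))) * 180 / pi
  expect_true(all(g$vertex_region[ang >= 160.001] == "macula"))
  expect_true(all(g$vertex_region[ang > 90.001 & ang < 159.999] ==
                    "postequatorial"))
  expect_true(all(g$vertex_region[ang > 40.001 & ang < 89.999] ==
                    "preequatorial"))
  expect_true(all(g$vertex_region[ang < 39.999] == "ora"))
  expect_true(all(g$vertex_hemisphere[g$vertices[, 2] > 0] == "superior"))
  expect_true(all(g$vertex_hemisphere[g$vertices[, 2] < 0] == "inferior"))
  ## lens vertices are exactly the indented ones
  gc <- coarse_chamber()
  expect_identical(as.character(gc$vertex_region) == "lens",
                   unname(gc$on_lens))
})

test_that("region areas match spherical-zone closed forms on the sphere", {
  g <- medium_sphere()
  ra <- region_areas(g)
  pick <- function(region, hemi = "both")
    ra$area_mm2[ra$region == region & ra$hemisphere == hemi]
  R <- 12
  zone <- function(a1, a2)   # polar angles from anterior pole, degrees
    2 * pi * R^2 * (cos(a1 * pi / 180) - cos(a2 * pi / 180))
  expect_equal(pick("macula"), zone(160, 180), tolerance = 0.015)
  expect_equal(pick("postequatorial"), zone(90, 160), tolerance = 0.01)
  expect_equal(pick("preequatorial"), zone(40, 90), tolerance = 0.01)
  expect_equal(pick("ora"), zone(0, 40), tolerance = 0.01)
  ## conservation and hemisphere symmetry
  base <- ra[ra$hemisphere != "both" & ra$region != "retina", ]
  expect_equal(sum(base$area_mm2), mesh_area(g), tolerance = 1e-12)
  sup <- ra$area_mm2[ra$hemisphere == "superior"]
  inf <- ra$area_mm2[ra$hemisphere == "inferior"]
  expect_equal(sup, inf, tolerance = 0.01)
})

test_that("region areas converge: doubling resolution changes them < 0.5%", {
  ra1 <- region_areas(medium_sphere())
  ra2 <- region_areas(fine_sphere())
  both1 <- ra1$area_mm2[ra1$hemisphere == "both"]
  both2 <- ra2$area_mm2[ra2$hemisphere == "both"]
  nz <- both2 > 0
  expect_true(all(abs(both1[nz] / both2[nz] - 1) < 0.005 |
                    abs(both1[nz] - both2[nz]) < 0.5))
})

test_that("segmentation is rotation-invariant about the anterior axis", {
  g <- coarse_sphere()
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  g2 <- g
  g2$vertices <- g$vertices %*% t(rot)
  g2 <- segment_regions(g2)
  ra <- region_areas(g)
  ra2 <- region_areas(g2)
  both <- ra$hemisphere == "both"
  expect_equal(ra2$area_mm2[both], ra$area_mm2[both], tolerance = 0.005)
})

test_that("mesh writers emit valid headers and round-trippable counts", {
  g <- coarse_chamber()
  vtk <- tempfile(fileext = ".vtk")
  ply <- tempfile(fileext = ".ply")
  write_vtk_polydata(g, vtk, point_data = list(wet = rep(1L, nrow(g$vertices))))
  write_ply(g, ply)
  lv <- readLines(vtk)
  expect_true(any(grepl(sprintf("^POINTS %d float", nrow(g$vertices)), lv)))
  expect_true(any(grepl(sprintf("^POLYGONS %d", nrow(g$triangles)), lv)))
  expect_true(any(grepl("SCALARS region int", lv)))
  expect_true(any(grepl("SCALARS wet int", lv)))
  lp <- readLines(ply)
  expect_identical(lp[1], "ply")
  expect_true(any(grepl(sprintf("element vertex %d", nrow(g$vertices)), lp)))
})
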