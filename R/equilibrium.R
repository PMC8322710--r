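#' Fluid property sets for tamponade and aqueous
#'
#' Defaults are the standard property set for polydimethylsiloxane (PDMS)
#' tamponades against aqueous: densities 980/1000 kg/m^3, interfacial tension
#' 0.044 N/m, static contact angle 16.2 deg with advancing/receding hysteresis
#' bounds 21.2/11.2 deg (the hysteresis angles are stored for reference; the
#' static solvers use the static angle only).
#'
#' @param oil_viscosity Oil dynamic viscosity in mPa.s (1000 or 5000 for the
#'   two commercial grades, but any positive value is accepted).
#' @param oil_density,aqueous_density Densities, kg/m^3.
#' @param aqueous_viscosity Aqueous dynamic viscosity, mPa.s.
#' @param interfacial_tension Oil-aqueous interfacial tension, N/m.
#' @param static_contact_angle,advancing_contact_angle,receding_contact_angle
#'   Contact angles at the oil-aqueous-wall line, degrees. See
#'   `angle_convention`.
#' @param angle_convention Phase through which the contact angles are
#'   measured: `"aqueous"` (default; a small angle means aqueous wets the
#'   wall, which reproduces the capillary rise of aqueous along the wall) or
#'   `"oil"`.
#' @return List of class `fluid_pair`.
#' @export
fluid_pair <- function(oil_viscosity = 1000,
                       oil_density = 980, aqueous_density = 1000,
                       aqueous_viscosity = 1,
                       interfacial_tension = 0.044,
                       static_contact_angle = 16.2,
                       advancing_contact_angle = 21.2,
                       receding_contact_angle = 11.2,
                       angle_convention = c("aqueous", "oil")) {
  stopifnot(oil_viscosity > 0, oil_density > 0, aqueous_density > 0,
            oil_density < aqueous_density,
            receding_contact_angle <= static_contact_angle,
            static_contact_angle <= advancing_contact_angle)
  structure(list(
    oil_viscosity = oil_viscosity, aqueous_viscosity = aqueous_viscosity,
    oil_density = oil_density, aqueous_density = aqueous_density,
    interfacial_tension = interfacial_tension,
    static_contact_angle = static_contact_angle,
    advancing_contact_angle = advancing_contact_angle,
    receding_contact_angle = receding_contact_angle,
    angle_convention = match.arg(angle_convention)
  ), class = "fluid_pair")
}

#' Patient posture as a gravity direction in the anatomical frame
#'
#' `standing`: gravity along minus the superior axis; `supine`: along minus
#' the anterior axis (patient on their back); `tilt45` (45 degree upward
#' gaze): the unit bisector of the two.
#'
#' @param name One of `"standing"`, `"tilt45"`, `"supine"`.
#' @return List of class `posture` with `name` and unit `gravity`.
#' @export
posture <- function(name = c("standing", "tilt45", "supine")) {
  name <- match.arg(name)
  sup <- c(0, 1, 0); ant <- c(0, 0, 1)
  g <- switch(name,
              standing = -sup,
              supine = -ant,
              tilt45 = -(sup + ant) / sqrt(2))
  structure(list(name = name, gravity = g / sqrt(sum(g^2))), class = "posture")
}

## ---------------------------------------------------------------------------
## Interface descriptions. `up` is the unit anti-gravity direction. Oil sits
## on the positive side of the signed function s(x):
##   plane:  s = x.up - h
##   sphere (oil outside the ball, aqueous cap at the bottom):  s = |x-c| - r
##   sphere (oil inside the ball, aqueous climbing the walls):  s = r - |x-c|
## with the ball centre c = z0 * up.

iface_plane <- function(up, h) list(type = "plane", up = up, h = h)

## Spherical interface: centre = base + z0*up, where `base` is the component
## of the chamber centroid perpendicular to gravity (the cap centre moves on
## the gravity line through the centroid).
iface_sphere <- function(up, z0, r, oil_inside, base = c(0, 0, 0)) {
  list(type = "sphere", up = up, z0 = z0, r = r, oil_inside = oil_inside,
       base = base, center = base + z0 * up)
}

iface_signed <- function(iface, pts) {
  if (iface$type == "none") return(rep(1, nrow(pts)))
  if (iface$type == "plane") return(c(pts %*% iface$up) - iface$h)
  w <- pts - matrix(iface$center, nrow(pts), 3, byrow = TRUE)
  d <- sqrt(rowSums(w^2)) - iface$r
  if (iface$oil_inside) -d else d
}

## Precomputed per-solve clip context.
clip_context <- function(geom) {
  p <- triangle_corners(geom)
  nraw <- cross3(p$p2 - p$p1, p$p3 - p$p1)
  a2 <- sqrt(rowSums(nraw^2))
  ctx <- list(geom = geom, p1 = p$p1, p2 = p$p2, p3 = p$p3,
              nhat = nraw / a2, area = a2 / 2,
              total_volume = mesh_volume(geom))
  ctx$centroid <- chamber_centroid(ctx)
  ctx
}

## Centroid of the enclosed chamber via the divergence theorem; the quadratic
## flux integrand is integrated exactly with the degree-2 midedge rule.
chamber_centroid <- function(ctx) {
  mids <- list((ctx$p1 + ctx$p2) / 2, (ctx$p2 + ctx$p3) / 2,
               (ctx$p1 + ctx$p3) / 2)
  m <- c(0, 0, 0)
  for (q in mids)
    m <- m + colSums((q^2 / 2) * (ctx$nhat * ctx$area / 3))
  m / ctx$total_volume
}

## Clip every triangle against s(x) = 0 (linear in the per-vertex values) and
## return the oil-side (s > 0) decomposition as sub-triangles:
## list(parent, q1, q2, q3) plus the per-parent oil-side area.
clip_oil_side <- function(ctx, s) {
  tri <- ctx$geom$triangles
  m <- nrow(tri)
  sv <- matrix(s[tri], ncol = 3)
  pos <- sv > 0
  np <- rowSums(pos)

  full <- which(np == 3L)
  mix1 <- which(np == 1L)
  mix2 <- which(np == 2L)

  lerp <- function(pa, pb, sa, sb) pa + (pb - pa) * (sa / (sa - sb))

  parent <- full
  q1 <- ctx$p1[full, , drop = FALSE]
  q2 <- ctx$p2[full, , drop = FALSE]
  q3 <- ctx$p3[full, , drop = FALSE]

  corner <- function(rows, k) {
    ## coordinates of local corner k (vector per row)
    cbind(ctx$p1[rows, 1] * (k == 1) + ctx$p2[rows, 1] * (k == 2) + ctx$p3[rows, 1] * (k == 3),
          ctx$p1[rows, 2] * (k == 1) + ctx$p2[rows, 2] * (k == 2) + ctx$p3[rows, 2] * (k == 3),
          ctx$p1[rows, 3] * (k == 1) + ctx$p2[rows, 3] * (k == 2) + ctx$p3[rows, 3] * (k == 3))
  }

  if (length(mix1)) {
    k <- max.col(pos[mix1, , drop = FALSE], ties.method = "first")
    kb <- k %% 3L + 1L
    kc <- kb %% 3L + 1L
    va <- corner(mix1, k); vb <- corner(mix1, kb); vc <- corner(mix1, kc)
    sa <- sv[cbind(mix1, k)]; sb <- sv[cbind(mix1, kb)]; sc <- sv[cbind(mix1, kc)]
    pab <- lerp(va, vb, sa, sb)
    pac <- lerp(va, vc, sa, sc)
    parent <- c(parent, mix1)
    q1 <- rbind(q1, va); q2 <- rbind(q2, pab); q3 <- rbind(q3, pac)
  }
  if (length(mix2)) {
    k <- max.col(!pos[mix2, , drop = FALSE], ties.method = "first")  # negative corner
    ka <- k %% 3L + 1L
    kb <- ka %% 3L + 1L
    vc <- corner(mix2, k); va <- corner(mix2, ka); vb <- corner(mix2, kb)
    sc <- sv[cbind(mix2, k)]; sa <- sv[cbind(mix2, ka)]; sb <- sv[cbind(mix2, kb)]
    pbc <- lerp(vb, vc, sb, sc)
    pac <- lerp(va, vc, sa, sc)
    parent <- c(parent, mix2, mix2)
    q1 <- rbind(q1, va, va); q2 <- rbind(q2, vb, pbc); q3 <- rbind(q3, pbc, pac)
  }

  sub_area <- sqrt(rowSums(cross3(q2 - q1, q3 - q1)^2)) / 2
  tri_oil_area <- numeric(m)
  if (length(parent)) {
    sums <- rowsum(sub_area, parent)
    tri_oil_area[as.integer(rownames(sums))] <- sums[, 1]
  }
  list(parent = parent, q1 = q1, q2 = q2, q3 = q3, sub_area = sub_area,
       tri_oil_area = tri_oil_area)
}

## Oil volume, anti-gravity first moment (integral of zeta dV, zeta = x.up)
## and oil-wetted wall area. For the plane the divergence-theorem fields are
## chosen to vanish on the interface, so the wall mesh alone suffices. For a
## spherical interface smooth fields (w/3 and w_u w/4, w = x - centre) are
## integrated over the clipped wall mesh and the flux through the open
## interface patch is added from the semi-analytic patch integrals (on the
## patch the outward normal is +-w/r, so the flux reduces to the patch area
## and its first polar moment).
oil_integrals <- function(ctx, iface, want_moment = FALSE,
                          want_patch = FALSE) {
  geom <- ctx$geom
  s <- iface_signed(iface, geom$vertices)
  cl <- clip_oil_side(ctx, s)
  patch_area <- NA_real_
  if (!length(cl$parent)) {
    return(list(volume = 0, moment = 0, wet_area = 0, s = s,
                tri_oil_area = cl$tri_oil_area, patch_area = 0))
  }
  cen <- (cl$q1 + cl$q2 + cl$q3) / 3
  nh <- ctx$nhat[cl$parent, , drop = FALSE]
  up <- iface$up
  ## edge midpoints: the degree-2 rule is exact for the quadratic moment
  ## integrands (the volume integrands are linear, the centroid suffices)
  mids <- list((cl$q1 + cl$q2) / 2, (cl$q2 + cl$q3) / 2, (cl$q1 + cl$q3) / 2)
  if (iface$type == "plane") {
    zc <- c(cen %*% up)
    ndotu <- c(nh %*% up)
    vol <- sum((zc - iface$h) * ndotu * cl$sub_area)
    mom <- 0
    if (want_moment) {
      for (q in mids) {
        zq <- c(q %*% up)
        mom <- mom + sum(((zq^2 - iface$h^2) / 2) * ndotu * cl$sub_area) / 3
      }
    }
    if (want_patch)
      patch_area <- interface_patch_integrals(iface, geom)$area
  } else {
    ## Fields are gauged to the sphere pole nearest the chamber (qp), so the
    ## integrands stay of chamber size however large the cap radius is; the
    ## interface-patch fluxes then involve (1 -+ cos psi) factors that vanish
    ## towards the pole, keeping the decomposition well conditioned.
    r <- iface$r
    cc <- iface$center
    sgn <- if (iface$oil_inside) 1 else -1    # patch normal = sgn * w / r
    sigp <- if (iface$oil_inside) -1 else 1   # pole facing the chamber
    qp <- cc + sigp * r * up
    qu <- sum(qp * up)
    pt <- interface_patch_integrals(iface, geom)
    patch_area <- pt$area
    xi <- cen - matrix(qp, nrow(cen), 3, byrow = TRUE)
    vol <- sum(rowSums(xi * nh) * cl$sub_area) / 3 +
      sgn * r * (pt$area - sigp * pt$mpsi) / 3
    mom <- 0
    if (want_moment) {
      for (q in mids) {
        xq <- q - matrix(qp, nrow(q), 3, byrow = TRUE)
        mom <- mom + sum((c(xq %*% up) / 4 + qu / 3) * rowSums(xq * nh) *
                           cl$sub_area) / 3
      }
      mom <- mom + sgn * (r^2 * (2 * pt$mpsi - sigp * (pt$area + pt$m2psi)) / 4 +
                            qu * r * (pt$area - sigp * pt$mpsi) / 3)
    }
  }
  list(volume = vol, moment = mom, wet_area = sum(cl$sub_area), s = s,
       tri_oil_area = cl$tri_oil_area, patch_area = patch_area)
}

## Integrals over the interface patch (the part of the plane/sphere inside
## the chamber), computed semi-analytically: for each azimuth about the
## interface axis the admissible radial/polar intervals against the analytic
## chamber (eye sphere minus lens sphere) are closed-form; the azimuthal
## integral is a periodic midpoint rule. Returns the patch area and, for
## spheres, the first polar moment mpsi = integral of cos(psi) dA (psi
## measured from the up-axis at the sphere centre), which carries the
## interface flux of the moment field.
interface_patch_integrals <- function(iface, geom, nphi = 240L) {
  ## effective radii absorb the facet volume deficit of the triangulated
  ## sphere, so the analytic patch rim sits on the mean polyhedral surface
  fac <- if (is.null(geom$facet_factor)) 1 else geom$facet_factor^(1 / 3)
  R <- geom$eye_radius * fac
  has_lens <- !is.na(geom$lens_radius)
  cl <- if (has_lens) geom$lens_center_offset * geom$anterior_axis else c(0, 0, 0)
  rl <- if (has_lens) geom$lens_radius * fac else 0
  up <- iface$up
  ## orthonormal basis perpendicular to up
  tmp <- if (abs(up[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- tmp - sum(tmp * up) * up; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(up[2] * e1[3] - up[3] * e1[2],
          up[3] * e1[1] - up[1] * e1[3],
          up[1] * e1[2] - up[2] * e1[1])
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  dphi <- 2 * pi / nphi

  if (iface$type == "plane") {
    h <- iface$h
    if (h^2 >= R^2) return(list(area = 0, mpsi = 0, m2psi = 0))
    smax <- sqrt(R^2 - h^2)
    area <- pi * smax^2
    if (has_lens) {
      ## x = h*up + s*e(phi); lens-violated where s^2 - 2 B s + C < 0
      B <- (sum(cl * e1)) * cos(phi) + (sum(cl * e2)) * sin(phi)
      C <- sum((h * up - cl)^2) - rl^2
      disc <- B^2 - C
      s1 <- ifelse(disc > 0, B - sqrt(pmax(disc, 0)), Inf)
      s2 <- ifelse(disc > 0, B + sqrt(pmax(disc, 0)), -Inf)
      lo <- pmax(s1, 0); hi <- pmin(s2, smax)
      cut <- ifelse(hi > lo, (hi^2 - lo^2) / 2, 0)
      area <- area - dphi * sum(cut)
    }
    return(list(area = area, mpsi = 0, m2psi = 0))
  }

  ## Sphere patch, centre possibly off the up-axis. Points on the interface
  ## sphere: x(psi, phi) = c + r cos(psi) u + r sin(psi) e(phi). Both chamber
  ## conditions reduce per azimuth to alpha + beta cos(psi) + gamma sin(psi)
  ## with a sign, solvable in closed form on psi in [0, pi].
  r <- iface$r; cc <- iface$center
  a_eye <- sum(cc^2) + r^2 - R^2
  b_eye <- 2 * r * sum(cc * up)
  g_eye <- c(2 * r * sum(cc * e1), 2 * r * sum(cc * e2))
  lens_matters <- FALSE
  if (has_lens) {
    mvec <- cc - cl
    dcl <- sqrt(sum(mvec^2))
    if (dcl <= rl - r)                       # patch sphere inside the lens
      return(list(area = 0, mpsi = 0, m2psi = 0))
    lens_matters <- dcl < r + rl             # otherwise lens never touches
    a_len <- sum(mvec^2) + r^2 - rl^2
    b_len <- 2 * r * sum(mvec * up)
    g_len <- c(2 * r * sum(mvec * e1), 2 * r * sum(mvec * e2))
  }
  cphi <- cos(phi); sphi <- sin(phi)
  tot_a <- 0; tot_m <- 0; tot_m2 <- 0
  for (j in seq_len(nphi)) {
    iv <- trig_intervals(-a_eye, -b_eye,
                         -(g_eye[1] * cphi[j] + g_eye[2] * sphi[j]))
    if (lens_matters && nrow(iv))
      iv <- intersect_intervals(
        iv, trig_intervals(a_len, b_len,
                           g_len[1] * cphi[j] + g_len[2] * sphi[j]))
    if (nrow(iv)) {
      c1 <- cos(iv[, 1]); c2 <- cos(iv[, 2])
      tot_a <- tot_a + sum(c1 - c2)
      tot_m <- tot_m + sum(c1^2 - c2^2) / 2
      tot_m2 <- tot_m2 + sum(c1^3 - c2^3) / 3
    }
  }
  list(area = r^2 * dphi * tot_a, mpsi = r^2 * dphi * tot_m,
       m2psi = r^2 * dphi * tot_m2)
}

interface_patch_area <- function(iface, geom, nphi = 240L)
  interface_patch_integrals(iface, geom, nphi)$area

## {psi in [0, pi] : alpha + beta cos(psi) + gamma sin(psi) >= 0} as a small
## matrix of [lo, hi] intervals.
trig_intervals <- function(alpha, beta, gamma) {
  rho <- sqrt(beta^2 + gamma^2)
  none <- matrix(numeric(0), 0, 2)
  if (rho < 1e-12)
    return(if (alpha >= 0) matrix(c(0, pi), 1) else none)
  ratio <- -alpha / rho
  if (ratio <= -1) return(matrix(c(0, pi), 1))
  if (ratio >= 1) return(none)
  delta <- atan2(gamma, beta)
  D <- acos(ratio)
  iv <- NULL
  for (k in -1:1) {
    lo <- max(delta - D + 2 * pi * k, 0)
    hi <- min(delta + D + 2 * pi * k, pi)
    if (hi > lo) iv <- rbind(iv, c(lo, hi))
  }
  if (is.null(iv)) none else iv
}

intersect_intervals <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(numeric(0), 0, 2))
  out <- NULL
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
    ok <- hi > lo
    if (any(ok)) out <- rbind(out, cbind(lo[ok], hi[ok]))
  }
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

## Position the interface so the oil volume matches `target`. Returns the
## iface (with h or z0 set) or NULL when the family member cannot hold the
## required volume. `kind` is "plane", "oil_outside" or "oil_inside".
position_interface <- function(ctx, kind, up, target, r = NULL, tol = 1e-4,
                               base = c(0, 0, 0)) {
  geom <- ctx$geom
  R <- geom$eye_radius
  vol_of <- function(iface) oil_integrals(ctx, iface)$volume
  vtol <- tol * ctx$total_volume

  if (kind == "plane") {
    zeta <- c(geom$vertices %*% up)
    lo <- min(zeta) - 1e-6; hi <- max(zeta) + 1e-6
    f <- function(h) vol_of(iface_plane(up, h)) - target
    root <- stats::uniroot(f, c(lo, hi), tol = 1e-7 * R)$root
    return(iface_plane(up, root))
  }

  oil_inside <- kind == "oil_inside"
  zr <- R + r
  grid <- seq(-zr, zr, length.out = 25L)
  if (oil_inside) grid <- rev(grid)   # scan from the top down
  f <- function(z0) vol_of(iface_sphere(up, z0, r, oil_inside, base)) - target
  fv <- vapply(grid, f, 0)
  ## oil_outside: f starts positive (ball outside, all oil), first crossing to
  ## negative as the ball bites in from below. oil_inside: scanning down from
  ## the top f starts negative (empty ball) and crosses positive.
  want <- if (oil_inside) fv > 0 else fv < 0
  i <- which(want)[1]
  if (is.na(i) || i == 1L) return(NULL)
  root <- stats::uniroot(f, sort(c(grid[i - 1L], grid[i])), tol = 1e-7 * R)$root
  iface <- iface_sphere(up, root, r, oil_inside, base)
  if (abs(vol_of(iface) - target) > 10 * vtol) return(NULL)
  iface
}

## Total configurational energy of a positioned interface, joules.
## sigma * (A_int + q * A_wet) + (rho_oil - rho_aq) * g * integral(zeta dV_oil)
## with q = +cos(theta) when the contact angle is measured through the
## aqueous phase and -cos(theta) when through the oil.
interface_energy <- function(ctx, iface, fluids) {
  ints <- oil_integrals(ctx, iface, want_moment = TRUE, want_patch = TRUE)
  a_int <- ints$patch_area
  th <- fluids$static_contact_angle * pi / 180
  q <- if (fluids$angle_convention == "aqueous") cos(th) else -cos(th)
  sigma <- fluids$interfacial_tension
  e <- sigma * (a_int + q * ints$wet_area) * 1e-6 +
    (fluids$oil_density - fluids$aqueous_density) * 9.81 * ints$moment * 1e-12
  list(energy = e, integrals = ints, interface_area = a_int)
}

make_equilibrium_state <- function(geom, iface, s, fill, fill_achieved,
                                   posture, mode, energy = NA_real_,
                                   diagnostics = NULL) {
  structure(list(
    geom_signature = geom_signature(geom),
    interface = iface, s = s, wet = s > 0,
    fill = fill, fill_achieved = fill_achieved,
    posture = posture, mode = mode, energy = energy,
    diagnostics = diagnostics
  ), class = "equilibrium_state")
}

#' Static equilibrium with a flat (gravity-normal) interface
#'
#' Positions a plane normal to gravity by root-finding so that the oil volume
#' above it matches `fill` times the chamber volume. This is the zero
#' interfacial-tension limit of [solve_capillary_interface()].
#'
#' @param geom A segmented [build_chamber_mesh()] geometry.
#' @param fill Oil volume fraction of the chamber, in (0, 1].
#' @param posture A [posture()].
#' @param tol Volume-fraction tolerance of the positioning.
#' @return An `equilibrium_state`: interface description, per-vertex signed
#'   oil-side value `s` and `wet` flags, achieved fill.
#' @export
solve_flat_interface <- function(geom, fill, posture, tol = 1e-4) {
  check_fill(fill)
  ctx <- clip_context(geom)
  up <- -posture$gravity
  if (fill >= 1) {
    return(make_equilibrium_state(
      geom, list(type = "none", up = up), rep(1, nrow(geom$vertices)),
      fill, 1, posture, "flat"))
  }
  target <- fill * ctx$total_volume
  iface <- position_interface(ctx, "plane", up, target, tol = tol)
  ints <- oil_integrals(ctx, iface)
  make_equilibrium_state(geom, iface, ints$s, fill,
                         ints$volume / ctx$total_volume, posture, "flat")
}

check_fill <- function(fill) {
  if (!is.numeric(fill) || length(fill) != 1 || fill <= 0 || fill > 1)
    stop("fill must be a single value in (0, 1]", call. = FALSE)
}

#' Static oil-aqueous equilibrium with interfacial tension
#'
#' The interface is chosen from the family of planes and spherical caps whose
#' centre lies on the gravity line: the family is exact in both the
#' zero-gravity limit (spherical cap meeting the wall at the contact angle)
#' and the zero-tension limit (flat interface), and the Bond number of the
#' silicone-oil-filled eye is of order one, so the energy-minimizing member
#' interpolates between the two. For each candidate curvature the interface
#' is positioned to conserve the oil volume, and the total energy
#' (interfacial + wall-wetting + gravitational) is minimized over curvature
#' by a grid scan refined with golden-section search.
#'
#' @inheritParams solve_flat_interface
#' @param fluids A [fluid_pair()]; only densities, interfacial tension and
#'   the static contact angle enter (equilibrium is viscosity-independent).
#' @param kappa_max Largest interface curvature explored, 1/mm (smallest cap
#'   radius = `1/kappa_max`).
#' @param n_kappa Number of curvature grid points (odd, so the flat member is
#'   always a candidate).
#' @return An `equilibrium_state` with energy diagnostics.
#' @export
solve_capillary_interface <- function(geom, fill, posture, fluids,
                                      tol = 1e-4, kappa_max = 0.4,
                                      n_kappa = 13L) {
  check_fill(fill)
  stopifnot(inherits(fluids, "fluid_pair"))
  ctx <- clip_context(geom)
  up <- -posture$gravity
  if (fill >= 1) {
    return(make_equilibrium_state(
      geom, list(type = "none", up = up), rep(1, nrow(geom$vertices)),
      fill, 1, posture, "capillary"))
  }
  target <- fill * ctx$total_volume
  zeta <- c(geom$vertices %*% up)
  i_top <- which.max(zeta); i_bot <- which.min(zeta)
  ## thinnest aqueous layer the surface mesh can represent: interfaces
  ## hugging the wall closer than ~1.5 edge lengths are sub-resolution
  ## films, not macroscopic menisci, and are excluded from the family
  edge <- sqrt(4 * mean(ctx$area) / sqrt(3))
  min_depth <- 1.5 * edge

  base <- ctx$centroid - sum(ctx$centroid * up) * up
  ## caps flatter than r ~ 1 m over a 24 mm chamber are numerically and
  ## physically indistinguishable from the plane member
  make_iface <- function(kappa) {
    if (abs(kappa) < 1e-3)
      position_interface(ctx, "plane", up, target, tol = tol)
    else
      position_interface(ctx,
                         if (kappa < 0) "oil_inside" else "oil_outside",
                         up, target, r = 1 / abs(kappa), tol = tol,
                         base = base)
  }
  energy_of <- function(kappa) {
    iface <- make_iface(kappa)
    if (is.null(iface)) return(list(energy = Inf))
    if (iface$type == "sphere" && iface$oil_inside &&
        (iface$z0 - zeta[i_bot]) - iface$r < min_depth)
      return(list(energy = Inf))
    en <- interface_energy(ctx, iface, fluids)
    s <- en$integrals$s
    ## physical sanity: oil holds the anti-gravity extreme, aqueous the bottom
    if (s[i_top] <= 0 || s[i_bot] >= 0) return(list(energy = Inf))
    c(list(iface = iface), en)
  }

  if (n_kappa %% 2L == 0L) n_kappa <- n_kappa + 1L
  kappas <- seq(-kappa_max, kappa_max, length.out = n_kappa)
  evals <- lapply(kappas, energy_of)
  es <- vapply(evals, function(e) e$energy, 0)
  if (!any(is.finite(es)))
    stop("capillary solver failed: no admissible interface in the family",
         call. = FALSE)
  ib <- which.min(es)
  lo <- kappas[max(1L, ib - 1L)]; hi <- kappas[min(n_kappa, ib + 1L)]
  opt <- suppressWarnings(   # Inf marks infeasible family members
    stats::optimize(function(k) energy_of(k)$energy, c(lo, hi),
                    tol = kappa_max * 1e-3))
  best_kappa <- if (opt$objective < es[ib]) opt$minimum else kappas[ib]
  best <- energy_of(best_kappa)
  ints <- best$integrals
  make_equilibrium_state(
    geom, best$iface, ints$s, fill, ints$volume / ctx$total_volume,
    posture, "capillary", energy = best$energy,
    diagnostics = list(kappa = best_kappa, kappa_grid = kappas,
                       energy_grid = es,
                       interface_area_mm2 = best$interface_area,
                       wet_area_mm2 = ints$wet_area))
}

#' Closed-form supine coverage of a lens-free spherical chamber
#'
#' In the supine posture the problem is axisymmetric about gravity and the
#' oil-covered wall fraction of a spherical chamber has a closed form. With
#' the contact-angle term disabled (`mode = "flat"`) the covered fraction is
#' x/2 where x solves x^2 (3 - x) = 4 fill. In capillary mode the interface
#' is the spherical cap that meets the wall exactly at the contact angle
#' (measured through the aqueous); the rim colatitude then follows from oil
#' volume conservation and the covered fraction is (1 + cos(beta))/2 with
#' beta the rim colatitude from the lowest point. Gravity does not enter the
#' capillary variant: it is the zero-Bond-number limit.
#'
#' @param fill Oil volume fraction, in (0, 1).
#' @param eye_radius Chamber radius, mm.
#' @param contact_angle Contact angle through the aqueous phase, degrees
#'   (capillary mode only).
#' @param mode `"capillary"` or `"flat"`.
#' @return Covered fraction of the spherical wall, in [0, 1].
#' @export
analytic_supine_coverage <- function(fill, eye_radius = 12,
                                     contact_angle = 16.2,
                                     mode = c("capillary", "flat")) {
  mode <- match.arg(mode)
  stopifnot(fill > 0, fill < 1)
  if (length(fill) > 1)
    return(vapply(fill, analytic_supine_coverage, 0,
                  eye_radius = eye_radius, contact_angle = contact_angle,
                  mode = mode))
  if (mode == "flat") {
    x <- stats::uniroot(function(x) x^2 * (3 - x) - 4 * fill,
                        c(0, 2), tol = 1e-12)$root
    return(x / 2)
  }
  R <- eye_radius
  th <- contact_angle * pi / 180
  v_target <- (1 - fill) * 4 * pi * R^3 / 3
  aq_vol <- function(beta) {
    zc <- -R * cos(beta)
    h1 <- R * (1 - cos(beta))
    v1 <- pi * h1^2 * (3 * R - h1) / 3
    sol <- supine_cap_solution(beta, R, th)
    if (is.null(sol)) {
      ## theta ~= beta: the interface degenerates to the flat plane and the
      ## cap volume vanishes; near the degeneracy the quadratic root filter
      ## loses precision, so fall back to the flat volume in a small window
      if (abs(beta - th) < 0.02) return(v1)
      return(NA_real_)
    }
    r <- sol$r; w <- sol$w
    if (sol$branch == "bowl") {
      hb <- r + w                   # bowl depth below the rim plane
      if (hb <= 0 || hb > 2 * r) return(NA_real_)
      if ((zc - w) - r < -R) return(NA_real_)   # pokes through the wall
      v1 - pi * hb^2 * (3 * r - hb) / 3
    } else {
      hd <- r - w                   # dome height above the rim plane
      if (hd <= 0 || hd > 2 * r) return(NA_real_)
      if ((zc - w) + r > R) return(NA_real_)    # pokes through the wall
      v1 + pi * hd^2 * (3 * r - hd) / 3
    }
  }
  f <- function(beta) aq_vol(beta) - v_target
  ## bracket the rim colatitude between consecutive finite grid values
  betas <- seq(0.02, pi - 0.02, length.out = 400)
  vals <- vapply(betas, f, 0)
  n <- length(betas)
  cross <- which(is.finite(vals[-n]) & is.finite(vals[-1]) &
                   sign(vals[-n]) * sign(vals[-1]) <= 0)[1]
  if (is.na(cross))
    stop("no axisymmetric capillary solution for this fill/contact angle",
         call. = FALSE)
  beta <- suppressWarnings(   # NA marks infeasible rim colatitudes
    stats::uniroot(f, c(betas[cross], betas[cross + 1L]), tol = 1e-10))$root
  (1 + cos(beta)) / 2
}

## Interface sphere meeting the wall at contact angle `th` (through the
## aqueous) at rim colatitude `beta`. Returns w = z_rim - z_centre, the cap
## radius r and the branch: "bowl" (theta < beta, aqueous climbing, centre
## above the rim, w < 0) or "dome" (theta > beta, interface bulging upward,
## centre below the rim, w > 0). Both satisfy the squared contact condition
## (a^2 + zc w)^2 = R^2 cos^2(th) (a^2 + w^2); the unsquared sign picks the
## branch.
supine_cap_solution <- function(beta, R, th) {
  zc <- -R * cos(beta); a <- R * sin(beta)
  ct <- cos(th)
  den <- zc^2 - (R * ct)^2
  if (abs(den) < 1e-10 * R^2) return(NULL)   # flat-degenerate: theta == beta
  disc <- a^2 * R^4 * ct^2 * sin(th)^2
  for (wc in (-a^2 * zc + c(1, -1) * sqrt(disc)) / den) {
    g <- a^2 + zc * wc
    r <- sqrt(a^2 + wc^2)
    if (wc < 0 && abs(g - R * ct * r) < 1e-6 * R^2)
      return(list(w = wc, r = r, branch = "bowl"))
    if (wc > 0 && abs(g + R * ct * r) < 1e-6 * R^2)
      return(list(w = wc, r = r, branch = "dome"))
  }
  NULL
}

#' Per-region oil-contact fractions
#'
#' Wetted area divided by region area for every (region, hemisphere) pair,
#' with aggregate rows for the retina (macula + post-equatorial +
#' pre-equatorial), for both hemispheres combined, and for the whole wall.
#' With `method = "split"` (default) triangles straddling the interface are
#' clipped exactly against the interpolated interface; `"majority"` assigns
#' whole triangles by majority vote of their vertex wetting flags.
#'
#' @param state An `equilibrium_state`.
#' @param geom The segmented geometry the state was solved on.
#' @param method `"split"` or `"majority"`.
#' @return data.frame with columns `region`, `hemisphere`, `area_mm2`,
#'   `wetted_area_mm2`, `fraction`. Regions with zero area (e.g. the lens of
#'   a lens-free build) report `NA` fractions.
#' @export
contact_fractions <- function(state, geom, method = c("split", "majority")) {
  method <- match.arg(method)
  stopifnot(inherits(state, "equilibrium_state"),
            !is.null(geom$tri_region),
            length(state$s) == nrow(geom$vertices))
  st <- geom$subtris
  if (method == "split") {
    ## clip the cached region decomposition against the interface directly
    iface <- state$interface
    cb <- clip_both_sides(st$q1, st$q2, st$q3,
                          iface_signed(iface, st$q1),
                          iface_signed(iface, st$q2),
                          iface_signed(iface, st$q3))
    wet_sub <- numeric(length(st$area))
    oil_area <- sqrt(rowSums(cross3(cb$pos$q2 - cb$pos$q1,
                                    cb$pos$q3 - cb$pos$q1)^2)) / 2
    if (length(cb$pos$src)) {
      sums <- rowsum(oil_area, cb$pos$src)
      wet_sub[as.integer(rownames(sums))] <- sums[, 1]
    }
  } else {
    votes <- rowSums(matrix(state$wet[geom$triangles], ncol = 3))
    wet_sub <- ifelse(votes[st$tri] >= 2, st$area, 0)
  }
  tot <- aggregate_region_table(st$area, st$region, st$hemisphere)
  wet <- aggregate_region_table(wet_sub, st$region, st$hemisphere)
  out <- data.frame(region = tot$region, hemisphere = tot$hemisphere,
                    area_mm2 = tot$value, wetted_area_mm2 = wet$value)
  wall <- data.frame(region = "wall", hemisphere = "both",
                     area_mm2 = sum(st$area), wetted_area_mm2 = sum(wet_sub))
  out <- rbind(out, wall)
  out$fraction <- ifelse(out$area_mm2 > 0,
                         out$wetted_area_mm2 / out$area_mm2, NA_real_)
  if (all(out$area_mm2[out$region == "retina"] == 0))
    stop("degenerate segmentation: retina has zero area", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Look up one fraction in a [contact_fractions()] table
#' @param tab A contact-fraction table.
#' @param region,hemisphere Row selector.
#' @return The fraction, a single number.
#' @export
contact_value <- function(tab, region, hemisphere = "both") {
  tab$fraction[tab$region == region & tab$hemisphere == hemisphere]
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("equilibrium_state (%s): posture %s, fill %.3f (achieved %.4f)\n",
              x$mode, x$posture$name, x$fill, x$fill_achieved))
  if (x$interface$type == "plane")
    cat(sprintf("  plane interface at h = %.3f mm along anti-gravity axis\n",
                x$interface$h))
  else if (x$interface$type == "sphere")
    cat(sprintf("  spherical interface: r = %.2f mm, centre at %.2f mm, oil %s\n",
                x$interface$r, x$interface$z0,
                if (x$interface$oil_inside) "inside" else "outside"))
  else cat("  full fill: no interface\n")
  cat(sprintf("  wet vertices: %d / %d\n", sum(x$wet), length(x$wet)))
  invisible(x)
}

## Cheap fingerprint tying an equilibrium state to its geometry.
geom_signature <- function(geom) {
  c(n = nrow(geom$vertices), area = round(sum(triangle_areas(geom)), 9))
}
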