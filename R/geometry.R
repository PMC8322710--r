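#' Vitreous-chamber surface geometry
#'
#' The vitreous chamber is modelled as a sphere (default diameter 24 mm)
#' indented on the anterior side by a second sphere representing the back of
#' the crystalline lens. The wall is discretized as a triangle surface mesh
#' obtained by subdividing an icosahedron and radially projecting vertices
#' onto the chamber boundary, so the mesh is closed and watertight by
#' construction. Enclosed volumes are computed with the divergence theorem.
#'
#' The anatomical frame is fixed to the eye: `anterior_axis` points from the
#' posterior pole towards the lens, `superior_axis` towards the superior
#' retina. The lens centre sits at `lens_center_offset` along the anterior
#' axis; the lens sphere must intersect the eye sphere without engulfing it.
#'
#' @param eye_radius Eye (chamber) radius in mm.
#' @param lens_radius Lens-sphere radius in mm; `NA` or `0` disables the
#'   lens indentation.
#' @param lens_center_offset Distance of the lens-sphere centre from the eye
#'   centre along the anterior axis, mm.
#' @param resolution Target triangle edge length in mm; the icosphere
#'   subdivision level is the smallest one whose edge length does not exceed
#'   this value.
#' @return An object of class `eye_geometry`: list with `vertices` (n x 3,
#'   mm), `triangles` (m x 3, 1-based), `on_lens` (logical per vertex),
#'   anatomical axes and the generating parameters. Region labels are added
#'   by [segment_regions()].
#' @seealso [segment_regions()], [region_areas()], [mesh_volume()]
#' @examples
#' geom <- build_chamber_mesh(resolution = 2)
#' mesh_volume(geom)
#' @export
build_chamber_mesh <- function(eye_radius = 12, lens_radius = 5.5,
                               lens_center_offset = 13, resolution = 0.75) {
  stopifnot(eye_radius > 0, resolution > 0)
  has_lens <- !is.na(lens_radius) && lens_radius > 0
  if (has_lens) {
    if (!(abs(lens_center_offset - lens_radius) < eye_radius &&
          eye_radius < lens_center_offset + lens_radius))
      stop("lens sphere must intersect the eye sphere without engulfing it",
           call. = FALSE)
  }
  ## icosahedron edge length is ~1.05146 R; each subdivision halves it
  edge0 <- 1.0514622 * eye_radius
  level <- max(0L, ceiling(log2(edge0 / resolution)))
  ico <- icosphere(level)
  anterior <- c(0, 0, 1)
  superior <- c(0, 1, 0)
  radii <- rep(eye_radius, nrow(ico$vertices))
  on_lens <- rep(FALSE, nrow(ico$vertices))
  if (has_lens) {
    ## radial distance at which the unit ray first meets the lens sphere
    b <- ico$vertices[, 3] * lens_center_offset      # dot(dir, lens centre)
    disc <- b^2 - (lens_center_offset^2 - lens_radius^2)
    hit <- disc > 0
    t1 <- ifelse(hit, b - sqrt(pmax(disc, 0)), Inf)
    indent <- hit & t1 > 0 & t1 < eye_radius
    radii[indent] <- t1[indent]
    on_lens <- indent
  }
  ## volume deficit of the faceted sphere relative to the true sphere, used
  ## to keep semi-analytic interface integrals consistent with the mesh
  pc <- ico$vertices[ico$triangles[, 1], , drop = FALSE]
  qc <- ico$vertices[ico$triangles[, 2], , drop = FALSE]
  rc <- ico$vertices[ico$triangles[, 3], , drop = FALSE]
  nr <- cbind(
    (qc - pc)[, 2] * (rc - pc)[, 3] - (qc - pc)[, 3] * (rc - pc)[, 2],
    (qc - pc)[, 3] * (rc - pc)[, 1] - (qc - pc)[, 1] * (rc - pc)[, 3],
    (qc - pc)[, 1] * (rc - pc)[, 2] - (qc - pc)[, 2] * (rc - pc)[, 1])
  v_unit <- sum(rowSums((pc + qc + rc) / 3 * nr)) / 6
  facet_factor <- v_unit / (4 * pi / 3)

  geom <- structure(list(
    vertices = ico$vertices * radii,
    triangles = ico$triangles,
    on_lens = on_lens,
    eye_radius = eye_radius,
    lens_radius = if (has_lens) lens_radius else NA_real_,
    lens_center_offset = if (has_lens) lens_center_offset else NA_real_,
    anterior_axis = anterior,
    superior_axis = superior,
    resolution = resolution,
    subdivision = level,
    facet_factor = facet_factor
  ), class = "eye_geometry")
  geom
}

## Icosphere: icosahedron subdivided `level` times, vertices on unit sphere.
icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(level)) {
    n <- nrow(v)
    ## midpoint of every undirected edge, deduplicated via edge keys
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    e <- t(apply(e, 1, sort))
    key <- e[, 1] * (n + 1L) + e[, 2]
    uk <- !duplicated(key)
    mid_idx <- match(key, key[uk]) + n
    mids <- (v[e[uk, 1], ] + v[e[uk, 2], ]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m <- nrow(f)
    ab <- mid_idx[seq_len(m)]
    bc <- mid_idx[m + seq_len(m)]
    ca <- mid_idx[2 * m + seq_len(m)]
    f <- rbind(cbind(f[, 1], ab, ca), cbind(f[, 2], bc, ab),
               cbind(f[, 3], ca, bc), cbind(ab, bc, ca))
  }
  dimnames(v) <- NULL
  dimnames(f) <- NULL
  list(vertices = v, triangles = f)
}

region_levels <- c("macula", "postequatorial", "preequatorial", "ora", "lens")
hemisphere_levels <- c("superior", "inferior")

#' Segment the chamber wall into anatomical regions
#'
#' Labels every vertex (and triangle, via its centroid) with one of
#' `macula`, `postequatorial`, `preequatorial`, `ora` or `lens`, and a
#' `superior`/`inferior` hemisphere flag. Angles are polar angles measured at
#' the eye centre from the anterior axis: the macula is the posterior cap
#' within `macula_half_angle` of the posterior pole, the post-equatorial
#' retina runs from there to the equator, the pre-equatorial retina from the
#' equator to `ora_limit_angle`, and the ora serrata band from there to the
#' lens rim. Vertices on the lens indentation are `lens`. The hemisphere
#' split is anatomical (sign of the superior-axis coordinate), not
#' gravity-dependent.
#'
#' @param geom An [build_chamber_mesh()] geometry.
#' @param macula_half_angle Macula half-angle from the posterior pole,
#'   degrees.
#' @param ora_limit_angle Anterior limit of the retina (start of the ora
#'   band), degrees from the anterior pole.
#' @return `geom` with `vertex_region`, `vertex_hemisphere`, `tri_region`,
#'   `tri_hemisphere` factors and a cached exact sub-triangle decomposition
#'   (`subtris`, triangles split along region boundaries and the hemisphere
#'   plane) added.
#' @export
segment_regions <- function(geom, macula_half_angle = 20,
                            ora_limit_angle = 40) {
  stopifnot(inherits(geom, "eye_geometry"),
            macula_half_angle > 0, ora_limit_angle > macula_half_angle)
  lab <- function(pts, on_lens) {
    ang <- polar_angle_deg(geom, pts)
    reg <- ifelse(on_lens, "lens",
           ifelse(ang >= 180 - macula_half_angle, "macula",
           ifelse(ang > 90, "postequatorial",
           ifelse(ang > ora_limit_angle, "preequatorial", "ora"))))
    if (anyNA(reg)) stop("unlabeled vertex in segmentation", call. = FALSE)
    factor(reg, levels = region_levels)
  }
  hemi <- function(pts) {
    factor(ifelse(c(pts %*% geom$superior_axis) >= 0, "superior", "inferior"),
           levels = hemisphere_levels)
  }
  geom$macula_half_angle <- macula_half_angle
  geom$ora_limit_angle <- ora_limit_angle
  geom$vertex_region <- lab(geom$vertices, geom$on_lens)
  geom$vertex_hemisphere <- hemi(geom$vertices)
  cen <- triangle_centroids(geom)
  tri_on_lens <- rowSums(matrix(geom$on_lens[geom$triangles], ncol = 3)) >= 2
  geom$tri_region <- lab(cen, tri_on_lens)
  geom$tri_hemisphere <- hemi(cen)
  geom$subtris <- segment_subtris(geom)
  geom
}

polar_angle_deg <- function(geom, pts) {
  ct <- pts %*% geom$anterior_axis / sqrt(rowSums(pts^2))
  c(acos(pmin(1, pmax(-1, ct)))) * 180 / pi   # anterior pole = 0
}

## Clip a set of triangles (corner matrices q1..q3, per-corner signed values
## s1..s3) into the s > 0 and s <= 0 sides. `src` carries the row index of
## the originating triangle so attributes can follow the pieces. `crossing`
## optionally replaces the default linear-interpolation edge crossing with an
## exact one (used for the curved region boundaries).
clip_both_sides <- function(q1, q2, q3, s1, s2, s3, crossing = NULL) {
  n <- nrow(q1)
  pos <- cbind(s1 > 0, s2 > 0, s3 > 0)
  np <- rowSums(pos)
  lerp <- if (is.null(crossing))
    function(pa, pb, sa, sb) pa + (pb - pa) * (sa / (sa - sb))
  else crossing
  pick <- function(rows, k)  # corner k per row
    q1[rows, , drop = FALSE] * (k == 1) + q2[rows, , drop = FALSE] * (k == 2) +
    q3[rows, , drop = FALSE] * (k == 3)
  sval <- function(rows, k)
    s1[rows] * (k == 1) + s2[rows] * (k == 2) + s3[rows] * (k == 3)

  out <- list(
    pos = list(q1 = q1[np == 3, , drop = FALSE], q2 = q2[np == 3, , drop = FALSE],
               q3 = q3[np == 3, , drop = FALSE], src = which(np == 3)),
    neg = list(q1 = q1[np == 0, , drop = FALSE], q2 = q2[np == 0, , drop = FALSE],
               q3 = q3[np == 0, , drop = FALSE], src = which(np == 0)))
  add <- function(side, a, b, cc, src) {
    out[[side]]$q1 <<- rbind(out[[side]]$q1, a)
    out[[side]]$q2 <<- rbind(out[[side]]$q2, b)
    out[[side]]$q3 <<- rbind(out[[side]]$q3, cc)
    out[[side]]$src <<- c(out[[side]]$src, src)
  }
  mix1 <- which(np == 1L)
  if (length(mix1)) {
    k <- max.col(pos[mix1, , drop = FALSE], ties.method = "first")
    kb <- k %% 3L + 1L; kc <- kb %% 3L + 1L
    va <- pick(mix1, k); vb <- pick(mix1, kb); vc <- pick(mix1, kc)
    sa <- sval(mix1, k); sb <- sval(mix1, kb); sc <- sval(mix1, kc)
    pab <- lerp(va, vb, sa, sb); pac <- lerp(va, vc, sa, sc)
    add("pos", va, pab, pac, mix1)
    add("neg", rbind(pab, pab), rbind(vb, vc), rbind(vc, pac), c(mix1, mix1))
  }
  mix2 <- which(np == 2L)
  if (length(mix2)) {
    k <- max.col(!pos[mix2, , drop = FALSE], ties.method = "first")
    ka <- k %% 3L + 1L; kb <- ka %% 3L + 1L
    vc <- pick(mix2, k); va <- pick(mix2, ka); vb <- pick(mix2, kb)
    sc <- sval(mix2, k); sa <- sval(mix2, ka); sb <- sval(mix2, kb)
    pbc <- lerp(vb, vc, sb, sc); pac <- lerp(va, vc, sa, sc)
    add("pos", rbind(va, va), rbind(vb, pbc), rbind(pbc, pac), c(mix2, mix2))
    add("neg", pac, pbc, vc, mix2)
  }
  out
}

## Exact edge crossing with the polar-angle cone ang = bound about `axis`:
## along the segment p(t) = (1-t) pa + t pb, solves (p.axis)^2 = cos^2 |p|^2
## (a quadratic in t), keeping the root on the correct nappe. Falls back to
## linear interpolation of the angle when roots degenerate numerically.
polar_crossing_fun <- function(axis, bound_deg) {
  cb <- cos(bound_deg * pi / 180)
  function(pa, pb, sa, sb) {
    t_lin <- sa / (sa - sb)
    ua <- c(pa %*% axis); ub <- c(pb %*% axis)
    maa <- rowSums(pa^2); mbb <- rowSums(pb^2); mab <- rowSums(pa * pb)
    du <- ub - ua
    A <- du^2 - cb^2 * (maa - 2 * mab + mbb)
    B <- 2 * (ua * du - cb^2 * (mab - maa))
    C <- ua^2 - cb^2 * maa
    disc <- B^2 - 4 * A * C
    ok <- disc >= 0 & abs(A) > 1e-300
    sq <- sqrt(pmax(disc, 0))
    score <- function(cand) {
      u <- ua + cand * du
      good <- ok & cand >= -1e-9 & cand <= 1 + 1e-9 &
        (u * cb >= 0 | abs(cb) < 1e-12)
      ifelse(good, abs(cand - t_lin), Inf)
    }
    c1 <- (-B - sq) / (2 * A)
    c2 <- (-B + sq) / (2 * A)
    s1c <- score(c1); s2c <- score(c2)
    t <- ifelse(pmin(s1c, s2c) == Inf, t_lin, ifelse(s1c <= s2c, c1, c2))
    t <- pmin(pmax(t, 0), 1)
    pa + (pb - pa) * t
  }
}

## Exact decomposition of the wall triangles along the polar-angle region
## boundaries and the hemisphere plane.
segment_subtris <- function(geom) {
  has_lens <- !is.na(geom$lens_radius)
  rim <- if (has_lens)
    acos((geom$eye_radius^2 + geom$lens_center_offset^2 - geom$lens_radius^2) /
           (2 * geom$eye_radius * geom$lens_center_offset)) * 180 / pi
  else NA_real_
  bounds <- c(lens = if (has_lens) rim else -1,
              ora = geom$ora_limit_angle,
              preequatorial = 90,
              postequatorial = 180 - geom$macula_half_angle)
  p <- triangle_corners(geom)
  cur <- list(q1 = p$p1, q2 = p$p2, q3 = p$p3,
              src = seq_len(nrow(geom$triangles)))
  pieces <- list()
  for (nm in names(bounds)) {
    if (bounds[[nm]] < 0) next
    s1 <- bounds[[nm]] - polar_angle_deg(geom, cur$q1)
    s2 <- bounds[[nm]] - polar_angle_deg(geom, cur$q2)
    s3 <- bounds[[nm]] - polar_angle_deg(geom, cur$q3)
    crossing <- polar_crossing_fun(geom$anterior_axis, bounds[[nm]])
    cb <- clip_both_sides(cur$q1, cur$q2, cur$q3, s1, s2, s3, crossing)
    inside <- cb$pos                        # polar angle below the bound
    inside$src <- cur$src[inside$src]
    inside$region <- nm
    pieces[[nm]] <- inside
    cur <- list(q1 = cb$neg$q1, q2 = cb$neg$q2, q3 = cb$neg$q3,
                src = cur$src[cb$neg$src])
  }
  cur$region <- "macula"
  pieces[["macula"]] <- cur
  q1 <- do.call(rbind, lapply(pieces, `[[`, "q1"))
  q2 <- do.call(rbind, lapply(pieces, `[[`, "q2"))
  q3 <- do.call(rbind, lapply(pieces, `[[`, "q3"))
  tri <- unlist(lapply(pieces, `[[`, "src"), use.names = FALSE)
  region <- rep(vapply(pieces, `[[`, "", "region"),
                vapply(pieces, function(p) length(p$src), 0L))
  ## hemisphere split on the superior-axis coordinate
  su <- geom$superior_axis
  hb <- clip_both_sides(q1, q2, q3, c(q1 %*% su), c(q2 %*% su), c(q3 %*% su))
  q1 <- rbind(hb$pos$q1, hb$neg$q1)
  q2 <- rbind(hb$pos$q2, hb$neg$q2)
  q3 <- rbind(hb$pos$q3, hb$neg$q3)
  src <- c(hb$pos$src, hb$neg$src)
  hemisphere <- rep(c("superior", "inferior"),
                    c(length(hb$pos$src), length(hb$neg$src)))
  area <- sqrt(rowSums(cross3(q2 - q1, q3 - q1)^2)) / 2
  keep <- area > 0
  list(q1 = q1[keep, , drop = FALSE], q2 = q2[keep, , drop = FALSE],
       q3 = q3[keep, , drop = FALSE],
       tri = tri[src][keep],
       region = factor(region[src][keep], levels = region_levels),
       hemisphere = factor(hemisphere[keep], levels = hemisphere_levels),
       area = area[keep])
}

#' Areas of the wall regions
#'
#' Triangle areas accumulated per (region, hemisphere), the denominators of
#' the contact fractions. Rows with region `retina` aggregate macula,
#' post-equatorial and pre-equatorial retina; hemisphere `both` aggregates
#' the two hemispheres.
#'
#' @param geom A segmented geometry (see [segment_regions()]).
#' @return data.frame with columns `region`, `hemisphere`, `area_mm2`.
#' @export
region_areas <- function(geom) {
  stopifnot(!is.null(geom$subtris))
  agg <- aggregate_region_table(geom$subtris$area,
                                geom$subtris$region, geom$subtris$hemisphere)
  names(agg)[3] <- "area_mm2"
  agg
}

## Shared aggregation: per-element scalar -> (region, hemisphere) table with
## retina and both-hemisphere aggregates.
aggregate_region_table <- function(values, region, hemisphere) {
  df <- data.frame(region = region, hemisphere = hemisphere, value = values)
  base <- stats::aggregate(value ~ region + hemisphere, df, sum, drop = FALSE)
  base$value[is.na(base$value)] <- 0
  retina <- base[base$region %in% c("macula", "postequatorial", "preequatorial"), ]
  ret <- stats::aggregate(value ~ hemisphere, retina, sum)
  ret <- data.frame(region = "retina", hemisphere = ret$hemisphere,
                    value = ret$value)
  out <- rbind(base, ret)
  both <- stats::aggregate(value ~ region, out, sum)
  out <- rbind(out, data.frame(region = both$region, hemisphere = "both",
                               value = both$value))
  out$region <- factor(out$region, levels = c(region_levels, "retina"))
  out$hemisphere <- factor(out$hemisphere,
                           levels = c(hemisphere_levels, "both"))
  out <- out[order(out$region, out$hemisphere), ]
  rownames(out) <- NULL
  out
}

triangle_corners <- function(geom) {
  list(p1 = geom$vertices[geom$triangles[, 1], , drop = FALSE],
       p2 = geom$vertices[geom$triangles[, 2], , drop = FALSE],
       p3 = geom$vertices[geom$triangles[, 3], , drop = FALSE])
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

triangle_normals_raw <- function(geom) {
  p <- triangle_corners(geom)
  cross3(p$p2 - p$p1, p$p3 - p$p1)   # outward, length = 2*area
}

#' @rdname mesh_volume
#' @export
triangle_areas <- function(geom) {
  n <- triangle_normals_raw(geom)
  sqrt(rowSums(n^2)) / 2
}

triangle_centroids <- function(geom) {
  p <- triangle_corners(geom)
  (p$p1 + p$p2 + p$p3) / 3
}

#' Mesh area and enclosed volume
#'
#' `mesh_area()` sums triangle areas; `mesh_volume()` applies the divergence
#' theorem (exact for a closed triangle mesh); `triangle_areas()` returns the
#' per-triangle areas.
#'
#' @param geom An `eye_geometry`.
#' @return Scalar area (mm^2) or volume (mm^3).
#' @export
mesh_volume <- function(geom) {
  n <- triangle_normals_raw(geom)
  cen <- triangle_centroids(geom)
  sum(rowSums(cen * n)) / 6
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(geom) sum(triangle_areas(geom))

#' @export
print.eye_geometry <- function(x, ...) {
  cat("eye_geometry: R =", x$eye_radius, "mm,",
      nrow(x$vertices), "vertices,", nrow(x$triangles), "triangles\n")
  if (!is.na(x$lens_radius))
    cat("  lens: r =", x$lens_radius, "mm at", x$lens_center_offset,
        "mm anterior offset\n")
  if (!is.null(x$vertex_region))
    cat("  regions:", paste(levels(x$vertex_region), collapse = ", "), "\n")
  invisible(x)
}
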