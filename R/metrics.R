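#' Wall-shear summary metrics
#'
#' Five summary statistics of a wall-traction time series, following the
#' usual naming in the tamponade literature:
#'
#' * IMSS - instantaneous maximum shear stress: per instant, the maximum
#'   traction magnitude over the region (Pa).
#' * PMSS - pointwise maximum shear stress: per vertex, the maximum traction
#'   magnitude over time (Pa).
#' * VASS - vertical average shear stress: per vertex, the time average of
#'   the traction component along the vertical (anti-gravity) axis, signed,
#'   positive upward (Pa).
#' * ARSS - average regional shear stress: per instant, the area-weighted
#'   spatial mean of the traction magnitude over the region (Pa).
#' * IMSR - instantaneous maximum shear rate: per instant, the maximum over
#'   the region of traction magnitude divided by the local viscosity (1/s).
#'
#' Spatial means are area-weighted with per-vertex Voronoi-style weights (one
#' third of the incident triangle areas). Region selection accepts any region
#' label from [segment_regions()] plus `"retina"` (macula + post- +
#' pre-equatorial) and `"wall"` (everything), optionally restricted to one
#' hemisphere.
#'
#' @param series A `traction_series` from [simulate_saccade_shear()] (or a
#'   synthetic fixture).
#' @param geom The segmented geometry the series was computed on.
#' @param region Region name (see above).
#' @param hemisphere `"both"` (default), `"superior"` or `"inferior"`.
#' @param vertical_axis Unit vector defining "up" for VASS; defaults to the
#'   anti-gravity axis of the posture stored in the series.
#' @param rate_convention_factor Divisor convention for the shear rate:
#'   `1` (default, engineering rate tau/mu) or `2` (strain-rate-tensor
#'   magnitude convention tau/(2 mu)).
#' @return `imss`, `arss`, `imsr`: numeric vector over `series$times`;
#'   `pmss`, `vass`: numeric vector over vertices.
#' @name shear_metrics
NULL

region_vertex_mask <- function(geom, region, hemisphere = "both") {
  stopifnot(!is.null(geom$vertex_region))
  vr <- as.character(geom$vertex_region)
  m <- switch(region,
              wall = rep(TRUE, length(vr)),
              retina = vr %in% c("macula", "postequatorial", "preequatorial"),
              vr == region)
  if (hemisphere != "both")
    m <- m & geom$vertex_hemisphere == hemisphere
  if (!any(m)) stop("empty region: ", region, "/", hemisphere, call. = FALSE)
  m
}

#' Per-vertex area weights (one third of incident triangle areas)
#' @param geom An `eye_geometry`.
#' @return Numeric vector, mm^2, summing to the mesh area.
#' @export
vertex_areas <- function(geom) {
  a <- triangle_areas(geom)
  w <- numeric(nrow(geom$vertices))
  for (k in 1:3) {
    s <- rowsum(a, geom$triangles[, k])
    idx <- as.integer(rownames(s))
    w[idx] <- w[idx] + s[, 1]
  }
  w / 3
}

check_series <- function(series, geom) {
  stopifnot(inherits(series, "traction_series"))
  if (nrow(series$magnitude) != nrow(geom$vertices))
    stop("traction series does not match the geometry", call. = FALSE)
}

#' @rdname shear_metrics
#' @export
imss <- function(series, geom, region = "retina", hemisphere = "both") {
  check_series(series, geom)
  m <- region_vertex_mask(geom, region, hemisphere)
  apply(abs(series$magnitude[m, , drop = FALSE]), 2, max)
}

#' @rdname shear_metrics
#' @export
pmss <- function(series) {
  stopifnot(inherits(series, "traction_series"))
  apply(abs(series$magnitude), 1, max)
}

#' @rdname shear_metrics
#' @export
vass <- function(series, vertical_axis = NULL) {
  stopifnot(inherits(series, "traction_series"))
  if (is.null(vertical_axis)) {
    if (is.null(series$posture))
      stop("no posture stored in series; supply vertical_axis", call. = FALSE)
    vertical_axis <- -series$posture$gravity
  }
  vcomp <- c(series$dir %*% vertical_axis)
  rowMeans(series$magnitude) * vcomp
}

#' @rdname shear_metrics
#' @export
arss <- function(series, geom, region = "retina", hemisphere = "both") {
  check_series(series, geom)
  m <- region_vertex_mask(geom, region, hemisphere)
  w <- vertex_areas(geom)[m]
  colSums(abs(series$magnitude[m, , drop = FALSE]) * w) / sum(w)
}

#' @rdname shear_metrics
#' @export
imsr <- function(series, geom, region = "retina", hemisphere = "both",
                 rate_convention_factor = 1) {
  check_series(series, geom)
  stopifnot(rate_convention_factor > 0)
  if (any(series$viscosity <= 0)) stop("zero viscosity", call. = FALSE)
  m <- region_vertex_mask(geom, region, hemisphere)
  rate <- abs(series$magnitude[m, , drop = FALSE]) /
    (rate_convention_factor * series$viscosity[m])
  apply(rate, 2, max)
}

#' All five shear metrics for a set of regions
#'
#' @inheritParams shear_metrics
#' @param regions Character vector of region names.
#' @param hemispheres Character vector of hemisphere selectors.
#' @return List with `per_region` (tidy data.frame: time_s, region,
#'   hemisphere, imss_Pa, arss_Pa, imsr_per_s) and per-vertex fields
#'   `pmss_Pa`, `vass_Pa`.
#' @export
metrics_bundle <- function(series, geom,
                           regions = c("retina", "macula", "postequatorial",
                                       "preequatorial", "ora", "lens"),
                           hemispheres = "both",
                           vertical_axis = NULL,
                           rate_convention_factor = 1) {
  per <- list()
  for (rg in regions) for (hm in hemispheres) {
    ok <- tryCatch(region_vertex_mask(geom, rg, hm), error = function(e) NULL)
    if (is.null(ok)) next
    per[[paste(rg, hm)]] <- data.frame(
      time_s = series$times, region = rg, hemisphere = hm,
      imss_Pa = imss(series, geom, rg, hm),
      arss_Pa = arss(series, geom, rg, hm),
      imsr_per_s = imsr(series, geom, rg, hm,
                        rate_convention_factor = rate_convention_factor))
  }
  list(per_region = do.call(rbind, c(per, make.row.names = FALSE)),
       pmss_Pa = pmss(series),
       vass_Pa = vass(series, vertical_axis))
}

#' Count dominant local maxima of a time series
#'
#' A sample is a dominant local maximum when it exceeds its neighbours and is
#' at least `prominence` times the global maximum. Used to verify the bimodal
#' (start-of-motion / end-of-motion) shape of saccadic shear-stress curves.
#'
#' @param x Numeric series.
#' @param prominence Fraction of the global maximum below which peaks are
#'   ignored.
#' @return Integer count.
#' @export
count_dominant_maxima <- function(x, prominence = 0.2) {
  n <- length(x)
  if (n < 3 || max(x) <= 0) return(0L)
  thr <- prominence * max(x)
  peaks <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  sum(x[peaks] >= thr)
}
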