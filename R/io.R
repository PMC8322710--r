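#' Write a chamber mesh as legacy-ASCII VTK polydata
#'
#' Integer point-data arrays `region` (0 = macula, 1 = postequatorial,
#' 2 = preequatorial, 3 = ora, 4 = lens) and `hemisphere` (0 = superior,
#' 1 = inferior) are written when the geometry is segmented; extra per-vertex
#' arrays (e.g. a wetting map or PMSS field) can be passed in `point_data`.
#'
#' @param geom An `eye_geometry`.
#' @param file Output path.
#' @param point_data Named list of per-vertex numeric vectors.
#' @return `file`, invisibly.
#' @export
write_vtk_polydata <- function(geom, file, point_data = list()) {
  v <- geom$vertices
  f <- geom$triangles - 1L
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vitreous chamber surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  utils::write.table(format(v, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  utils::write.table(cbind(3L, f), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  pd <- point_data
  if (!is.null(geom$vertex_region)) {
    pd <- c(list(region = as.integer(geom$vertex_region) - 1L,
                 hemisphere = as.integer(geom$vertex_hemisphere) - 1L), pd)
  }
  if (length(pd)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(pd)) {
      x <- pd[[nm]]
      stopifnot(length(x) == nrow(v))
      isint <- is.integer(x) || all(x == round(x))
      writeLines(c(sprintf("SCALARS %s %s 1", nm,
                           if (isint) "int" else "float"),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(if (isint) as.integer(x) else x,
                        digits = 9, trim = TRUE), con)
    }
  }
  invisible(file)
}

#' Write a chamber mesh as ASCII PLY
#'
#' @inheritParams write_vtk_polydata
#' @return `file`, invisibly.
#' @export
write_ply <- function(geom, file) {
  v <- geom$vertices
  f <- geom$triangles - 1L
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  utils::write.table(format(v, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, f), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a traction series as a VTK polydata time series
#'
#' One legacy-ASCII VTK file per sample (`<prefix>_NNNN.vtk`) carrying the
#' traction vector as point data `traction_Pa`, plus a compact CSV of
#' per-region maxima next to them.
#'
#' @param series A `traction_series`.
#' @param geom The segmented geometry.
#' @param prefix Output path prefix.
#' @param stride Write every `stride`-th sample (default 10, i.e. 10 ms).
#' @return Vector of files written, invisibly.
#' @export
write_traction_vtk_series <- function(series, geom, prefix, stride = 10L) {
  idx <- seq(1, length(series$times), by = stride)
  files <- character(0)
  for (i in idx) {
    fn <- sprintf("%s_%04d.vtk", prefix, i - 1L)
    tv <- series$magnitude[, i] * series$dir
    write_vtk_polydata(geom, fn, point_data = list(
      traction_x_Pa = tv[, 1], traction_y_Pa = tv[, 2],
      traction_z_Pa = tv[, 3]))
    files <- c(files, fn)
  }
  mb <- metrics_bundle(series, geom)
  csv <- paste0(prefix, "_region_metrics.csv")
  utils::write.csv(mb$per_region, csv, row.names = FALSE)
  invisible(c(files, csv))
}

#' Read and write run configurations
#'
#' Configurations are stored as flat YAML (keys documented in
#' [run_config()]); writing then reading a configuration reproduces it
#' exactly.
#'
#' @param config A [run_config()] list.
#' @param file Path.
#' @return `read_run_config()` returns the configuration list.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  do.call(run_config, cfg)
}
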