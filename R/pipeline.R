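#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full tamponade sweep. The
#' defaults reproduce the reference configuration: 24 mm chamber with lens
#' indentation, 50 degree / 0.137 s saccade about the superior axis, oils of
#' 1000 and 5000 mPa.s, fills 80-100% in 5% steps, three postures, capillary
#' equilibrium, engineering shear-rate convention. Lengths are mm and angles
#' degrees at this interface; everything is converted to SI internally.
#'
#' @param eye_radius,lens_radius,lens_center_offset,resolution Geometry, mm.
#' @param macula_half_angle,ora_limit_angle Segmentation angles, degrees.
#' @param oils Oil viscosities to sweep, mPa.s.
#' @param fills Fill fractions to sweep.
#' @param postures Posture names.
#' @param equilibrium_mode `"capillary"` or `"flat"`.
#' @param tol Volume tolerance of the equilibrium positioning.
#' @param dt Traction sampling step, s.
#' @param rate_convention_factor Shear-rate divisor convention (1 or 2).
#' @param regions Regions tabulated in the metric tables.
#' @param output_dir Where [run_pipeline()] writes files (`NULL` = nowhere).
#' @param seed Seed recorded in the manifest (the pipeline is deterministic;
#'   the seed is consumed by fixture generation only).
#' @return List of class `run_config`.
#' @export
run_config <- function(eye_radius = 12, lens_radius = 5.5,
                       lens_center_offset = 13, resolution = 0.75,
                       macula_half_angle = 20, ora_limit_angle = 40,
                       oils = c(1000, 5000),
                       fills = seq(0.80, 1.00, by = 0.05),
                       postures = c("standing", "tilt45", "supine"),
                       equilibrium_mode = c("capillary", "flat"),
                       tol = 1e-4, dt = 1e-3,
                       rate_convention_factor = 1,
                       regions = c("retina", "macula", "postequatorial",
                                   "preequatorial", "ora", "lens"),
                       output_dir = NULL, seed = 1L) {
  equilibrium_mode <- match.arg(equilibrium_mode)
  stopifnot(all(fills > 0 & fills <= 1), all(oils > 0),
            all(postures %in% c("standing", "tilt45", "supine")))
  cfg <- as.list(environment())
  structure(cfg[order(names(cfg))], class = "run_config")
}

#' Run the full tamponade sweep
#'
#' For every (posture, fill) the static equilibrium is solved once (it is
#' viscosity-independent); for every (oil, posture, fill) the saccadic
#' Stokes-layer simulation and the five shear metrics are computed. A failing
#' configuration is logged and skipped, the sweep continues.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return List with `contact` (tidy per-configuration contact-fraction
#'   table), `metrics` (tidy per-configuration region metric series),
#'   `geometry`, `wave`, and `manifest` (seed, configuration hash, versions,
#'   counts).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  geom <- segment_regions(
    build_chamber_mesh(config$eye_radius, config$lens_radius,
                       config$lens_center_offset, config$resolution),
    config$macula_half_angle, config$ora_limit_angle)
  wave <- saccade_wave()
  statics <- list()
  contact <- list()
  for (p in config$postures) for (f in config$fills) {
    key <- sprintf("%s_%03d", p, round(100 * f))
    st <- tryCatch({
      if (config$equilibrium_mode == "capillary")
        solve_capillary_interface(geom, f, posture(p),
                                  fluid_pair(config$oils[1]),
                                  tol = config$tol)
      else
        solve_flat_interface(geom, f, posture(p), tol = config$tol)
    }, error = function(e) {
      say("equilibrium failed for ", key, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(st)) next
    statics[[key]] <- st
    cf <- contact_fractions(st, geom)
    cf <- cbind(posture = p, fill = f, cf)
    contact[[key]] <- cf
    say(sprintf("equilibrium %s fill %.2f: retina contact %.3f",
                p, f, contact_value(cf, "retina")))
  }
  metrics <- list()
  for (oil in config$oils) for (p in config$postures) for (f in config$fills) {
    key <- sprintf("%s_%03d", p, round(100 * f))
    st <- statics[[key]]
    if (is.null(st)) next
    res <- tryCatch({
      ser <- simulate_saccade_shear(geom, st, fluid_pair(oil), wave,
                                    dt = config$dt)
      mb <- metrics_bundle(ser, geom, regions = config$regions,
                           rate_convention_factor =
                             config$rate_convention_factor)
      cbind(oil_mPas = oil, posture = p, fill = f, mb$per_region)
    }, error = function(e) {
      say("simulation failed for oil ", oil, " ", key, ": ",
          conditionMessage(e))
      NULL
    })
    if (!is.null(res)) metrics[[paste(oil, key)]] <- res
  }
  contact <- do.call(rbind, c(contact, make.row.names = FALSE))
  metrics <- do.call(rbind, c(metrics, make.row.names = FALSE))
  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("oculotamp")),
    n_static = length(statics),
    n_dynamic = length(metrics) / max(1, length(config$regions)),
    timestamp = format(Sys.time(), tz = "UTC"))
  out <- list(contact = contact, metrics = metrics, geometry = geom,
              wave = wave, manifest = manifest)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(contact, file.path(config$output_dir, "contact.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(config$output_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write_vtk_polydata(geom, file.path(config$output_dir, "chamber.vtk"))
  }
  out
}

## Stable hash of a configuration (order-independent serialization).
config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  txt <- paste(names(x), vapply(x, function(v) paste(format(v), collapse = ","),
                                ""), sep = "=", collapse = ";")
  ## polynomial rolling hash, exact in doubles
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Figure-companion report tables
#'
#' Reshapes pipeline results into the tables behind the usual figures:
#' contact fraction vs fill per posture/region/hemisphere, and the
#' IMSS/ARSS/IMSR time series per configuration.
#'
#' @param results Output of [run_pipeline()].
#' @return List with `contact_vs_fill` and `metric_series` data.frames.
#' @export
report_tables <- function(results) {
  ct <- results$contact
  contact_vs_fill <- ct[order(ct$posture, ct$region, ct$hemisphere, ct$fill),
                        c("posture", "fill", "region", "hemisphere",
                          "area_mm2", "wetted_area_mm2", "fraction")]
  rownames(contact_vs_fill) <- NULL
  list(contact_vs_fill = contact_vs_fill,
       metric_series = results$metrics)
}
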