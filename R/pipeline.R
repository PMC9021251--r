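#' Run the full modeling pipeline
#'
#' Orchestrates geometry -> field -> thermal -> threshold fitting from a
#' single configuration and writes all artifacts (field/temperature/damage
#' rasters, per-element CSV, DSC curves, threshold report, run manifest) into
#' an output directory. The configuration is validated before any solve.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{protocol}{preset name (`"hexagonal_ect"`, `"linear_ect"`) or a
#'       list of [pulse_protocol()] arguments.}
#'     \item{layout}{`"hexagonal"` or `"linear"` (nominal array geometry), or
#'       NULL when `geometry` is given.}
#'     \item{geometry}{optional path to a [save_geometry()] config; its
#'       regions/electrodes replace the nominal layout's homogeneous domain.}
#'     \item{tissue_table}{optional path to a [save_tissue_table()] file;
#'       default is [default_tissue_table()].}
#'     \item{h_mm}{mesh size near the electrodes (default 0.2).}
#'     \item{px_mm}{raster pixel size (default 0.1).}
#'     \item{zones}{optional list of paths (`A`, `B`) to mask rasters written
#'       by [write_raster()]; when present, thresholds are fitted.}
#'     \item{thermal}{logical: run the bioheat/damage stage (default TRUE).}
#'     \item{out_dir}{output directory (required).}
#'     \item{seed}{RNG seed recorded in the manifest.}
#'   }
#' @return the run manifest (invisibly), also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stopf("config$out_dir is required")
  ## ---- validation stage (before any solve) ----
  protocol <- if (is.character(config$protocol)) {
    protocol_presets(config$protocol)
  } else if (is.list(config$protocol)) {
    do.call(pulse_protocol, config$protocol)
  } else stopf("config$protocol is required (preset name or parameter list)")
  tissues <- if (!is.null(config$tissue_table)) {
    load_tissue_table(config$tissue_table)
  } else default_tissue_table()
  geom <- NULL
  if (!is.null(config$geometry)) geom <- load_geometry(config$geometry)
  layout_name <- config$layout %||% "hexagonal"
  lay <- if (!is.null(geom) && length(geom$electrodes) == 7L) {
    list(electrodes = geom$electrodes,
         pairs = place_hexagonal_array()$pairs)
  } else if (!is.null(geom) && length(geom$electrodes) == 2L) {
    list(electrodes = geom$electrodes,
         pairs = matrix(c(geom$electrodes[[1]]$id, geom$electrodes[[2]]$id), 1))
  } else if (layout_name == "hexagonal") {
    place_hexagonal_array()
  } else place_linear_pair()
  dd <- default_domain(lay$electrodes)
  regions <- c(list(rect_region("liver", dd[1], dd[2], dd[3], dd[4])),
               if (!is.null(geom)) geom$regions else list())
  for (lab in unique(vapply(regions, `[[`, "", "label")))
    tissue_cond(tissues, lab)   # errors on a missing tissue before solving
  h_mm <- config$h_mm %||% 0.2
  px_mm <- config$px_mm %||% 0.1
  zones <- NULL
  if (!is.null(config$zones)) {
    zones <- list(A = read_raster(config$zones$A), B = read_raster(config$zones$B))
    stopifnot(inherits(zones$A, "ect_zone_mask"), inherits(zones$B, "ect_zone_mask"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list(); tick <- function() proc.time()[["elapsed"]]
  ## ---- field stage ----
  t0 <- tick()
  mesh <- triangulate(regions, lay$electrodes, h_max = h_mm,
                      h_far = max(h_mm, (dd[3] - dd[1]) / 40))
  timings$mesh_s <- tick() - t0
  run_thermal <- config$thermal %||% TRUE
  t0 <- tick()
  field <- run_pair_sequence(mesh, tissues, lay$pairs, protocol,
                             thermal_feedback = run_thermal,
                             bioheat_config = list(store_series = FALSE))
  timings$field_s <- tick() - t0
  ctr <- do.call(rbind, lapply(lay$electrodes, `[[`, "center"))
  half <- max(apply(ctr, 2, function(v) diff(range(v)))) / 2 + 10
  mid <- colMeans(ctr)
  grid <- raster_grid(mid[1] + c(-half, half), mid[2] + c(-half, half), px_mm)
  ras <- export_field(field, grid)
  write_raster(ras, file.path(out_dir, "field_superposed"))
  export_field_csv(field, file.path(out_dir, "field_elements.csv"))
  for (k in seq_along(field$per_pair)) {
    rk <- export_field(field$per_pair[[k]], grid, mesh = mesh)
    write_raster(rk, file.path(out_dir, sprintf("field_pair_%02d", k)))
  }
  ## ---- thermal summary ----
  thermal_summary <- NULL
  if (run_thermal) {
    th <- field$thermal
    tm <- th$T_max_degC
    imax <- which.max(replace(tm, is.na(tm), -Inf))
    thermal_summary <- list(
      max_temperature_degC = max(tm, na.rm = TRUE),
      max_temperature_at_mm = as.numeric(mesh$nodes[imax, ]),
      max_damage_probability_pct = 100 * max(th$P_damage))
    tem <- element_nodal_mean(mesh, tm)
    tras <- export_field(tem, grid, mesh = mesh, units = "degC")
    write_raster(tras, file.path(out_dir, "temperature_max"))
    dem <- element_nodal_mean(mesh, th$P_damage)
    write_raster(export_field(dem, grid, mesh = mesh, units = "probability"),
                 file.path(out_dir, "damage_probability"))
    write.csv(data.frame(max_T_degC = thermal_summary$max_temperature_degC,
                         x_mm = thermal_summary$max_temperature_at_mm[1],
                         y_mm = thermal_summary$max_temperature_at_mm[2],
                         max_P_pct = thermal_summary$max_damage_probability_pct),
              file.path(out_dir, "thermal_summary.csv"), row.names = FALSE)
  }
  ## ---- fitting stage ----
  fits <- NULL
  if (!is.null(zones)) {
    zgrid <- list(origin_mm = zones$A$origin_mm, px_mm = zones$A$px_mm,
                  nx = zones$A$nx, ny = zones$A$ny)
    zras <- export_field(field, zgrid)
    fits <- lapply(zones, function(z) fit_threshold(zras, z))
    for (z in names(fits))
      export_dsc_curve(fits[[z]], file.path(out_dir, sprintf("dsc_zone%s.csv", z)))
    rep <- data.frame(zone = names(fits),
                      threshold_V_per_cm = vapply(fits, function(f) f$best_threshold, 0),
                      dsc = vapply(fits, function(f) f$best_dsc, 0))
    write.csv(rep, file.path(out_dir, "threshold_report.csv"), row.names = FALSE)
  }
  manifest <- list(
    tool = "ectfield::run_pipeline",
    package_version = as.character(utils::packageVersion("ectfield")),
    config = config,
    protocol = unclass(protocol),
    assumption_warnings = "tissue parameters other than liver/portal-space base conductivity are configuration defaults, not measured values",
    mesh = list(nodes = nrow(mesh$nodes), elements = nrow(mesh$tri)),
    solver = list(iterations_per_pair = vapply(field$per_pair, `[[`, 0L, "iterations")),
    thermal = thermal_summary,
    thresholds = if (!is.null(fits))
      lapply(fits, function(f) list(threshold_V_per_cm = f$best_threshold, dsc = f$best_dsc)),
    timings_s = timings,
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

## nodal field -> per-element mean over active elements (for rasterizing
## nodal quantities like temperature with the element sampler)
element_nodal_mean <- function(mesh, v) {
  el <- which(mesh$elec_id == 0L)
  tri <- mesh$tri[el, , drop = FALSE]
  (v[tri[, 1]] + v[tri[, 2]] + v[tri[, 3]]) / 3
}
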