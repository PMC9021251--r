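#' Save a model geometry to a YAML config
#'
#' Schema `ectfield-geometry-1`: a list of regions (label plus either a
#' polygon vertex list or a circle/ellipse primitive), electrodes (center,
#' diameter, id) and an optional microstructure spec. All lengths are in the
#' units stated by the field names (mm, um).
#'
#' @param regions list of [region()].
#' @param electrodes list of [electrode()].
#' @param path output path.
#' @param microstructure optional [microstructure_spec()].
#' @export
save_geometry <- function(regions, electrodes, path, microstructure = NULL) {
  enc_poly <- function(p) lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))
  out <- list(schema = "ectfield-geometry-1")
  out$regions <- lapply(regions, function(r) {
    list(label = r$label, polygon_mm = enc_poly(r$boundary),
         holes_mm = lapply(r$holes, enc_poly))
  })
  out$electrodes <- lapply(electrodes, function(e) {
    list(id = e$id, center_mm = as.numeric(e$center), diameter_mm = e$diameter,
         invert = e$invert)
  })
  if (!is.null(microstructure)) {
    out$microstructure <- list(
      lobule_diameter_um = microstructure$lobule_diameter_um,
      cv_diameter_um = microstructure$cv_diameter_um,
      septum_thickness_um = microstructure$septum_thickness_um,
      extent_mm = microstructure$extent_mm)
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Load a geometry config written by [save_geometry()]
#'
#' Regions may be given as `polygon_mm` vertex lists or as primitives:
#' `circle_mm: [cx, cy, r]` or `ellipse_mm: [cx, cy, rx, ry]`.
#'
#' @param path config path.
#' @return list with `regions`, `electrodes`, and `microstructure` (or NULL).
#' @export
load_geometry <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$schema, "ectfield-geometry-1"))
    stopf("unrecognized geometry schema: %s", cfg$schema %||% "<missing>")
  dec_poly <- function(p) do.call(rbind, lapply(p, as.numeric))
  regions <- lapply(cfg$regions, function(r) {
    boundary <- if (!is.null(r$polygon_mm)) {
      dec_poly(r$polygon_mm)
    } else if (!is.null(r$circle_mm)) {
      v <- as.numeric(r$circle_mm); circle_polygon(v[1:2], v[3])
    } else if (!is.null(r$ellipse_mm)) {
      v <- as.numeric(r$ellipse_mm)
      p <- circle_polygon(c(0, 0), 1)
      cbind(v[1] + v[3] * p[, 1], v[2] + v[4] * p[, 2])
    } else stopf("region '%s': no polygon or primitive", r$label)
    region(r$label, boundary, holes = lapply(r$holes_mm %||% list(), dec_poly))
  })
  electrodes <- lapply(cfg$electrodes %||% list(), function(e)
    electrode(as.numeric(e$center_mm), e$diameter_mm, e$id %||% 1L,
              isTRUE(e$invert)))
  micro <- NULL
  if (!is.null(cfg$microstructure)) {
    m <- cfg$microstructure
    micro <- microstructure_spec(m$lobule_diameter_um, m$cv_diameter_um,
                                 m$septum_thickness_um, as.numeric(m$extent_mm))
  }
  list(regions = regions, electrodes = electrodes, microstructure = micro)
}

#' Reference porcine liver ECT damage-zone thresholds
#'
#' Per-sample electric-field thresholds (V/cm) and Dice coefficients fitted
#' to the two histological damage zones of four reconstructed porcine liver
#' ECT cases (two hexagonal-array, two linear-electrode samples): Zone A,
#' coagulation necrosis around the electrode tracks, and Zone B, partially
#' damaged parenchyma attributed to IRE. Shipped as packaged reference data
#' for aggregate checks and as realistic generator settings for synthetic
#' cases.
#'
#' @return data frame with columns `sample`, `geometry`,
#'   `zoneA_threshold_V_per_cm`, `zoneB_threshold_V_per_cm`, `zoneA_dsc`,
#'   `zoneB_dsc`.
#' @export
reference_thresholds <- function() {
  path <- system.file("extdata", "porcine_ect_thresholds.csv",
                      package = "ectfield", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
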