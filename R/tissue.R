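#' Field-dependent (smoothed-step) tissue conductivity
#'
#' Electroporation increases tissue conductivity once the local electric field
#' exceeds the permeabilization level. The dependence is modeled as a C1
#' cubic-Hermite smoothed step in field strength E: conductivity equals the
#' base value below `e_center - e_width/2`, rises smoothly across the
#' transition zone, and plateaus at `factor` times the base above
#' `e_center + e_width/2`. Temperature scales the base value linearly:
#' `sigma0 * (1 + temp_coeff * (T - 37))`.
#'
#' @param sigma0 base conductivity at 37 degC and E = 0, S/m (> 0).
#' @param factor plateau multiplier (>= 1); `factor = 1` gives a
#'   field-independent conductivity.
#' @param e_center center of the transition zone E_C, V/cm.
#' @param e_width width of the transition zone E_W, V/cm (> 0).
#' @param temp_coeff fractional conductivity change per kelvin (default 0.015).
#' @return object of class `conductivity_fun`.
#' @export
conductivity_fun <- function(sigma0, factor = 1, e_center = 580, e_width = 240,
                             temp_coeff = 0.015) {
  check_number(sigma0, "sigma0", lower = 1e-12)
  check_number(factor, "factor", lower = 1)
  check_number(e_center, "e_center", lower = 0)
  check_number(e_width, "e_width", lower = 1e-12)
  check_number(temp_coeff, "temp_coeff")
  structure(list(sigma0 = sigma0, factor = factor, e_center = e_center,
                 e_width = e_width, temp_coeff = temp_coeff),
            class = "conductivity_fun")
}

#' @export
print.conductivity_fun <- function(x, ...) {
  cat(sprintf("<sigma(E): %.3g S/m x [1 .. %.3g], E_C = %g V/cm, E_W = %g V/cm, dT coeff %g /K>\n",
              x$sigma0, x$factor, x$e_center, x$e_width, x$temp_coeff))
  invisible(x)
}

## cubic Hermite smoothstep on [0, 1]
smoothstep01 <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

#' Evaluate tissue conductivity at a field strength and temperature
#'
#' @param f a [conductivity_fun()].
#' @param E electric field magnitude(s), V/cm (>= 0).
#' @param T_degC temperature(s), degC (default 37). Recycled against `E`.
#' @return conductivity in S/m, same length as `E`.
#' @export
sigma_of_E <- function(f, E, T_degC = 37) {
  stopifnot(inherits(f, "conductivity_fun"))
  if (any(!is.finite(E)) || any(E < 0)) stopf("E must be non-negative and finite")
  sT <- f$sigma0 * (1 + f$temp_coeff * (T_degC - 37))
  s <- smoothstep01((E - (f$e_center - f$e_width / 2)) / f$e_width)
  sT * (1 + (f$factor - 1) * s)
}

#' Thermal tissue properties
#'
#' Parameters of the Pennes bioheat equation for one tissue.
#'
#' @param density_kg_m3 mass density rho, kg/m^3.
#' @param heat_capacity_J_kgK specific heat capacity c, J/(kg K).
#' @param thermal_conductivity_W_mK thermal conductivity k, W/(m K).
#' @param perfusion_per_s blood perfusion rate omega_b, 1/s.
#' @param blood_rhoc_J_m3K volumetric heat capacity of blood rho_b c_b,
#'   J/(m^3 K).
#' @param arterial_temp_degC arterial blood temperature T_b, degC (30-40).
#' @param metabolic_heat_W_m3 metabolic heat source Q_m, W/m^3.
#' @return object of class `thermal_props`.
#' @export
thermal_props <- function(density_kg_m3 = 1079, heat_capacity_J_kgK = 3540,
                          thermal_conductivity_W_mK = 0.52,
                          perfusion_per_s = 0.0064,
                          blood_rhoc_J_m3K = 1060 * 3617,
                          arterial_temp_degC = 37,
                          metabolic_heat_W_m3 = 0) {
  for (nm in c("density_kg_m3", "heat_capacity_J_kgK", "thermal_conductivity_W_mK",
               "perfusion_per_s", "blood_rhoc_J_m3K", "metabolic_heat_W_m3"))
    check_number(get(nm), nm, lower = 0)
  check_number(arterial_temp_degC, "arterial_temp_degC", lower = 30, upper = 40)
  structure(list(density_kg_m3 = density_kg_m3,
                 heat_capacity_J_kgK = heat_capacity_J_kgK,
                 thermal_conductivity_W_mK = thermal_conductivity_W_mK,
                 perfusion_per_s = perfusion_per_s,
                 blood_rhoc_J_m3K = blood_rhoc_J_m3K,
                 arterial_temp_degC = arterial_temp_degC,
                 metabolic_heat_W_m3 = metabolic_heat_W_m3),
            class = "thermal_props")
}

#' Tissue property table
#'
#' Maps tissue labels to their electrical ([conductivity_fun()]) and thermal
#' ([thermal_props()]) properties. Tissues without an explicit thermal entry
#' default to liver values (with a warning at load time).
#'
#' @param entries named list; each element a list with components `cond` and
#'   optionally `thermal`.
#' @return object of class `tissue_table`.
#' @export
tissue_table <- function(entries) {
  stopifnot(is.list(entries), length(entries) > 0, !is.null(names(entries)))
  if (anyDuplicated(names(entries))) stopf("duplicate tissue name in table")
  for (nm in names(entries)) {
    if (!inherits(entries[[nm]]$cond, "conductivity_fun"))
      stopf("tissue '%s' lacks a conductivity_fun", nm)
    if (is.null(entries[[nm]]$thermal))
      entries[[nm]]$thermal <- thermal_props()
    stopifnot(inherits(entries[[nm]]$thermal, "thermal_props"))
  }
  structure(list(entries = entries), class = "tissue_table")
}

#' @export
print.tissue_table <- function(x, ...) {
  cat(sprintf("<tissue_table: %d tissues>\n", length(x$entries)))
  for (nm in names(x$entries)) {
    f <- x$entries[[nm]]$cond
    cat(sprintf("  %-12s sigma0 %.3g S/m, factor %.3g, E_C %g, E_W %g V/cm\n",
                nm, f$sigma0, f$factor, f$e_center, f$e_width))
  }
  invisible(x)
}

tissue_cond <- function(tissues, label) {
  e <- tissues$entries[[label]]
  if (is.null(e)) stopf("tissue '%s' is not in the tissue table", label)
  e$cond
}

tissue_thermal <- function(tissues, label) {
  e <- tissues$entries[[label]]
  if (is.null(e)) stopf("tissue '%s' is not in the tissue table", label)
  e$thermal
}

#' Default liver tissue table
#'
#' Packaged configuration for the tissues of the liver cross-section models.
#' Liver parenchyma (and hepatic-lobule) base conductivity is 0.091 S/m and
#' portal space 0.26 S/m, as established for porcine liver; the remaining
#' parameters (conductivity-increase factors, transition-zone locations,
#' blood and vessel-wall conductivities, thermal constants, perfusion) are a
#' documented configuration with magnitudes typical of the electroporation
#' treatment-planning literature, and are all overridable. The transition zone
#' spans roughly the reversible-to-irreversible electroporation range of liver
#' (about 460-700 V/cm).
#'
#' @return a [tissue_table()] with entries `liver`, `lobule`, `septa`, `cv`
#'   (blood-filled centrilobular-vein lumen), `blood`, `vessel_wall`,
#'   `portal_space` and `electrode`.
#' @export
default_tissue_table <- function() {
  liver_cond <- conductivity_fun(0.091, factor = 3.5, e_center = 580, e_width = 240)
  wall_cond  <- conductivity_fun(0.22, factor = 2, e_center = 700, e_width = 400)
  liver_th <- thermal_props()
  blood_th <- thermal_props(density_kg_m3 = 1060, heat_capacity_J_kgK = 3617,
                            thermal_conductivity_W_mK = 0.52, perfusion_per_s = 0)
  tissue_table(list(
    liver        = list(cond = liver_cond, thermal = liver_th),
    lobule       = list(cond = liver_cond, thermal = liver_th),
    septa        = list(cond = conductivity_fun(0.26, factor = 2, e_center = 700, e_width = 400),
                        thermal = liver_th),
    cv           = list(cond = conductivity_fun(0.70, factor = 1, e_width = 240),
                        thermal = blood_th),
    blood        = list(cond = conductivity_fun(0.70, factor = 1, e_width = 240),
                        thermal = blood_th),
    vessel_wall  = list(cond = wall_cond, thermal = liver_th),
    portal_space = list(cond = conductivity_fun(0.26, factor = 2, e_center = 700, e_width = 400),
                        thermal = liver_th),
    electrode    = list(cond = conductivity_fun(1e6, factor = 1),
                        thermal = thermal_props(density_kg_m3 = 7900,
                                                heat_capacity_J_kgK = 500,
                                                thermal_conductivity_W_mK = 15,
                                                perfusion_per_s = 0))
  ))
}

#' Save a tissue table to a YAML file
#' @param tissues a [tissue_table()].
#' @param path output path.
#' @export
save_tissue_table <- function(tissues, path) {
  stopifnot(inherits(tissues, "tissue_table"))
  out <- list(schema = "ectfield-tissue-table-1")
  out$tissues <- lapply(tissues$entries, function(e) {
    list(sigma0_S_per_m = e$cond$sigma0,
         factor = e$cond$factor,
         e_center_V_per_cm = e$cond$e_center,
         e_width_V_per_cm = e$cond$e_width,
         temp_coeff_per_K = e$cond$temp_coeff,
         density_kg_per_m3 = e$thermal$density_kg_m3,
         heat_capacity_J_per_kgK = e$thermal$heat_capacity_J_kgK,
         thermal_conductivity_W_per_mK = e$thermal$thermal_conductivity_W_mK,
         perfusion_per_s = e$thermal$perfusion_per_s,
         blood_rhoc_J_per_m3K = e$thermal$blood_rhoc_J_m3K,
         arterial_temp_degC = e$thermal$arterial_temp_degC,
         metabolic_heat_W_per_m3 = e$thermal$metabolic_heat_W_m3)
  })
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Load a tissue table from a YAML file
#'
#' Field names carry explicit units (e.g. `sigma0_S_per_m`,
#' `e_center_V_per_cm`). Tissues missing thermal fields fall back to liver
#' defaults with a warning.
#'
#' @param path file written by [save_tissue_table()] (schema
#'   `ectfield-tissue-table-1`).
#' @return a [tissue_table()].
#' @export
load_tissue_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!identical(cfg$schema, "ectfield-tissue-table-1"))
    stopf("unrecognized tissue-table schema: %s", cfg$schema %||% "<missing>")
  if (is.null(cfg$tissues) || !length(cfg$tissues))
    stopf("empty tissue table; required tissues include at least 'liver' (or 'lobule'), 'electrode'")
  entries <- list()
  for (nm in names(cfg$tissues)) {
    t <- cfg$tissues[[nm]]
    for (f in c("sigma0_S_per_m", "factor", "e_center_V_per_cm", "e_width_V_per_cm"))
      if (is.null(t[[f]])) stopf("tissue '%s': missing field '%s'", nm, f)
    if (t$sigma0_S_per_m <= 0) stopf("tissue '%s': sigma0 must be positive", nm)
    cond <- conductivity_fun(t$sigma0_S_per_m, t$factor, t$e_center_V_per_cm,
                             t$e_width_V_per_cm, t$temp_coeff_per_K %||% 0.015)
    if (is.null(t$density_kg_per_m3)) {
      warning(sprintf("tissue '%s': no thermal entries; defaulting to liver values", nm),
              call. = FALSE)
      th <- thermal_props()
    } else {
      th <- thermal_props(t$density_kg_per_m3, t$heat_capacity_J_per_kgK,
                          t$thermal_conductivity_W_per_mK, t$perfusion_per_s,
                          t$blood_rhoc_J_per_m3K, t$arterial_temp_degC,
                          t$metabolic_heat_W_per_m3)
    }
    entries[[nm]] <- list(cond = cond, thermal = th)
  }
  tissue_table(entries)
}
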