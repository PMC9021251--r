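#' Arrhenius thermal-damage kinetic parameters
#'
#' Defaults are standard first-order coagulation kinetics for liver tissue:
#' frequency factor A = 7.39e39 1/s and activation energy
#' E_a = 2.577e5 J/mol. These are configuration, not measured values.
#'
#' @param frequency_factor_per_s A, 1/s (> 0).
#' @param activation_energy_J_mol E_a, J/mol (> 0).
#' @param gas_constant_J_molK R, J/(mol K).
#' @return object of class `arrhenius_params`.
#' @export
arrhenius_params <- function(frequency_factor_per_s = 7.39e39,
                             activation_energy_J_mol = 2.577e5,
                             gas_constant_J_molK = 8.314) {
  check_number(frequency_factor_per_s, "frequency_factor_per_s", lower = 1e-300)
  check_number(activation_energy_J_mol, "activation_energy_J_mol", lower = 1e-12)
  check_number(gas_constant_J_molK, "gas_constant_J_molK", lower = 1e-12)
  structure(list(A = frequency_factor_per_s, Ea = activation_energy_J_mol,
                 R = gas_constant_J_molK), class = "arrhenius_params")
}

arrhenius_rate <- function(T_degC, params) {
  params$A * exp(-params$Ea / (params$R * (T_degC + 273.15)))
}

#' Arrhenius damage integral from a temperature history
#'
#' Integrates the first-order damage rate `A exp(-E_a / (R T))` over time by
#' the trapezoidal rule and converts the damage integral Omega to a damage
#' probability `P = 1 - exp(-Omega)`.
#'
#' @param T_series temperatures in degC: a vector (one node) or a matrix with
#'   one row per node and one column per time point.
#' @param times_s strictly increasing time points, s.
#' @param params an [arrhenius_params()].
#' @return list with `omega` and `probability` (per node).
#' @export
arrhenius_damage <- function(T_series, times_s, params = arrhenius_params()) {
  if (is.vector(T_series)) T_series <- matrix(T_series, nrow = 1L)
  if (ncol(T_series) != length(times_s))
    stopf("temperature series (%d columns) and times (%d) do not match",
          ncol(T_series), length(times_s))
  dt <- diff(times_s)
  if (length(dt) == 0L) stopf("temperature series must cover an interval")
  if (any(dt <= 0)) stopf("time series has gaps or is not increasing")
  rate <- arrhenius_rate(T_series, params)
  nt <- length(times_s)
  omega <- as.numeric((rate[, -nt, drop = FALSE] + rate[, -1L, drop = FALSE]) %*% dt) / 2
  list(omega = omega, probability = 1 - exp(-omega))
}

#' Base-conductivity multiplier from tissue temperature
#'
#' Heating raises the base electrical conductivity of tissue; the multiplier
#' is `1 + temp_coeff * (T - 37)`, clipped below at 1 (cooling below baseline
#' does not reduce the base conductivity).
#'
#' @param T_degC temperature(s), degC.
#' @param temp_coeff fractional change per kelvin (default 0.015).
#' @export
temperature_feedback <- function(T_degC, temp_coeff = 0.015) {
  pmax(1, 1 + temp_coeff * (T_degC - 37))
}

## Incremental duty-cycle bioheat integrator (implicit Euler, P1 elements,
## lumped mass / perfusion / load). Shared by solve_bioheat() and the
## thermally coupled pair sequence.
bioheat_stepper <- function(mesh, tissues, config = list()) {
  baseline <- config$baseline_degC %||% 37
  boundary <- config$boundary %||% "fixed"      # "fixed" or "insulated"
  store_series <- config$store_series %||% TRUE
  smooth_source <- config$smooth_source %||% TRUE
  params <- config$arrhenius %||% arrhenius_params()
  geom <- element_geometry(mesh)
  ## the thermal domain includes the electrode interiors: metal needles have
  ## no Joule source (no field inside a conductor) but conduct heat and act
  ## as heat sinks at the hot electrode-tissue interface
  invert_ids <- vapply(mesh$electrodes, function(e) if (e$invert) e$id else NA_integer_, 1L)
  invert_ids <- invert_ids[!is.na(invert_ids)]
  el_field <- which(mesh$elec_id == 0L)
  el <- which(mesh$elec_id == 0L | !(mesh$elec_id %in% c(0L, invert_ids)))
  field_pos <- match(el_field, el)
  labs <- mesh$label[el]
  th <- lapply(setNames(nm = unique(labs)), function(l) tissue_thermal(tissues, l))
  get_e <- function(f) vapply(labs, function(l) f(th[[l]]), 0, USE.NAMES = FALSE)
  rhoc_e <- get_e(function(t) t$density_kg_m3 * t$heat_capacity_J_kgK)
  k_e    <- get_e(function(t) t$thermal_conductivity_W_mK)
  perf_e <- get_e(function(t) t$perfusion_per_s * t$blood_rhoc_J_m3K)
  tb_e   <- get_e(function(t) t$arterial_temp_degC)
  qm_e   <- get_e(function(t) t$metabolic_heat_W_m3)
  n <- nrow(mesh$nodes)
  tri <- mesh$tri[el, , drop = FALSE]
  a3 <- geom$area[el] / 3                        # m^2
  lump <- function(w) {
    v <- numeric(n)
    for (a in 1:3) v <- v + tabulate2(tri[, a], w, n)
    v
  }
  M <- lump(rhoc_e * a3)
  P <- lump(perf_e * a3)
  f0 <- lump((qm_e + perf_e * tb_e) * a3)
  K <- assemble_stiffness(mesh, geom, k_e, el)
  active_nodes <- sort(unique(as.vector(tri)))
  dom <- mesh$domain; tolb <- 1e-9
  on_outer <- abs(mesh$nodes[, 1] - dom[1]) < tolb | abs(mesh$nodes[, 1] - dom[3]) < tolb |
              abs(mesh$nodes[, 2] - dom[2]) < tolb | abs(mesh$nodes[, 2] - dom[4]) < tolb
  fixed <- if (boundary == "fixed") intersect(active_nodes, which(on_outer)) else integer(0)
  free <- setdiff(active_nodes, fixed)
  Tn <- rep(NA_real_, n)
  Tn[active_nodes] <- baseline
  state <- new.env(parent = emptyenv())
  state$T <- Tn; state$t <- 0
  state$T_max <- Tn
  state$omega <- numeric(n)
  state$rate_prev <- replace(arrhenius_rate(Tn, params), is.na(Tn), 0)
  state$times <- 0
  state$series <- if (store_series) list(Tn) else NULL
  state$fac <- NULL; state$fac_dt <- NA_real_
  advance <- function(power_e, protocol, duration_s = NULL, dt_s = NULL) {
    duration <- duration_s %||% protocol$burst_duration_s
    dt <- dt_s %||% config$dt_s %||% min(10e-3, duration / 4)
    if (dt > duration + 1e-12)
      stopf("time step %.3g s exceeds the %.3g s schedule; use dt <= %.3g s",
            dt, duration, duration / 4)
    nstep <- max(1L, round(duration / dt))
    dt <- duration / nstep
    D <- protocol$duty_cycle
    if (length(power_e) == length(field_pos)) {
      p_full <- numeric(length(el))
      p_full[field_pos] <- power_e
    } else if (length(power_e) == length(el)) {
      p_full <- power_e
    } else stopf("power density has %d values; expected %d (field elements)",
                 length(power_e), length(field_pos))
    ## patch-average the Joule source over edge-neighboring elements: raw P1
    ## gradients are noisy on boundary-snapped triangles, and the noise enters
    ## the source quadratically
    if (smooth_source) {
      if (is.null(state$adj)) {
        adj <- element_adjacency(mesh)[el, el, drop = FALSE]
        state$adj <- adj
        state$adj_area <- as.numeric(adj %*% abs(geom$area[el]))
      }
      p_full <- as.numeric(state$adj %*% (p_full * abs(geom$area[el]))) / state$adj_area
    }
    fsrc <- lump(D * p_full * a3)
    if (is.null(state$fac) || !isTRUE(all.equal(state$fac_dt, dt))) {
      A <- Matrix::Diagonal(n, M / dt + P) + K
      state$Aff <- A[free, free, drop = FALSE]
      state$Afc <- A[free, fixed, drop = FALSE]
      state$fac <- Matrix::Cholesky(Matrix::forceSymmetric(state$Aff), LDL = FALSE, super = NA)
      state$fac_dt <- dt
    }
    for (s in seq_len(nstep)) {
      rhs <- (M / dt)[free] * state$T[free] + f0[free] + fsrc[free]
      if (length(fixed)) rhs <- rhs - as.numeric(state$Afc %*% rep(baseline, length(fixed)))
      Tf <- as.numeric(Matrix::solve(state$fac, rhs))
      state$T[free] <- Tf
      state$T[fixed] <- baseline
      state$t <- state$t + dt
      state$T_max <- pmax(state$T_max, state$T, na.rm = FALSE)
      rate <- replace(arrhenius_rate(state$T, params), is.na(state$T), 0)
      state$omega <- state$omega + (state$rate_prev + rate) / 2 * dt
      state$rate_prev <- rate
      state$times <- c(state$times, state$t)
      if (store_series) state$series[[length(state$series) + 1L]] <- state$T
    }
    invisible(NULL)
  }
  tissue_nodes <- sort(unique(as.vector(mesh$tri[el_field, , drop = FALSE])))
  finish <- function() {
    series <- if (store_series) do.call(cbind, state$series) else NULL
    structure(list(T_final_degC = state$T, T_max_degC = state$T_max,
                   times_s = state$times, T_series_degC = series,
                   omega = state$omega,
                   P_damage = 1 - exp(-state$omega),
                   baseline_degC = baseline, boundary = boundary,
                   arrhenius = params, active_nodes = active_nodes,
                   tissue_nodes = tissue_nodes),
              class = "thermal_solution")
  }
  list(advance = advance, finish = finish,
       temperature = function() replace(state$T, is.na(state$T), baseline))
}

tabulate2 <- function(idx, w, n) {
  v <- numeric(n)
  agg <- rowsum(w, idx)
  v[as.integer(rownames(agg))] <- agg[, 1]
  v
}

#' Duty-cycle Pennes bioheat solution over a pulse schedule
#'
#' Integrates the Pennes bioheat equation
#' `rho c dT/dt = div(k grad T) - w_b (rho c)_b (T - T_b) + Q_m + D p`
#' with implicit Euler time stepping over each pair's burst in sequence
#' (pairs heat cumulatively). The Joule source is the duty-cycle-averaged
#' power density `D p` from the converged stationary field solution of the
#' respective pair.
#'
#' @param mesh an `ect_mesh`.
#' @param tissues a [tissue_table()].
#' @param power_per_pair list of per-element power densities (W/m^3), one per
#'   pair, e.g. `lapply(fs$per_pair, function(p) p$power_W_per_m3)`.
#' @param protocol a [pulse_protocol()].
#' @param config list: `baseline_degC` (37), `boundary` (`"fixed"` at the
#'   outer domain boundary, or `"insulated"`), `dt_s` (default
#'   `min(10 ms, burst/4)`), `gap_s` inter-pair gap (0), `store_series`
#'   (keep the full nodal history; `TRUE`), `arrhenius`
#'   ([arrhenius_params()]).
#' @return object of class `thermal_solution` with nodal temperature history,
#'   per-node maxima, damage integral `omega` and damage probability.
#' @export
solve_bioheat <- function(mesh, tissues, power_per_pair, protocol, config = list()) {
  if (inherits(power_per_pair, "pair_solution"))
    power_per_pair <- list(power_per_pair$power_W_per_m3)
  stopifnot(is.list(power_per_pair), length(power_per_pair) >= 1L)
  gap <- config$gap_s %||% 0
  st <- bioheat_stepper(mesh, tissues, config)
  for (k in seq_along(power_per_pair)) {
    st$advance(power_per_pair[[k]], protocol)
    if (gap > 0 && k < length(power_per_pair)) {
      st$advance(rep(0, length(power_per_pair[[k]])), protocol, duration_s = gap)
    }
  }
  st$finish()
}

#' Maximum temperature / damage probability over tissue nodes
#'
#' Electrode-interior nodes are excluded (the needle itself is not tissue);
#' the electrode-tissue interface nodes count as tissue.
#'
#' @param thermal a `thermal_solution`.
#' @return named numeric: maximum, and the node index attaining it.
#' @export
max_tissue_temperature <- function(thermal) {
  v <- thermal$T_max_degC[thermal$tissue_nodes]
  i <- which.max(v)
  c(T_max_degC = v[i], node = thermal$tissue_nodes[i])
}

#' @rdname max_tissue_temperature
#' @export
max_tissue_damage <- function(thermal) {
  v <- thermal$P_damage[thermal$tissue_nodes]
  i <- which.max(v)
  c(P_max = v[i], node = thermal$tissue_nodes[i])
}

#' @export
print.thermal_solution <- function(x, ...) {
  cat(sprintf("<thermal_solution: %d time points over %.4g s, max T %.2f degC, max damage P %.3g%%>\n",
              length(x$times_s), max(x$times_s), max(x$T_max_degC, na.rm = TRUE),
              100 * max(x$P_damage)))
  invisible(x)
}
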