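## Nonlinear steady-state potential solver.
##
## First-order (P1) triangular finite elements on the meshes built by
## triangulate(). The potential problem div(sigma(|grad u|, T) grad u) = 0 is
## solved with Dirichlet conditions on the active electrode boundaries (u = U
## on the anode, 0 on the cathode), zero normal flux on the outer boundary and
## on inactive electrodes (whose interiors are excluded from the domain). The
## field dependence of sigma is resolved by Picard (fixed-point) iteration
## with under-relaxation on the conductivity update.

## Per-element P1 geometry factors. Coordinates converted mm -> m so that
## assembled quantities are SI (fields in V/m, power in W/m^3 per unit depth).
element_geometry <- function(mesh) {
  nodes <- mesh$nodes * 1e-3
  tri <- mesh$tri
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  area <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  ## gradients of barycentric shape functions: grad N_i = (b_i, c_i)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / (2 * area)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / (2 * area)
  list(area = area, b = b, c = cc)
}

## Sparse stiffness matrix for conductivity sigma_e on elements `el`.
assemble_stiffness <- function(mesh, geom, sigma_e, el) {
  tri <- mesh$tri[el, , drop = FALSE]
  w <- sigma_e * geom$area[el]
  b <- geom$b[el, , drop = FALSE]; cc <- geom$c[el, , drop = FALSE]
  n <- nrow(mesh$nodes)
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (bb in 1:3) {
    k <- k + 1L
    ii[[k]] <- tri[, a]; jj[[k]] <- tri[, bb]
    xx[[k]] <- w * (b[, a] * b[, bb] + cc[, a] * cc[, bb])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

## Element-wise field magnitude (V/m) and gradient from nodal potential.
element_field <- function(mesh, geom, u, el) {
  tri <- mesh$tri[el, , drop = FALSE]
  ex <- geom$b[el, 1] * u[tri[, 1]] + geom$b[el, 2] * u[tri[, 2]] + geom$b[el, 3] * u[tri[, 3]]
  ey <- geom$c[el, 1] * u[tri[, 1]] + geom$c[el, 2] * u[tri[, 2]] + geom$c[el, 3] * u[tri[, 3]]
  sqrt(ex^2 + ey^2)
}

#' Solve the potential problem for one electrode pair
#'
#' Picard iteration on the field-dependent conductivity: each iteration solves
#' the linear potential problem with the previous iterate's per-element
#' conductivity, then updates `sigma` with under-relaxation until the relative
#' L2 change of the element field magnitudes drops below `tol`.
#'
#' @param mesh an `ect_mesh`.
#' @param tissues a [tissue_table()] covering every element label.
#' @param anode,cathode electrode ids present in the mesh.
#' @param U applied voltage, V (anode at `U`, cathode at 0).
#' @param T_nodal nodal temperature field in degC, or a single value
#'   (default 37). Values below 37 do not reduce the base conductivity.
#' @param control list of solver controls: `tol` (default 1e-3), `max_iter`
#'   (100), `relax` (0.5).
#' @return object of class `pair_solution`: nodal potential `u` (V, NA on
#'   nodes outside the conducting domain), per-element `E_V_per_cm`,
#'   `power_W_per_m3`, `sigma_S_per_m`, iteration diagnostics, and the
#'   anode/cathode currents (A per metre of needle length).
#' @export
solve_pair <- function(mesh, tissues, anode, cathode, U, T_nodal = 37,
                       control = list()) {
  stopifnot(inherits(mesh, "ect_mesh"), inherits(tissues, "tissue_table"))
  if (anode == cathode) stopf("anode and cathode must differ")
  an <- mesh$electrode_nodes[[as.character(anode)]]
  ca <- mesh$electrode_nodes[[as.character(cathode)]]
  if (is.null(an) || is.null(ca)) stopf("anode/cathode id not present in mesh")
  check_number(U, "U", lower = 1e-12)
  tol <- control$tol %||% 1e-3
  max_iter <- control$max_iter %||% 100L
  relax <- control$relax %||% 0.5
  geom <- element_geometry(mesh)
  el <- which(mesh$elec_id == 0L)
  labs <- mesh$label[el]
  conds <- lapply(setNames(nm = unique(labs)), function(l) tissue_cond(tissues, l))
  ## per-element effective temperature (clipped at baseline: heating raises the
  ## base conductivity, cooling below 37 does not reduce it)
  if (length(T_nodal) == 1L) {
    T_e <- rep(max(T_nodal, 37), length(el))
  } else {
    stopifnot(length(T_nodal) == nrow(mesh$nodes))
    tri <- mesh$tri[el, , drop = FALSE]
    T_e <- pmax((T_nodal[tri[, 1]] + T_nodal[tri[, 2]] + T_nodal[tri[, 3]]) / 3, 37)
  }
  uniformly_linear <- all(vapply(conds, function(f) f$factor == 1, TRUE))
  n <- nrow(mesh$nodes)
  free_nodes <- setdiff(unique(as.vector(mesh$tri[el, ])), c(an, ca))
  fixed <- c(an, ca)
  u_fix <- c(rep(U, length(an)), rep(0, length(ca)))
  E_cm <- rep(0, length(el))
  sigma_e <- numeric(length(el))
  for (l in unique(labs)) {
    m <- labs == l
    sigma_e[m] <- sigma_of_E(conds[[l]], 0, T_e[m])
  }
  residuals <- numeric(0)
  E_prev <- NULL
  chol_fac <- NULL
  K <- NULL
  for (it in seq_len(max_iter)) {
    K <- assemble_stiffness(mesh, geom, sigma_e, el)
    Kff <- K[free_nodes, free_nodes, drop = FALSE]
    rhs <- -K[free_nodes, fixed, drop = FALSE] %*% u_fix
    if (is.null(chol_fac)) {
      chol_fac <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE, super = NA)
    } else {
      chol_fac <- Matrix::update(chol_fac, Matrix::forceSymmetric(Kff))
    }
    uf <- as.numeric(Matrix::solve(chol_fac, rhs))
    u <- rep(NA_real_, n)
    u[fixed] <- u_fix
    u[free_nodes] <- uf
    E_SI <- element_field(mesh, geom, u, el)     # V/m
    E_cm <- E_SI * 0.01                          # V/cm
    if (!is.null(E_prev)) {
      res <- sqrt(sum((E_cm - E_prev)^2)) / max(sqrt(sum(E_prev^2)), 1e-30)
      ## damp the sigma update adaptively: a rising residual signals the
      ## period-2 oscillation typical of steep sigma(E) transitions
      if (length(residuals) && res > residuals[length(residuals)])
        relax <- max(0.05, relax * 0.5)
      residuals <- c(residuals, res)
      if (res < tol) { E_prev <- E_cm; break }
    }
    E_prev <- E_cm
    if (uniformly_linear && it >= 2L) break
    s_new <- numeric(length(el))
    for (l in unique(labs)) {
      m <- labs == l
      s_new[m] <- sigma_of_E(conds[[l]], E_cm[m], T_e[m])
    }
    sigma_e <- relax * s_new + (1 - relax) * sigma_e
    if (it == max_iter)
      stopf("pair %d-%d: no convergence after %d iterations (last residual %.3g)",
            anode, cathode, max_iter, tail(residuals, 1))
  }
  E_SI <- E_cm * 100
  power <- sigma_e * E_SI^2
  ## electrode currents from the full stiffness residual at Dirichlet nodes
  r <- as.numeric(K %*% replace(u, is.na(u), 0))
  I_anode <- sum(r[an]); I_cathode <- -sum(r[ca])
  structure(list(u = u, elements = el, E_V_per_cm = E_cm,
                 power_W_per_m3 = power, sigma_S_per_m = sigma_e,
                 anode = anode, cathode = cathode, U = U,
                 iterations = length(residuals) + 1L, residuals = residuals,
                 I_anode_A_per_m = I_anode, I_cathode_A_per_m = I_cathode),
            class = "pair_solution")
}

#' @export
print.pair_solution <- function(x, ...) {
  cat(sprintf("<pair %d->%d at %g V: %d elements, %d iterations, |E| max %.0f V/cm, I = %.3g A/m>\n",
              x$anode, x$cathode, x$U, length(x$elements), x$iterations,
              max(x$E_V_per_cm), x$I_anode_A_per_m))
  invisible(x)
}

#' Run an electrode-pair activation sequence
#'
#' Solves the potential problem for every anode-cathode pair in order. Each
#' pair starts from the base (non-electroporated) conductivity — the
#' electroporation-induced conductivity rise does not carry over between
#' pairs, but (with `thermal_feedback = TRUE`) the slower thermal rise does:
#' after each pair the duty-cycle bioheat problem is advanced over that pair's
#' burst and the updated temperature raises the base conductivity for the
#' following pairs. Per-pair field magnitudes are superposed into the final
#' field map, by default as the element-wise maximum.
#'
#' @param mesh an `ect_mesh`.
#' @param tissues a [tissue_table()].
#' @param pairs integer matrix (n x 2) of anode/cathode electrode ids.
#' @param protocol a [pulse_protocol()].
#' @param thermal_feedback couple pair solves to the bioheat solution.
#' @param superposition `"max"` (element-wise maximum of per-pair `|E|`) or
#'   `"sum_potentials"` (field of the summed potentials, for sensitivity
#'   checks).
#' @param bioheat_config see [solve_bioheat()]; used when
#'   `thermal_feedback = TRUE`.
#' @param control solver controls passed to [solve_pair()].
#' @return object of class `field_solution`: list of per-pair solutions,
#'   superposed per-element field `E_V_per_cm`, and (with feedback) the
#'   `thermal` solution.
#' @export
run_pair_sequence <- function(mesh, tissues, pairs, protocol,
                              thermal_feedback = FALSE,
                              superposition = c("max", "sum_potentials"),
                              bioheat_config = list(), control = list()) {
  superposition <- match.arg(superposition)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) < 1L) stopf("pair sequence is empty")
  stopifnot(inherits(protocol, "pulse_protocol"))
  per_pair <- vector("list", nrow(pairs))
  thermal <- NULL
  T_now <- rep(bioheat_config$baseline_degC %||% 37, nrow(mesh$nodes))
  stepper <- if (thermal_feedback) bioheat_stepper(mesh, tissues, bioheat_config) else NULL
  for (k in seq_len(nrow(pairs))) {
    per_pair[[k]] <- solve_pair(mesh, tissues, pairs[k, 1], pairs[k, 2],
                                protocol$voltage_V,
                                T_nodal = if (thermal_feedback) T_now else 37,
                                control = control)
    if (thermal_feedback) {
      stepper$advance(per_pair[[k]]$power_W_per_m3, protocol)
      T_now <- stepper$temperature()
    }
  }
  el <- per_pair[[1]]$elements
  if (superposition == "max") {
    E_sup <- per_pair[[1]]$E_V_per_cm
    for (k in seq_along(per_pair)[-1]) E_sup <- pmax(E_sup, per_pair[[k]]$E_V_per_cm)
  } else {
    u_tot <- rowSums(do.call(cbind, lapply(per_pair, function(p) replace(p$u, is.na(p$u), 0))))
    geom <- element_geometry(mesh)
    E_sup <- element_field(mesh, geom, u_tot, el) * 0.01
  }
  if (thermal_feedback) thermal <- stepper$finish()
  structure(list(mesh = mesh, pairs = pairs, per_pair = per_pair,
                 elements = el, E_V_per_cm = E_sup,
                 superposition = superposition, protocol = protocol,
                 thermal = thermal),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution: %d pair(s), superposition '%s', |E| range %.0f-%.0f V/cm%s>\n",
              nrow(x$pairs), x$superposition, min(x$E_V_per_cm), max(x$E_V_per_cm),
              if (!is.null(x$thermal)) sprintf(", max T %.1f degC", max(x$thermal$T_max_degC, na.rm = TRUE)) else ""))
  invisible(x)
}
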