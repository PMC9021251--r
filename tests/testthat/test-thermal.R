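## small uniform square with no electrodes, for closed-form thermal checks
thermal_fixture <- function(perfusion = 0) {
  regs <- list(rect_region("liver", 0, 0, 10, 10))
  mesh <- triangulate(regs, list(), h_max = 1)
  th <- thermal_props(perfusion_per_s = perfusion)
  tissues <- tissue_table(list(liver = list(cond = conductivity_fun(0.1), thermal = th)))
  list(mesh = mesh, tissues = tissues,
       n_el = sum(mesh$elec_id == 0L))
}

test_that("zero source and zero perfusion keep the temperature constant", {
  fx <- thermal_fixture()
  pro <- pulse_protocol(100, 8, 100e-6, 1)
  sol <- solve_bioheat(fx$mesh, fx$tissues, list(rep(0, fx$n_el)), pro,
                       config = list(boundary = "insulated"))
  expect_true(all(abs(sol$T_final_degC[sol$active_nodes] - 37) < 1e-10))
})

test_that("a constant source in an insulated body heats at q/(rho c)", {
  fx <- thermal_fixture()
  q <- 5e6                        # W/m^3
  pro <- pulse_protocol(100, 8, 100e-6, 1)   # D = 1e-4, 8 s schedule
  sol <- solve_bioheat(fx$mesh, fx$tissues, list(rep(q, fx$n_el)), pro,
                       config = list(boundary = "insulated"))
  rhoc <- 1079 * 3540
  expected <- 37 + pro$duty_cycle * q * 8 / rhoc
  expect_equal(max(sol$T_final_degC, na.rm = TRUE), expected, tolerance = 1e-8)
  expect_equal(min(sol$T_final_degC, na.rm = TRUE), expected, tolerance = 1e-8)
})

test_that("energy is conserved with insulated boundaries and no perfusion", {
  fx <- thermal_fixture()
  set.seed(7)
  p <- runif(fx$n_el, 0, 1e7)     # nonuniform source
  pro <- pulse_protocol(100, 4, 100e-6, 1)
  sol <- solve_bioheat(fx$mesh, fx$tissues, list(p), pro,
                       config = list(boundary = "insulated",
                                     smooth_source = FALSE))
  geom <- ectfield:::element_geometry(fx$mesh)
  area <- abs(geom$area)          # m^2
  rhoc <- 1079 * 3540
  ## nodal heat content via the same lumped mass
  tri <- fx$mesh$tri
  M <- numeric(nrow(fx$mesh$nodes))
  for (a in 1:3) M <- M + ectfield:::tabulate2(tri[, a], rhoc * area / 3, length(M))
  dT <- sol$T_final_degC - 37
  stored <- sum(M * replace(dT, is.na(dT), 0))
  injected <- sum(pro$duty_cycle * p * area) * 4    # 4 s schedule
  expect_equal(stored, injected, tolerance = 0.01)
})

test_that("temperature rise is linear in the duty cycle", {
  fx <- thermal_fixture()
  set.seed(8)
  p <- runif(fx$n_el, 0, 1e7)
  rise <- sapply(c(100e-6, 50e-6), function(dur) {
    pro <- pulse_protocol(100, 8, dur, 1000)
    sol <- solve_bioheat(fx$mesh, fx$tissues, list(p), pro)
    max(sol$T_max_degC, na.rm = TRUE) - 37
  })
  expect_equal(rise[1] / rise[2], 2, tolerance = 0.02)
})

test_that("Arrhenius integration matches the closed form and is additive", {
  par <- arrhenius_params()
  ## constant temperature: Omega = A t exp(-Ea/(RT))
  for (Tc in c(37, 50, 65)) {
    times <- seq(0, 2.4, by = 0.01)
    out <- arrhenius_damage(rep(Tc, length(times)), times, par)
    closed <- par$A * 2.4 * exp(-par$Ea / (par$R * (Tc + 273.15)))
    expect_equal(out$omega, closed, tolerance = 1e-10)
    expect_equal(out$probability, 1 - exp(-closed), tolerance = 1e-10)
  }
  ## 37 degC for 2.4 s (a full hexagonal schedule with gaps): negligible
  ## damage, and exactly the closed-form value (~6e-4 with liver kinetics)
  out <- arrhenius_damage(rep(37, 241), seq(0, 2.4, by = 0.01), par)
  expect_lt(out$probability, 1e-3)
  expect_equal(out$omega, par$A * 2.4 * exp(-par$Ea / (par$R * 310.15)),
               tolerance = 1e-10)
  ## additivity over a split of the series
  set.seed(9)
  Tser <- 37 + cumsum(runif(101, -0.2, 0.4))
  times <- seq(0, 1, length.out = 101)
  whole <- arrhenius_damage(Tser, times, par)$omega
  part1 <- arrhenius_damage(Tser[1:51], times[1:51], par)$omega
  part2 <- arrhenius_damage(Tser[51:101], times[51:101], par)$omega
  expect_equal(whole, part1 + part2, tolerance = 1e-14)
  expect_error(arrhenius_damage(c(37, 38), c(1, 1), par), "gaps")
  expect_error(arrhenius_damage(c(37, 38, 39), c(0, 1), par), "do not match")
})

test_that("damage probability is monotone in exposure time and temperature", {
  par <- arrhenius_params()
  probs_t <- sapply(c(1, 2, 4, 8), function(tend) {
    times <- seq(0, tend, length.out = 50)
    arrhenius_damage(rep(60, 50), times, par)$probability
  })
  expect_true(all(diff(probs_t) > 0))
  probs_T <- sapply(c(45, 55, 65, 75), function(Tc) {
    arrhenius_damage(rep(Tc, 50), seq(0, 1, length.out = 50), par)$probability
  })
  expect_true(all(diff(probs_T) > 0))
})

test_that("temperature feedback multiplies the base conductivity, clipped at 1", {
  expect_equal(temperature_feedback(37), 1)
  expect_equal(temperature_feedback(47, 0.015), 1.15)
  expect_equal(temperature_feedback(30), 1)    # no decrease below baseline
  Ts <- seq(30, 80, by = 2.5)
  expect_true(all(diff(temperature_feedback(Ts)) >= 0))
})

test_that("the burst time step is validated", {
  fx <- thermal_fixture()
  pro <- pulse_protocol(100, 8, 100e-6, 5000)   # 1.6 ms burst
  expect_error(solve_bioheat(fx$mesh, fx$tissues, list(rep(0, fx$n_el)), pro,
                             config = list(dt_s = 0.01)), "time step")
})

test_that("the hot spot of a coupled pair solve sits at the electrode surface", {
  fx <- fx_linear()
  pro <- protocol_presets("linear_ect")
  fs <- run_pair_sequence(fx$mesh, fx$tissues, fx$lay$pairs, pro,
                          thermal_feedback = TRUE,
                          bioheat_config = list(store_series = FALSE))
  mt <- max_tissue_temperature(fs$thermal)
  expect_gt(mt[1], 37)
  node_xy <- fx$mesh$nodes[mt[2], ]
  dist_surface <- min(vapply(fx$mesh$electrodes, function(e)
    abs(sqrt(sum((node_xy - e$center)^2)) - e$diameter / 2), 0))
  ## the steel needle cools the interface, so over the slow 8 s linear
  ## schedule the tissue hot spot sits within a couple of boundary elements
  ## of the electrode surface rather than exactly on it
  expect_lt(dist_surface, 0.5)
})
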