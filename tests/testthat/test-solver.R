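test_that("coaxial electrodes reproduce the closed-form Laplace field", {
  fx <- fx_coax()
  ctr <- ectfield:::element_centroids(fx$mesh)[fx$sol$elements, ]
  r <- sqrt(rowSums(ctr^2))
  ## interior annulus, away from both boundaries
  sel <- r > fx$a + 0.3 & r < fx$b - 0.5
  E_analytic <- fx$U / (r[sel] * log(fx$b / fx$a)) * 10   # V/cm
  err <- abs(fx$sol$E_V_per_cm[sel] - E_analytic) / E_analytic
  expect_lt(median(err), 0.01)
  expect_lt(mean(err), 0.01)
  ## total current against the closed form 2 pi sigma U / ln(b/a)
  I_analytic <- 2 * pi * fx$sigma * fx$U / log(fx$b / fx$a)
  expect_lt(abs(fx$sol$I_anode_A_per_m - I_analytic) / I_analytic, 0.01)
})

test_that("anode and cathode currents balance", {
  fx <- fx_linear()
  I_in <- fx$sol$I_anode_A_per_m
  I_out <- fx$sol$I_cathode_A_per_m
  expect_lt(abs(I_in - I_out) / I_in, 0.005)
  ## independent oracle: integrate sigma E . n over a circle around the anode
  mesh <- fx$mesh; sol <- fx$sol
  geom <- ectfield:::element_geometry(mesh)
  u <- replace(sol$u, is.na(sol$u), 0)
  rho <- 3                        # mm, ring radius around the anode
  nthet <- 2000
  th <- seq(0, 2 * pi, length.out = nthet + 1L)[-1]
  anode_ctr <- fx$lay$electrodes[[1]]$center
  px <- anode_ctr[1] + rho * cos(th); py <- anode_ctr[2] + rho * sin(th)
  eidx <- ectfield:::locate_elements(mesh, px, py)
  full_sigma <- rep(NA_real_, nrow(mesh$tri)); full_sigma[sol$elements] <- sol$sigma_S_per_m
  tri <- mesh$tri[eidx, ]
  ex <- geom$b[eidx, 1] * u[tri[, 1]] + geom$b[eidx, 2] * u[tri[, 2]] + geom$b[eidx, 3] * u[tri[, 3]]
  ey <- geom$c[eidx, 1] * u[tri[, 1]] + geom$c[eidx, 2] * u[tri[, 2]] + geom$c[eidx, 3] * u[tri[, 3]]
  ## current out of the ring: J . n = -sigma grad u . n, ds = rho dtheta (SI)
  flux <- -sum(full_sigma[eidx] * (ex * cos(th) + ey * sin(th))) *
    (rho * 1e-3) * (2 * pi / nthet)
  expect_lt(abs(flux - I_in) / I_in, 0.05)
})

test_that("the potential obeys the maximum principle", {
  fx <- fx_linear()
  u <- fx$sol$u
  expect_gte(min(u, na.rm = TRUE), -1e-9)
  expect_lte(max(u, na.rm = TRUE), 2000 + 1e-9)
  an <- fx$mesh$electrode_nodes[["1"]]; ca <- fx$mesh$electrode_nodes[["2"]]
  expect_equal(max(u, na.rm = TRUE), max(u[an]))
  expect_equal(min(u, na.rm = TRUE), min(u[ca]))
})

test_that("the linear preset delivers ~1000 V/cm along the center line", {
  fx <- fx_linear()
  prof <- cutline_profile(fx$sol, c(-9.2, 0), c(9.2, 0), n = 401, mesh = fx$mesh)
  expect_equal(mean(prof$E_V_per_cm), 1000, tolerance = 0.05)
})

test_that("uniform conductivity scaling leaves the field invariant", {
  e1 <- electrode(c(-2, 0), 0.8, 1L); e2 <- electrode(c(2, 0), 0.8, 2L)
  regs <- list(rect_region("liver", -8, -8, 8, 8))
  mesh <- triangulate(regs, list(e1, e2), h_max = 0.5)
  s1 <- solve_pair(mesh, uniform_liver_table(0.1), 1L, 2L, 100)
  s2 <- solve_pair(mesh, uniform_liver_table(1.0), 1L, 2L, 100)
  expect_equal(s1$E_V_per_cm, s2$E_V_per_cm, tolerance = 1e-9)
  expect_equal(s2$I_anode_A_per_m / s1$I_anode_A_per_m, 10, tolerance = 1e-9)
})

test_that("Picard iteration converges below tolerance and is logged", {
  fx <- fx_linear()
  expect_lt(tail(fx$sol$residuals, 1), 1e-3)
  expect_gte(fx$sol$iterations, 2L)
  expect_error(solve_pair(fx$mesh, fx$tissues, 1L, 2L, 2000,
                          control = list(max_iter = 2L)), "convergence")
  expect_error(solve_pair(fx$mesh, fx$tissues, 1L, 1L, 2000), "differ")
  expect_error(solve_pair(fx$mesh, fx$tissues, 1L, 9L, 2000), "not present")
})

test_that("pair-sequence superposition behaves as an element-wise maximum", {
  fx <- fx_linear()
  pro <- protocol_presets("linear_ect")
  one <- run_pair_sequence(fx$mesh, fx$tissues, fx$lay$pairs, pro)
  expect_equal(one$E_V_per_cm, one$per_pair[[1]]$E_V_per_cm)
  ## duplicating a pair leaves the superposed field unchanged
  two <- run_pair_sequence(fx$mesh, fx$tissues, rbind(fx$lay$pairs, fx$lay$pairs), pro)
  expect_equal(two$E_V_per_cm, one$E_V_per_cm, tolerance = 1e-12)
  ## reversed polarity: same magnitude
  rev1 <- run_pair_sequence(fx$mesh, fx$tissues, fx$lay$pairs[, 2:1, drop = FALSE], pro)
  expect_equal(rev1$E_V_per_cm, one$E_V_per_cm, tolerance = 1e-9)
  expect_error(run_pair_sequence(fx$mesh, fx$tissues,
                                 matrix(integer(0), 0, 2), pro), "empty")
})

test_that("doubling the domain padding barely changes the near field", {
  lay <- place_linear_pair()
  tissues <- uniform_liver_table()
  sols <- lapply(c(3, 6), function(pf) {
    dd <- default_domain(lay$electrodes, pad_factor = pf)
    regs <- list(rect_region("liver", dd[1], dd[2], dd[3], dd[4]))
    mesh <- triangulate(regs, lay$electrodes, h_max = 0.8,
                        h_far = (dd[3] - dd[1]) / 40)
    list(mesh = mesh, sol = solve_pair(mesh, tissues, 1L, 2L, 2000))
  })
  ## compare mean field in a 2 mm annulus around the anode, and total current
  grid <- raster_grid(c(-13, -7), c(-3, 3), 0.1)
  m1 <- export_field(sols[[1]]$sol, grid, mesh = sols[[1]]$mesh)
  m2 <- export_field(sols[[2]]$sol, grid, mesh = sols[[2]]$mesh)
  v1 <- mean(m1$values, na.rm = TRUE); v2 <- mean(m2$values, na.rm = TRUE)
  expect_lt(abs(v1 - v2) / v1, 0.01)
  expect_lt(abs(sols[[1]]$sol$I_anode_A_per_m - sols[[2]]$sol$I_anode_A_per_m) /
              sols[[1]]$sol$I_anode_A_per_m, 0.01)
})

test_that("field rasters sample element values and flag electrodes", {
  fx <- fx_linear()
  grid <- raster_grid(c(-12, 12), c(-6, 6), 0.2)
  ras <- export_field(fx$sol, grid, mesh = fx$mesh)
  expect_s3_class(ras, "ect_raster")
  ## electrode interiors are sentinels
  pc <- ectfield:::pixel_centers(grid)
  ia <- which.min(abs(pc$x + 10)); ja <- which.min(abs(pc$y))
  expect_true(is.na(ras$values[ia, ja]))
  expect_true(ras$electrode[ia, ja])
  ## raster of the superposed field = pixelwise max of per-pair rasters
  pro <- protocol_presets("linear_ect")
  fs <- run_pair_sequence(fx$mesh, fx$tissues, fx$lay$pairs, pro)
  rs <- export_field(fs, grid)
  rp <- export_field(fs$per_pair[[1]], grid, mesh = fx$mesh)
  expect_equal(rs$values, rp$values, tolerance = 1e-12)
  expect_error(export_field(fx$sol, raster_grid(c(-200, 200), c(-5, 5), 1),
                            mesh = fx$mesh), "outside")
})

test_that("rasters and masks round-trip through PGM + sidecar", {
  fx <- fx_case()
  tmp <- withr::local_tempdir()
  write_raster(fx$raster, file.path(tmp, "field"))
  back <- read_raster(file.path(tmp, "field"))
  expect_equal(back$px_mm, fx$raster$px_mm)
  expect_equal(back$origin_mm, fx$raster$origin_mm)
  ok <- !is.na(fx$raster$values)
  expect_lt(max(abs(back$values[ok] - fx$raster$values[ok])),
            diff(range(fx$raster$values, na.rm = TRUE)) / 60000)
  expect_identical(is.na(back$values), is.na(fx$raster$values))
  write_raster(fx$masks$A, file.path(tmp, "zoneA"))
  mback <- read_raster(file.path(tmp, "zoneA"))
  expect_s3_class(mback, "ect_zone_mask")
  expect_identical(mback$values, fx$masks$A$values)
})
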