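test_that("matching septa and CV conductivity reproduces the homogeneous model", {
  lat <- fx_lattice()
  hom <- run_variant("homogeneous", lat$mesh, lat$tissues, 1L, 2L, 365)
  lob <- lat$tissues$entries$lobule$cond
  het_matched <- run_variant("heterogeneous", lat$mesh, lat$tissues, 1L, 2L, 365,
                             septa_override = lob, cv_override = lob)
  expect_equal(het_matched$E_V_per_cm, hom$E_V_per_cm, tolerance = 1e-12)
  ## homogeneous variant equals a genuinely single-tissue table on the same mesh
  tt1 <- lat$tissues
  tt1$entries$septa$cond <- lob; tt1$entries$cv$cond <- lob
  direct <- solve_pair(lat$mesh, tt1, 1L, 2L, 365)
  expect_equal(hom$E_V_per_cm, direct$E_V_per_cm, tolerance = 1e-12)
  expect_error(variant_tissue_table(lat$tissues, "homogeneous",
                                    septa_override = lob), "overrides")
})

test_that("blood-filled CVs depress the field in the lumen", {
  ## compare each CV's lumen field against the lobule tissue immediately
  ## around it (the field varies strongly with position between the
  ## electrodes, so the comparison must be local)
  lat <- fx_lattice()
  het <- run_variant("heterogeneous", lat$mesh, lat$tissues, 1L, 2L, 365)
  ctr <- ectfield:::element_centroids(lat$mesh)[het$elements, ]
  labs <- lat$mesh$label[het$elements]
  centers <- attr(lat$regs, "lobule_centers_mm")
  complete <- attr(lat$regs, "lobule_complete")
  checked <- 0L
  for (k in which(complete)) {
    cc <- centers[k, ]
    if (cc[1] < 0.8 || cc[1] > 2.9) next      # keep CVs between the electrodes
    d <- sqrt((ctr[, 1] - cc[1])^2 + (ctr[, 2] - cc[2])^2)
    cv_sel <- labs == "cv" & d < 0.08
    ring <- labs == "lobule" & d > 0.1 & d < 0.25
    if (!any(cv_sel) || !any(ring)) next
    expect_lt(mean(het$E_V_per_cm[cv_sel]), mean(het$E_V_per_cm[ring]))
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})

test_that("cut-line profiles show septa dips only in the heterogeneous model", {
  lat <- fx_lattice()
  het <- run_variant("heterogeneous", lat$mesh, lat$tissues, 1L, 2L, 365)
  hom <- run_variant("homogeneous", lat$mesh, lat$tissues, 1L, 2L, 365)
  from <- c(0.6, 0.05); to <- c(3.05, 0.05)       # anode to cathode, off-axis
  ph <- cutline_profile(het, from, to, n = 301, mesh = lat$mesh)
  pm <- cutline_profile(hom, from, to, n = 301, mesh = lat$mesh)
  in_septa <- ph$tissue == "septa"
  expect_gt(sum(in_septa), 0)
  ## the heterogeneous profile deviates from the homogeneous one in the septa
  rel <- abs(ph$E_V_per_cm - pm$E_V_per_cm) / pm$E_V_per_cm
  expect_gt(mean(rel[in_septa]), mean(rel[!in_septa]))
  ## doubling the sampling keeps shared points identical
  p2 <- cutline_profile(het, from, to, n = 601, mesh = lat$mesh)
  expect_equal(p2$E_V_per_cm[seq(1, 601, by = 2)], ph$E_V_per_cm,
               tolerance = 1e-12)
  expect_error(cutline_profile(het, c(0, 0), c(50, 0), mesh = lat$mesh),
               "exits the mesh")
})

test_that("relative-error statistics match a brute-force oracle", {
  grid <- list(origin_mm = c(0, 0), px_mm = 1, nx = 8, ny = 8)
  set.seed(13)
  a <- ectfield:::new_raster(matrix(runif(64, 50, 150), 8, 8), grid, "V/cm")
  b <- ectfield:::new_raster(matrix(runif(64, 50, 150), 8, 8), grid, "V/cm")
  s <- relative_error_stats(a, b, exclude_rim_px = 0L)
  r <- numeric(0)
  for (i in 1:8) for (j in 1:8)
    r <- c(r, abs(a$values[i, j] - b$values[i, j]) / b$values[i, j] * 100)
  expect_equal(unname(s["mean_pct"]), mean(r), tolerance = 1e-12)
  expect_equal(unname(s["median_pct"]), median(r), tolerance = 1e-12)
  expect_equal(unname(s["sd_pct"]), sd(r), tolerance = 1e-12)
  expect_equal(unname(relative_error_stats(a, a)[1:3]), c(0, 0, 0))
  a2 <- a; a2$values <- 1.1 * a$values
  s2 <- relative_error_stats(a2, a)
  expect_equal(unname(s2[1:3]), c(10, 10, 0), tolerance = 1e-9)
})

test_that("the default sweep grid has 72 combinations", {
  g <- sweep_grid()
  expect_identical(nrow(g$combos), 72L)
  expect_identical(nrow(g$combos),
                   length(g$fractions) * length(g$factors) *
                     length(g$e_centers) * length(g$e_widths))
})

test_that("the parametric sweep fits thresholds per combination, deterministically", {
  lat <- fx_lattice()
  hom <- run_variant("homogeneous", lat$mesh, lat$tissues, 1L, 2L, 365)
  grid <- raster_grid(c(-1.2, 4.85), c(-2.2, 2.2), 0.05)
  ras <- export_field(hom, grid, mesh = lat$mesh)
  ## synthetic zones from the homogeneous solution (filled isocontours)
  zones <- list(A = zone_mask(field_mask(ras, 850), 0.05, grid$origin_mm, "A"),
                B = zone_mask(field_mask(ras, 480), 0.05, grid$origin_mm, "B"))
  lob <- lat$tissues$entries$lobule$cond
  g <- sweep_grid(fractions = c(0.1, 1, 2),
                  factors = c(lobule = lob$factor),
                  e_centers = c(lobule = lob$e_center),
                  e_widths = c(lobule = lob$e_width))
  sw <- parametric_sweep(g, lat$mesh, lat$tissues, 1L, 2L, 365, zones)
  expect_identical(nrow(sw$results), 3L)
  expect_length(sw$failed, 0L)
  ## fraction 1 with lobule-shaped function == homogeneous thresholds exactly
  row1 <- sw$results[sw$results$fraction == 1, ]
  fa <- fit_threshold(ras, zones$A); fb <- fit_threshold(ras, zones$B)
  expect_identical(row1$zoneA_threshold, fa$best_threshold)
  expect_identical(row1$zoneB_threshold, fb$best_threshold)
  ## Zone B thresholds vary less across septa conductivity than Zone A
  expect_lte(sd(sw$results$zoneB_threshold), sd(sw$results$zoneA_threshold))
  ## bit-identical rerun
  sw2 <- parametric_sweep(g, lat$mesh, lat$tissues, 1L, 2L, 365, zones)
  expect_identical(sw$results, sw2$results)
})

test_that("semi-homogeneous deviates less from homogeneous than heterogeneous", {
  lat <- fx_lattice()
  het <- run_variant("heterogeneous", lat$mesh, lat$tissues, 1L, 2L, 365)
  semi <- run_variant("semi_homogeneous", lat$mesh, lat$tissues, 1L, 2L, 365)
  hom <- run_variant("homogeneous", lat$mesh, lat$tissues, 1L, 2L, 365)
  grid <- raster_grid(c(-1.2, 4.85), c(-2.2, 2.2), 0.05)
  r_het <- export_field(het, grid, mesh = lat$mesh)
  r_semi <- export_field(semi, grid, mesh = lat$mesh)
  r_hom <- export_field(hom, grid, mesh = lat$mesh)
  e_het <- relative_error_stats(r_het, r_hom)["mean_pct"]
  e_semi <- relative_error_stats(r_semi, r_hom)["mean_pct"]
  expect_lte(e_semi, e_het)
})
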