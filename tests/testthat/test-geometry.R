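test_that("lobule lattice tiles the extent with the expected counts", {
  spec <- microstructure_spec(extent_mm = c(0, 0, 10, 10))
  regs <- build_hex_lobule_lattice(spec)
  labs <- vapply(regs, `[[`, "", "label")
  expect_setequal(unique(labs), c("septa", "lobule", "cv"))
  ## ~30 lobule tiles cover 10x10 mm (100 / 3.29 mm^2); at most 23 fit
  ## completely inside (5 columns x 5,4,5,4,5 rows for a centered lattice)
  n_complete <- attr(regs, "n_complete_lobules")
  expect_gte(n_complete, 20)
  expect_lte(n_complete, 35)
  ## lobule regions = complete tiles plus clipped boundary fragments: at
  ## least the equivalent-area count, at most ~1.7x it
  hex_area <- sqrt(3) / 2 * 1.95^2
  n_tiles <- sum(vapply(regs, `[[`, "", "label") == "lobule")
  expect_gte(n_tiles, floor(100 / hex_area))
  expect_lte(n_tiles, ceiling(1.7 * 100 / hex_area))
  ## one CV per complete lobule
  expect_identical(sum(labs == "cv"), as.integer(n_complete))
  ## union of regions tiles the extent (areas: lobule holes carry the CVs,
  ## septa holes carry the lobules, so plain sum = extent area)
  areas <- vapply(regs, ectfield:::region_area, 0)
  expect_equal(sum(areas), 100, tolerance = 1e-6)
  ## lattice pitch is the lobule diameter exactly
  expect_equal(attr(regs, "pitch_mm"), 1.95)
})

test_that("interior lobules have exactly six neighbors at the lattice pitch", {
  spec <- microstructure_spec(extent_mm = c(0, 0, 10, 10))
  regs <- build_hex_lobule_lattice(spec)
  ctr <- attr(regs, "lobule_centers_mm")
  complete <- attr(regs, "lobule_complete")
  pitch <- attr(regs, "pitch_mm")
  d <- as.matrix(dist(ctr))
  neighbors <- rowSums(abs(d - pitch) < 1e-9)
  ## interior = complete lobules whose six neighbor sites are all present
  interior <- complete & neighbors == 6
  expect_gte(sum(interior), 10)
  expect_true(all(neighbors[interior] == 6))
})

test_that("vanishing septum thickness removes the septa area", {
  spec <- microstructure_spec(septum_thickness_um = 0.5,
                              extent_mm = c(0, 0, 6, 6))
  regs <- build_hex_lobule_lattice(spec)
  labs <- vapply(regs, `[[`, "", "label")
  areas <- vapply(regs, ectfield:::region_area, 0)
  frac <- sum(areas[labs == "septa"]) / 36
  expect_lt(frac, 0.002)
})

test_that("septa area fraction agrees with a rasterization oracle", {
  spec <- microstructure_spec(extent_mm = c(0, 0, 4, 4))
  regs <- build_hex_lobule_lattice(spec)
  labs <- vapply(regs, `[[`, "", "label")
  areas <- vapply(regs, ectfield:::region_area, 0)
  frac_geo <- sum(areas[labs == "septa"]) / 16
  ## brute-force pixel classification at 10 um using an independent
  ## point-in-polygon implementation (mgcv::in.out)
  px <- 0.01
  g <- expand.grid(x = seq(px / 2, 4 - px / 2, by = px),
                   y = seq(px / 2, 4 - px / 2, by = px))
  in_lobule <- rep(FALSE, nrow(g))
  for (r in regs[labs == "lobule"]) {
    bnd <- rbind(r$boundary, r$boundary[1, ])
    in_lobule <- in_lobule | mgcv::in.out(bnd, as.matrix(g))
  }
  ## septa = extent minus lobule tiles (CVs are inside lobule tiles)
  frac_px <- 1 - mean(in_lobule)
  expect_lt(abs(frac_px - frac_geo), 0.005)
})

test_that("hexagonal array has 7 electrodes, 12 pairs and exact spacing", {
  arr <- place_hexagonal_array(center = c(0, 0))
  expect_length(arr$electrodes, 7L)
  expect_identical(nrow(arr$pairs), 12L)
  ctr <- do.call(rbind, lapply(arr$electrodes, `[[`, "center"))
  expect_equal(colMeans(ctr), c(0, 0), tolerance = 1e-12)
  ## periphery at 7.3 mm from the center electrode
  d_center <- sqrt(rowSums(ctr[-1, ]^2))
  expect_equal(d_center, rep(7.3, 6), tolerance = 1e-12)
  ## exhaustive pairwise check: every activated pair spans exactly 7.3 mm
  for (k in seq_len(nrow(arr$pairs))) {
    a <- ctr[arr$pairs[k, 1], ]; b <- ctr[arr$pairs[k, 2], ]
    expect_equal(sqrt(sum((a - b)^2)), 7.3, tolerance = 1e-12)
  }
})

test_that("electrode placement is equivariant under rigid motion", {
  arr0 <- place_hexagonal_array(center = c(0, 0))
  arr1 <- place_hexagonal_array(center = c(3, -2), angle_deg = 25)
  ctr0 <- do.call(rbind, lapply(arr0$electrodes, `[[`, "center"))
  ctr1 <- do.call(rbind, lapply(arr1$electrodes, `[[`, "center"))
  expected <- sweep(ectfield:::rotate_points(ctr0, 25), 2, c(3, -2), `+`)
  expect_equal(ctr1, expected, tolerance = 1e-12)
  expect_identical(arr0$pairs, arr1$pairs)
})

test_that("linear pair placement respects spacing, angle and symmetry", {
  p <- place_linear_pair()
  ctr <- do.call(rbind, lapply(p$electrodes, `[[`, "center"))
  expect_equal(sqrt(sum((ctr[1, ] - ctr[2, ])^2)), 20, tolerance = 1e-12)
  expect_equal(p$electrodes[[1]]$diameter, 1.2)
  ## angle 0 vs 180: same set, anode/cathode swapped
  p180 <- place_linear_pair(angle_deg = 180)
  ctr180 <- do.call(rbind, lapply(p180$electrodes, `[[`, "center"))
  expect_equal(ctr180, ctr[2:1, ], tolerance = 1e-12)
  ## angle 90: centers differ only in y
  p90 <- place_linear_pair(angle_deg = 90)
  ctr90 <- do.call(rbind, lapply(p90$electrodes, `[[`, "center"))
  expect_equal(ctr90[, 1], c(0, 0), tolerance = 1e-12)
  expect_equal(sort(ctr90[, 2]), c(-10, 10), tolerance = 1e-12)
})

test_that("triangulation labels, conserves area and refines at electrodes", {
  regs <- list(rect_region("liver", 0, 0, 10, 8))
  mesh <- triangulate(regs, list(), h_max = 1)
  expect_true(all(mesh$label == "liver"))
  expect_equal(mesh_area(mesh), 80, tolerance = 1e-6)

  e <- electrode(c(5, 4), 1, id = 1L)
  m1 <- triangulate(regs, list(e), h_max = 1, refinement = list(electrode = 0.2))
  m2 <- triangulate(regs, list(e), h_max = 1, refinement = list(electrode = 0.1))
  expect_equal(mesh_area(m1), 80, tolerance = 1e-6)
  expect_equal(mesh_area(m2), 80, tolerance = 1e-6)
  n_bnd <- function(m) {
    bn <- m$electrode_nodes[["1"]]
    sum(apply(matrix(m$tri %in% bn, ncol = 3), 1, any) & m$elec_id == 0L)
  }
  ratio <- n_bnd(m2) / n_bnd(m1)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.8)
})

test_that("geometry errors are caught", {
  expect_error(microstructure_spec(cv_diameter_um = 2000), "smaller")
  expect_error(build_hex_lobule_lattice(
    microstructure_spec(extent_mm = c(0, 0, 1, 1))), "at least one lobule")
  expect_error(region("x", rbind(c(0, 0), c(1, 1))), "n >= 3")
  expect_error(region("x", rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
  expect_error(place_hexagonal_array(spacing_mm = 0.5, diameter_mm = 0.7),
               "spacing")
  expect_error(electrode(c(0, 0), -1), "diameter")
})

test_that("geometry configs round-trip through YAML", {
  lat <- fx_lattice()
  path <- withr::local_tempfile(fileext = ".yml")
  save_geometry(lat$regs[1:4], lat$elecs, path, microstructure = lat$spec)
  back <- load_geometry(path)
  expect_length(back$regions, 4L)
  expect_equal(back$regions[[2]]$boundary, lat$regs[[2]]$boundary)
  expect_equal(back$electrodes[[1]]$center, c(0, 0))
  expect_equal(back$microstructure$lobule_diameter_um, 1950)
})

test_that("mesh exports to legacy VTK", {
  regs <- list(rect_region("liver", 0, 0, 2, 2))
  mesh <- triangulate(regs, list(), h_max = 1)
  path <- withr::local_tempfile(fileext = ".vtk")
  export_mesh_vtk(mesh, path, cell_data = list(e = seq_len(nrow(mesh$tri)) * 1.0))
  lines <- readLines(path)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^CELLS", lines)))
  expect_true(any(grepl("SCALARS e double", lines)))
})
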