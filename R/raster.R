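#' Raster grid specification
#'
#' Pixel grid for sampling fields and masks. `origin_mm` is the lower-left
#' corner of pixel (1, 1); pixel centers are at
#' `origin + (i - 1/2) * px_mm`.
#'
#' @param xlim,ylim extents in mm.
#' @param px_mm pixel size in mm.
#' @return list with `origin_mm`, `px_mm`, `nx`, `ny`.
#' @export
raster_grid <- function(xlim, ylim, px_mm) {
  check_number(px_mm, "px_mm", lower = 1e-9)
  nx <- max(1L, round((xlim[2] - xlim[1]) / px_mm))
  ny <- max(1L, round((ylim[2] - ylim[1]) / px_mm))
  list(origin_mm = c(xlim[1], ylim[1]), px_mm = px_mm, nx = nx, ny = ny)
}

pixel_centers <- function(grid) {
  x <- grid$origin_mm[1] + (seq_len(grid$nx) - 0.5) * grid$px_mm
  y <- grid$origin_mm[2] + (seq_len(grid$ny) - 0.5) * grid$px_mm
  list(x = x, y = y)
}

new_raster <- function(values, grid, units, electrode = NULL) {
  structure(list(values = values, px_mm = grid$px_mm,
                 origin_mm = grid$origin_mm, nx = grid$nx, ny = grid$ny,
                 units = units, electrode = electrode),
            class = "ect_raster")
}

#' @export
print.ect_raster <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<ect_raster %dx%d px (%.3g mm/px), %s, range %.4g-%.4g>\n",
              x$nx, x$ny, x$px_mm, x$units, rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.ect_raster <- function(x, main = x$units, ...) {
  pc <- pixel_centers(x)
  graphics::image(pc$x, pc$y, x$values, asp = 1, xlab = "x [mm]", ylab = "y [mm]",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Sample a field solution onto a pixel raster
#'
#' Element values (piecewise constant, first-order elements) are sampled at
#' pixel centers. Pixels inside an electrode are flagged with `NA` and
#' recorded in the raster's electrode mask; they are excluded from downstream
#' statistics (zone masks re-include them, since damage zones enclose the
#' electrode tracks).
#'
#' @param solution a `field_solution`, `pair_solution`, or a numeric vector of
#'   per-element values (then `mesh` and `elements` describe it).
#' @param grid a [raster_grid()]; must lie inside the meshed domain.
#' @param mesh the `ect_mesh` (taken from a `field_solution` automatically).
#' @param what for a `field_solution`/`pair_solution`: `"E"` (superposed field,
#'   V/cm), `"power"` (W/m^3).
#' @param units unit string recorded in the raster.
#' @return an `ect_raster`.
#' @export
export_field <- function(solution, grid, mesh = NULL, what = "E", units = NULL) {
  if (inherits(solution, "field_solution")) {
    mesh <- mesh %||% solution$mesh
    el <- solution$elements
    values_e <- switch(what, E = solution$E_V_per_cm,
                       stopf("unknown field '%s'", what))
    units <- units %||% "V/cm"
  } else if (inherits(solution, "pair_solution")) {
    if (is.null(mesh)) stopf("mesh required for a pair_solution")
    el <- solution$elements
    values_e <- switch(what, E = solution$E_V_per_cm,
                       power = solution$power_W_per_m3,
                       stopf("unknown field '%s'", what))
    units <- units %||% if (what == "E") "V/cm" else "W/m^3"
  } else {
    if (is.null(mesh)) stopf("mesh required")
    el <- which(mesh$elec_id == 0L)
    values_e <- solution
    units <- units %||% "arb"
  }
  stopifnot(length(values_e) == length(el))
  pc <- pixel_centers(grid)
  dom <- mesh$domain
  if (min(pc$x) < dom[1] || max(pc$x) > dom[3] || min(pc$y) < dom[2] || max(pc$y) > dom[4])
    stopf("raster grid extends outside the meshed domain")
  px <- rep(pc$x, times = grid$ny); py <- rep(pc$y, each = grid$nx)
  eidx <- locate_elements(mesh, px, py)
  full <- rep(NA_real_, nrow(mesh$tri))
  full[el] <- values_e
  vals <- matrix(full[eidx], grid$nx, grid$ny)
  elec <- matrix(FALSE, grid$nx, grid$ny)
  for (e in mesh$electrodes) {
    r <- e$diameter / 2
    d2 <- (px - e$center[1])^2 + (py - e$center[2])^2
    inside <- if (e$invert) d2 > r^2 else d2 < r^2
    elec <- elec | matrix(inside, grid$nx, grid$ny)
  }
  vals[elec] <- NA_real_
  new_raster(vals, grid, units, electrode = elec)
}

#' Export per-element field values as CSV
#' @param solution a `pair_solution` or `field_solution`.
#' @param mesh the mesh (optional for `field_solution`).
#' @param path output CSV path.
#' @export
export_field_csv <- function(solution, path, mesh = NULL) {
  if (inherits(solution, "field_solution")) mesh <- mesh %||% solution$mesh
  stopifnot(inherits(mesh, "ect_mesh"))
  el <- solution$elements
  ctr <- element_centroids(mesh)[el, , drop = FALSE]
  df <- data.frame(x_mm = ctr[, 1], y_mm = ctr[, 2], tissue = mesh$label[el],
                   E_V_per_cm = solution$E_V_per_cm)
  if (!is.null(solution$power_W_per_m3)) df$power_W_per_m3 <- solution$power_W_per_m3
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## ---- portable raster I/O: ASCII PGM + YAML sidecar -------------------------

#' Write a raster (or mask) as ASCII PGM with a YAML sidecar
#'
#' Values are linearly scaled to 0..65000; `NA` (electrode/sentinel) pixels
#' are stored as 65535. The sidecar (`<prefix>.yml`) records pixel size,
#' origin, units and the scaling, so the raster round-trips losslessly up to
#' quantization.
#'
#' @param raster an `ect_raster` or `ect_zone_mask`.
#' @param prefix output path prefix (writes `<prefix>.pgm` and
#'   `<prefix>.yml`).
#' @export
write_raster <- function(raster, prefix) {
  is_mask <- inherits(raster, "ect_zone_mask")
  vals <- if (is_mask) raster$values * 1.0 else raster$values
  rng <- range(vals, na.rm = TRUE)
  if (!is.finite(rng[1])) rng <- c(0, 1)
  scale <- if (rng[2] > rng[1]) (rng[2] - rng[1]) / 65000 else 1
  enc <- round((vals - rng[1]) / scale)
  enc[is.na(enc)] <- 65535
  ## PGM row 1 is the top of the image (max y)
  m <- t(enc)[rev(seq_len(ncol(enc))), , drop = FALSE]
  con <- file(paste0(prefix, ".pgm"), "w"); on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", nrow(raster$values), ncol(raster$values)), "65535"), con)
  write(t(m), con, ncolumns = min(20L, nrow(raster$values)))
  yaml::write_yaml(list(schema = "ectfield-raster-1",
                        kind = if (is_mask) "mask" else "field",
                        pixel_size_mm = raster$px_mm,
                        origin_mm = as.numeric(raster$origin_mm),
                        units = if (is_mask) "binary" else raster$units,
                        offset = rng[1], scale = scale, sentinel = 65535,
                        label = raster$label %||% NULL),
                   paste0(prefix, ".yml"), precision = 15)
  invisible(prefix)
}

#' Read a raster written by [write_raster()]
#' @param prefix path prefix used at write time.
#' @return an `ect_raster` or `ect_zone_mask` depending on the sidecar `kind`.
#' @export
read_raster <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yml"))
  if (!identical(meta$schema, "ectfield-raster-1")) stopf("not an ectfield raster sidecar")
  txt <- scan(paste0(prefix, ".pgm"), what = character(), quiet = TRUE, comment.char = "#")
  if (txt[1] != "P2") stopf("only ASCII PGM (P2) is supported")
  nx <- as.integer(txt[2]); ny <- as.integer(txt[3])
  v <- as.numeric(txt[-(1:4)])
  m <- matrix(v, ny, nx, byrow = TRUE)          # row 1 = top
  vals <- t(m[rev(seq_len(ny)), , drop = FALSE])
  sent <- vals == meta$sentinel
  vals <- vals * meta$scale + meta$offset
  vals[sent] <- NA_real_
  grid <- list(origin_mm = meta$origin_mm, px_mm = meta$pixel_size_mm, nx = nx, ny = ny)
  if (identical(meta$kind, "mask")) {
    zone_mask(!is.na(vals) & vals > 0.5, meta$pixel_size_mm, meta$origin_mm,
              label = meta$label %||% "A")
  } else {
    new_raster(vals, grid, meta$units, electrode = if (any(sent)) sent else NULL)
  }
}
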