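#' Binary damage-zone mask
#'
#' A filled binary raster of a histological damage zone (Zone A: coagulation
#' necrosis around the electrode tracks; Zone B: partially damaged parenchyma
#' attributed to IRE). Zone masks are filled regions: they include the
#' electrode-track interiors, and a Zone B mask includes the Zone A area.
#'
#' @param values logical matrix (nx x ny), pixel (1,1) at the lower-left.
#' @param px_mm pixel size, mm.
#' @param origin_mm lower-left corner of pixel (1,1), mm.
#' @param label zone label, `"A"` or `"B"`.
#' @return object of class `ect_zone_mask`.
#' @export
zone_mask <- function(values, px_mm, origin_mm = c(0, 0), label = "A") {
  stopifnot(is.matrix(values))
  mode(values) <- "logical"
  if (!any(values)) stopf("zone mask has no true pixels")
  check_number(px_mm, "px_mm", lower = 1e-12)
  structure(list(values = values, px_mm = px_mm,
                 origin_mm = as.numeric(origin_mm),
                 nx = nrow(values), ny = ncol(values), label = label),
            class = "ect_zone_mask")
}

#' @export
print.ect_zone_mask <- function(x, ...) {
  cat(sprintf("<zone mask '%s': %dx%d px (%.3g mm/px), %d true pixels (%.3g mm^2)>\n",
              x$label, x$nx, x$ny, x$px_mm, sum(x$values),
              sum(x$values) * x$px_mm^2))
  invisible(x)
}

mask_values <- function(m) {
  if (inherits(m, "ect_zone_mask")) m$values else if (is.matrix(m)) m else
    stopf("expected a zone mask or a logical matrix")
}

#' Sorensen-Dice similarity coefficient
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`: 1 for perfectly matching masks,
#' 0 for disjoint ones.
#'
#' @param a,b binary masks ([zone_mask()] or logical matrices) on the same
#'   pixel grid.
#' @return similarity in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  A <- mask_values(a); B <- mask_values(b)
  if (!all(dim(A) == dim(B))) stopf("mask shapes differ: %dx%d vs %dx%d",
                                    nrow(A), ncol(A), nrow(B), ncol(B))
  nA <- sum(A); nB <- sum(B)
  if (nA + nB == 0L) stopf("both masks are empty")
  2 * sum(A & B) / (nA + nB)
}

#' Threshold a field raster into a binary field mask
#'
#' A pixel is true iff the field magnitude is at least `threshold`.
#' Electrode-interior pixels are true as well: the damage zones are filled
#' regions that enclose the electrode tracks.
#'
#' @param raster an `ect_raster` of `|E|` in V/cm.
#' @param threshold field threshold, V/cm (> 0).
#' @return logical matrix of the raster's shape.
#' @export
field_mask <- function(raster, threshold) {
  stopifnot(inherits(raster, "ect_raster"))
  check_number(threshold, "threshold", lower = 1e-12)
  m <- !is.na(raster$values) & raster$values >= threshold
  if (!is.null(raster$electrode)) m <- m | raster$electrode
  m
}

#' Fit the electric-field threshold of a damage zone
#'
#' Sweeps thresholds over the field raster (default 300 to 1500 V/cm in steps
#' of 10, i.e. 121 field masks), computes the Sorensen-Dice coefficient
#' between each field mask and the zone mask, and selects the threshold with
#' the highest DSC. Exact ties are broken toward the lowest threshold
#' (deterministic and conservative: the larger treated area).
#'
#' @param raster an `ect_raster` of `|E|` in V/cm, on the zone-mask grid.
#' @param zone a [zone_mask()].
#' @param thresholds sweep thresholds, V/cm.
#' @return object of class `threshold_fit` with the DSC curve and the
#'   best-fit threshold.
#' @export
fit_threshold <- function(raster, zone, thresholds = seq(300, 1500, by = 10)) {
  stopifnot(inherits(raster, "ect_raster"), inherits(zone, "ect_zone_mask"))
  if (raster$nx != zone$nx || raster$ny != zone$ny)
    stopf("raster (%dx%d) and zone mask (%dx%d) are not on the same grid",
          raster$nx, raster$ny, zone$nx, zone$ny)
  if (abs(raster$px_mm - zone$px_mm) > 1e-9)
    stopf("raster and zone mask pixel sizes differ")
  Z <- zone$values
  nZ <- sum(Z)
  v <- raster$values
  elec <- raster$electrode
  if (is.null(elec)) elec <- matrix(FALSE, raster$nx, raster$ny)
  vv <- v[!elec]; zz <- Z[!elec]
  n_elec <- sum(elec); n_elec_z <- sum(elec & Z)
  ok <- !is.na(vv)
  vv <- vv[ok]; zz <- zz[ok]
  d <- vapply(thresholds, function(t) {
    sel <- vv >= t
    nF <- sum(sel) + n_elec
    nI <- sum(sel & zz) + n_elec_z
    if (nF + nZ == 0L) return(0)
    2 * nI / (nF + nZ)
  }, 0)
  best <- which.max(d)
  tie <- sum(abs(d - d[best]) < 1e-15) > 1L
  structure(list(thresholds = thresholds, dsc = d,
                 best_threshold = thresholds[best], best_dsc = d[best],
                 tie = tie, zone_label = zone$label),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("Zone %s electric-field threshold fit\n", x$zone_label))
  cat(sprintf("  sweep: %g-%g V/cm in %d steps\n", min(x$thresholds),
              max(x$thresholds), length(x$thresholds)))
  cat(sprintf("  best threshold: %g V/cm (DSC = %.3f)%s\n", x$best_threshold,
              x$best_dsc, if (x$tie) " [tie; lowest threshold reported]" else ""))
  invisible(x)
}

#' @export
summary.threshold_fit <- function(object, ...) {
  cat(sprintf("Zone %s threshold fit over %d thresholds\n",
              object$zone_label, length(object$thresholds)))
  cat(sprintf("  best: %g V/cm, DSC %.4f\n", object$best_threshold, object$best_dsc))
  q <- stats::quantile(object$dsc, c(0, .25, .5, .75, 1))
  cat("  DSC curve quantiles:\n")
  print(round(q, 4))
  invisible(object)
}

#' @export
coef.threshold_fit <- function(object, ...) {
  c(threshold_V_per_cm = object$best_threshold, dsc = object$best_dsc)
}

#' @export
plot.threshold_fit <- function(x, ...) {
  plot(x$thresholds, x$dsc, type = "l", xlab = "threshold [V/cm]",
       ylab = "DSC", main = sprintf("Zone %s", x$zone_label), ...)
  graphics::abline(v = x$best_threshold, lty = 2)
  invisible(x)
}

#' Export a DSC curve as CSV
#' @param fit a `threshold_fit`.
#' @param path output path.
#' @export
export_dsc_curve <- function(fit, path) {
  write.csv(data.frame(threshold_V_per_cm = fit$thresholds, dsc = fit$dsc),
            path, row.names = FALSE)
  invisible(path)
}

#' Search the counter-electrode angle of a linear pair
#'
#' When only one electrode of a linear pair is visible in a section, the
#' counter electrode is found by rotating it around the first electrode at
#' the pair spacing in fixed angular steps, solving the field for each
#' candidate position, fitting the Zone A and Zone B thresholds, and keeping
#' the angle with the best composite DSC (by default the sum of the two
#' zones' best DSCs). Exact ties go to the lowest angle.
#'
#' @param first_center visible electrode center, mm.
#' @param zones list with zone masks `A` and `B` (grid defines the raster).
#' @param tissues a [tissue_table()].
#' @param protocol a [pulse_protocol()] (its voltage drives the solves).
#' @param regions optional tissue regions; default homogeneous liver on a
#'   padded domain.
#' @param spacing_mm pair spacing (default 20).
#' @param diameter_mm electrode diameter (default 1.2).
#' @param angle_step_deg angular step (default 5, i.e. 72 candidates).
#' @param h_mm mesh size for the candidate solves.
#' @param objective `"sum"` (Zone A + Zone B best DSC) or `"zoneB"`.
#' @param thresholds sweep passed to [fit_threshold()].
#' @param control solver controls.
#' @return list: `best_angle_deg`, `fits` (threshold fits at the best angle),
#'   `table` (data frame angle/objective/fitted thresholds), `failed` angles.
#' @export
search_counter_electrode <- function(first_center, zones, tissues, protocol,
                                     regions = NULL, spacing_mm = 20,
                                     diameter_mm = 1.2, angle_step_deg = 5,
                                     h_mm = 1, objective = c("sum", "zoneB"),
                                     thresholds = seq(300, 1500, by = 10),
                                     control = list()) {
  objective <- match.arg(objective)
  stopifnot(inherits(zones$A, "ect_zone_mask"), inherits(zones$B, "ect_zone_mask"))
  angles <- seq(0, 360 - angle_step_deg, by = angle_step_deg)
  grid <- list(origin_mm = zones$A$origin_mm, px_mm = zones$A$px_mm,
               nx = zones$A$nx, ny = zones$A$ny)
  rows <- list(); failed <- numeric(0)
  best <- NULL; best_obj <- -Inf; best_fits <- NULL
  for (ang in angles) {
    res <- tryCatch({
      a <- ang * pi / 180
      second <- first_center + spacing_mm * c(cos(a), sin(a))
      elecs <- list(electrode(first_center, diameter_mm, id = 1L),
                    electrode(second, diameter_mm, id = 2L))
      dd <- default_domain(elecs)
      regs <- regions %||% list(rect_region("liver", dd[1], dd[2], dd[3], dd[4]))
      mesh <- triangulate(regs, elecs, h_max = h_mm,
                          h_far = max(h_mm, (dd[3] - dd[1]) / 40))
      sol <- solve_pair(mesh, tissues, 1L, 2L, protocol$voltage_V, control = control)
      ras <- export_field(sol, grid, mesh = mesh)
      fa <- fit_threshold(ras, zones$A, thresholds)
      fb <- fit_threshold(ras, zones$B, thresholds)
      list(fa = fa, fb = fb)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("angle %g deg skipped: %s", ang, conditionMessage(res)), call. = FALSE)
      failed <- c(failed, ang)
      next
    }
    obj <- switch(objective, sum = res$fa$best_dsc + res$fb$best_dsc,
                  zoneB = res$fb$best_dsc)
    rows[[length(rows) + 1L]] <- data.frame(
      angle_deg = ang, objective = obj,
      zoneA_threshold = res$fa$best_threshold, zoneA_dsc = res$fa$best_dsc,
      zoneB_threshold = res$fb$best_threshold, zoneB_dsc = res$fb$best_dsc)
    if (obj > best_obj + 1e-15) {
      best_obj <- obj; best <- ang; best_fits <- res
    }
  }
  if (is.null(best)) stopf("counter-electrode search failed at every angle")
  list(best_angle_deg = best, fits = best_fits, table = do.call(rbind, rows),
       failed = failed)
}
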