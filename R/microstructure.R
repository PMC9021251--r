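#' Tissue-model variant of the microstructure study
#'
#' The microstructure comparison runs three tissue models on the *same*
#' lobule-lattice mesh (so meshing error cancels): heterogeneous (lobules,
#' interlobular septa and blood-filled centrilobular veins each with their own
#' conductivity), semi-homogeneous (septa matched to lobule conductivity, CVs
#' kept) and fully homogeneous (septa and CVs both matched to the lobules).
#'
#' @param tissues base [tissue_table()] (must contain `lobule`, `septa`, `cv`).
#' @param variant `"heterogeneous"`, `"semi_homogeneous"` or `"homogeneous"`.
#' @param septa_override optional [conductivity_fun()] replacing the septa
#'   entry (heterogeneous only; used by the parametric sweep).
#' @param cv_override optional [conductivity_fun()] for the CV lumen.
#' @return a [tissue_table()] for the requested variant.
#' @export
variant_tissue_table <- function(tissues, variant = c("heterogeneous",
                                                      "semi_homogeneous",
                                                      "homogeneous"),
                                 septa_override = NULL, cv_override = NULL) {
  variant <- match.arg(variant)
  e <- tissues$entries
  for (lab in c("lobule", "septa", "cv"))
    if (is.null(e[[lab]])) stopf("tissue table lacks the '%s' entry", lab)
  if (variant != "heterogeneous" && (!is.null(septa_override) || !is.null(cv_override)))
    stopf("conductivity overrides only apply to the heterogeneous variant")
  lob <- e$lobule$cond
  if (variant %in% c("semi_homogeneous", "homogeneous")) e$septa$cond <- lob
  if (variant == "homogeneous") e$cv$cond <- lob
  if (variant == "heterogeneous") {
    if (!is.null(septa_override)) e$septa$cond <- septa_override
    if (!is.null(cv_override)) e$cv$cond <- cv_override
  }
  tissue_table(e)
}

#' Solve one microstructure variant
#'
#' @param variant see [variant_tissue_table()].
#' @param mesh lobule-lattice `ect_mesh` (identical for all variants).
#' @param tissues base tissue table.
#' @param anode,cathode electrode ids.
#' @param U applied voltage, V.
#' @param septa_override,cv_override see [variant_tissue_table()].
#' @param control solver controls.
#' @return a `pair_solution`.
#' @export
run_variant <- function(variant, mesh, tissues, anode, cathode, U,
                        septa_override = NULL, cv_override = NULL,
                        control = list()) {
  tt <- variant_tissue_table(tissues, variant, septa_override, cv_override)
  solve_pair(mesh, tt, anode, cathode, U, control = control)
}

## binary dilation of a logical matrix by `r` pixels (Chebyshev ball)
dilate_mask <- function(m, r = 1L) {
  if (r < 1L) return(m)
  out <- m
  nx <- nrow(m); ny <- ncol(m)
  for (k in seq_len(r)) {
    p <- out
    out[-1, ] <- out[-1, ] | p[-nx, ]
    out[-nx, ] <- out[-nx, ] | p[-1, ]
    out[, -1] <- out[, -1] | p[, -ny]
    out[, -ny] <- out[, -ny] | p[, -1]
  }
  out
}

#' Pixel-wise relative error between two field rasters
#'
#' Computes `r = |a - b| / b` per pixel over the common valid pixels,
#' excluding electrode interiors plus a safety rim (the field is nearly
#' singular at the electrode boundary, so boundary pixels would dominate the
#' statistics), and returns mean, median and standard deviation in percent.
#'
#' @param a,b `ect_raster`s on the same grid; `b` is the reference and must be
#'   strictly positive on evaluated pixels.
#' @param exclude_rim_px electrode-rim exclusion width in pixels (default 1).
#' @return named numeric: `mean_pct`, `median_pct`, `sd_pct`, `n_pixels`.
#' @export
relative_error_stats <- function(a, b, exclude_rim_px = 1L) {
  stopifnot(inherits(a, "ect_raster"), inherits(b, "ect_raster"))
  if (a$nx != b$nx || a$ny != b$ny) stopf("rasters are not on the same grid")
  excl <- matrix(FALSE, a$nx, a$ny)
  for (r in list(a, b)) if (!is.null(r$electrode)) excl <- excl | r$electrode
  excl <- dilate_mask(excl, exclude_rim_px) | is.na(a$values) | is.na(b$values)
  av <- a$values[!excl]; bv <- b$values[!excl]
  ok <- bv > 0
  if (!any(ok)) stopf("no pixels available for relative-error evaluation")
  r <- abs(av[ok] - bv[ok]) / bv[ok] * 100
  c(mean_pct = mean(r), median_pct = median(r), sd_pct = sd(r), n_pixels = sum(ok))
}

#' Field profile along a cut line
#'
#' Samples the element-wise field magnitude at `n` uniformly spaced points on
#' the segment from `from` to `to` (mm). Crossing an interlobular septum
#' shows up as a local plateau of reduced field; crossing a centrilobular
#' vein as a spike at the lumen edge followed by a drop inside.
#'
#' @param solution a `pair_solution` or `field_solution`.
#' @param from,to segment endpoints, mm.
#' @param n number of sample points.
#' @param mesh the mesh (optional for a `field_solution`).
#' @return data frame with `s_mm` (arc length), `x_mm`, `y_mm`, `E_V_per_cm`,
#'   `tissue`.
#' @export
cutline_profile <- function(solution, from, to, n = 200L, mesh = NULL) {
  if (inherits(solution, "field_solution")) mesh <- mesh %||% solution$mesh
  stopifnot(inherits(mesh, "ect_mesh"))
  t <- seq(0, 1, length.out = n)
  px <- from[1] + t * (to[1] - from[1])
  py <- from[2] + t * (to[2] - from[2])
  eidx <- locate_elements(mesh, px, py)
  if (anyNA(eidx)) stopf("cut line exits the mesh")
  full <- rep(NA_real_, nrow(mesh$tri))
  full[solution$elements] <- solution$E_V_per_cm
  data.frame(s_mm = t * sqrt(sum((to - from)^2)), x_mm = px, y_mm = py,
             E_V_per_cm = full[eidx], tissue = mesh$label[eidx])
}

#' Parametric sweep grid over the septa conductivity function
#'
#' The septa base conductivity is expressed as a fraction of the lobule base
#' conductivity; the factor of conductivity increase and the center/width of
#' the transition zone take candidate values (conventionally those of the
#' lobule and of the vessel wall). The default grid is a documented stand-in
#' sized to 72 combinations: 9 base-conductivity fractions x 2 factors x 2
#' centers x 2 widths.
#'
#' @param fractions septa sigma0 as fractions of lobule sigma0.
#' @param factors candidate conductivity-increase factors.
#' @param e_centers candidate transition centers, V/cm.
#' @param e_widths candidate transition widths, V/cm.
#' @return object of class `sweep_grid` with a `combos` data frame.
#' @export
sweep_grid <- function(fractions = c(0.1, 0.2, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2),
                       factors = c(lobule = 3.5, vessel_wall = 2),
                       e_centers = c(lobule = 580, vessel_wall = 700),
                       e_widths = c(lobule = 240, vessel_wall = 400)) {
  combos <- expand.grid(fraction = fractions, factor = unname(factors),
                        e_center = unname(e_centers), e_width = unname(e_widths),
                        KEEP.OUT.ATTRS = FALSE)
  structure(list(fractions = fractions, factors = factors,
                 e_centers = e_centers, e_widths = e_widths, combos = combos),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("<sweep_grid: %d combinations (%d fractions x %d factors x %d centers x %d widths)>\n",
              nrow(x$combos), length(x$fractions), length(x$factors),
              length(x$e_centers), length(x$e_widths)))
  invisible(x)
}

#' Septa-conductivity parametric sweep
#'
#' For every combination in the grid, solves the heterogeneous variant with
#' the septa conductivity set accordingly, rasterizes the field, and fits the
#' Zone A and Zone B thresholds against the supplied masks. Failed
#' combinations are recorded and excluded from the summary.
#'
#' @param grid a [sweep_grid()].
#' @param mesh lobule-lattice mesh.
#' @param tissues base tissue table.
#' @param anode,cathode electrode ids of the active pair.
#' @param U applied voltage, V.
#' @param zones list of zone masks `A` and `B` (their grid is used for
#'   rasterization).
#' @param thresholds sweep for [fit_threshold()].
#' @param control solver controls.
#' @return object of class `sweep_result`: `results` (one row per
#'   combination), `summary` (per-zone median/mean/range/sd), `failed`.
#' @export
parametric_sweep <- function(grid, mesh, tissues, anode, cathode, U, zones,
                             thresholds = seq(300, 1500, by = 10),
                             control = list()) {
  stopifnot(inherits(grid, "sweep_grid"))
  lob <- tissue_cond(tissues, "lobule")
  rgrid <- list(origin_mm = zones$A$origin_mm, px_mm = zones$A$px_mm,
                nx = zones$A$nx, ny = zones$A$ny)
  combos <- grid$combos
  rows <- vector("list", nrow(combos))
  failed <- character(0)
  for (k in seq_len(nrow(combos))) {
    cb <- combos[k, ]
    res <- tryCatch({
      septa <- conductivity_fun(cb$fraction * lob$sigma0, cb$factor,
                                cb$e_center, cb$e_width, lob$temp_coeff)
      sol <- run_variant("heterogeneous", mesh, tissues, anode, cathode, U,
                         septa_override = septa, control = control)
      ras <- export_field(sol, rgrid, mesh = mesh)
      fa <- fit_threshold(ras, zones$A, thresholds)
      fb <- fit_threshold(ras, zones$B, thresholds)
      cbind(cb, data.frame(zoneA_threshold = fa$best_threshold,
                           zoneA_dsc = fa$best_dsc,
                           zoneB_threshold = fb$best_threshold,
                           zoneB_dsc = fb$best_dsc))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("combination %d: %s", k, conditionMessage(res)))
    } else rows[[k]] <- res
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  summarize <- function(v) c(median = median(v), mean = mean(v),
                             min = min(v), max = max(v), sd = sd(v))
  summ <- rbind(zoneA = summarize(results$zoneA_threshold),
                zoneB = summarize(results$zoneB_threshold))
  structure(list(results = results, summary = summ, failed = failed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %d combinations (%d failed)>\n",
              nrow(x$results), length(x$failed)))
  print(round(x$summary, 1))
  invisible(x)
}
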