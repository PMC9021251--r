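## Synthetic-case generation: every input the fitting pipeline needs, with
## known ground truth. Zone masks are produced as (optionally
## boundary-perturbed) isocontour regions of a computed field at known
## thresholds, emulating the statistical structure of pathologist-segmented
## damage zones.

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Chamfer 3-4 distance transform (in pixels) to the nearest TRUE pixel.
## Row scans are vectorized with the running-min trick
## f_i = c*i + cummin(d_i - c*i).
chamfer_dt <- function(feature) {
  nx <- nrow(feature); ny <- ncol(feature)
  BIG <- 3 * (nx + ny) + 10
  D <- matrix(BIG, nx, ny)
  D[feature] <- 0
  scan_col <- function(v) {
    i <- seq_along(v)
    f <- cummin(v - 3 * i) + 3 * i
    b <- rev(cummin(rev(v) - 3 * i) + 3 * i)
    pmin(v, f, b)
  }
  for (sweep in 1:2) {
    js <- if (sweep == 1) seq_len(ny) else rev(seq_len(ny))
    for (j in js) {
      if ((sweep == 1 && j > 1) || (sweep == 2 && j < ny)) {
        jp <- if (sweep == 1) j - 1L else j + 1L
        prev <- D[, jp]
        cand <- pmin(prev + 3, c(BIG, prev[-nx] + 4), c(prev[-1] + 4, BIG))
        D[, j] <- pmin(D[, j], cand)
      }
      D[, j] <- scan_col(D[, j])
    }
  }
  D / 3
}

## Signed distance in pixels: positive inside the mask.
signed_distance_px <- function(mask) {
  d_in <- chamfer_dt(!mask)   # distance of inside pixels to background
  d_out <- chamfer_dt(mask)   # distance of outside pixels to the mask
  ifelse(mask, d_in, -d_out)
}

## Zero-mean spatially correlated noise field, sd = 1, correlation length
## ~ corr_px, from seeded uniform noise smoothed by repeated moving averages.
correlated_noise <- function(nx, ny, corr_px = 10, seed) {
  with_seed(seed, {
    w <- matrix(runif(nx * ny, -1, 1), nx, ny)
    r <- max(1L, round(corr_px / 2))
    kern <- rep(1 / (2 * r + 1), 2 * r + 1)
    smooth1 <- function(m) {
      m <- apply(m, 2, function(col) stats::filter(col, kern, sides = 2, circular = TRUE))
      t(apply(m, 1, function(row) stats::filter(row, kern, sides = 2, circular = TRUE)))
    }
    w <- smooth1(smooth1(w))
    w <- w - mean(w)
    w / sd(w)
  })
}

#' Perturb a zone-mask boundary with smooth radial noise
#'
#' Displaces the mask boundary along its normal by a seeded, zero-mean,
#' spatially correlated noise field: the mask's signed distance (pixels,
#' positive inside) is shifted by the noise and re-thresholded at zero. The
#' noise standard deviation is `amplitude_px / sqrt(3)` (matching a uniform
#' draw on +/- `amplitude_px`) with correlation length ~10 px, giving the
#' smooth boundary wiggles of manually outlined histological zones.
#'
#' @param mask an [zone_mask()] (or logical matrix).
#' @param amplitude_px displacement amplitude in pixels (0 = no change).
#' @param seed RNG seed (required when `amplitude_px > 0`).
#' @param corr_px correlation length along the boundary, pixels.
#' @return perturbed mask of the same class.
#' @export
perturb_mask_boundary <- function(mask, amplitude_px, seed = NULL, corr_px = 10) {
  check_number(amplitude_px, "amplitude_px", lower = 0)
  if (amplitude_px == 0) return(mask)
  if (is.null(seed)) stopf("a seed is required for boundary noise")
  m <- mask_values(mask)
  sdist <- signed_distance_px(m)
  noise <- correlated_noise(nrow(m), ncol(m), corr_px, seed) * amplitude_px / sqrt(3)
  out <- (sdist + noise) > 0
  if (inherits(mask, "ect_zone_mask")) {
    zone_mask(out, mask$px_mm, mask$origin_mm, mask$label)
  } else out
}

#' Generate a random vessel/portal-space scene
#'
#' Places non-overlapping vessels (blood-filled lumen with a vessel wall
#' annulus) and portal-space blobs inside the given frame, reproducibly by
#' seed.
#'
#' @param seed RNG seed.
#' @param n_vessels number of vessels.
#' @param n_portal number of portal spaces.
#' @param frame_mm placement frame c(x0, y0, x1, y1), mm.
#' @param lumen_radius_mm range of lumen radii, mm.
#' @param wall_thickness_mm range of wall thicknesses, mm.
#' @param portal_radius_mm range of portal-space radii, mm.
#' @param margin_mm minimum clearance between structures, mm.
#' @param max_tries placement attempts per structure before giving up.
#' @return list of [region()]s (`blood` lumina, `vessel_wall` annuli,
#'   `portal_space` blobs), possibly empty.
#' @export
generate_vessel_scene <- function(seed, n_vessels = 2, n_portal = 1,
                                  frame_mm = c(-10, -10, 10, 10),
                                  lumen_radius_mm = c(0.6, 1.8),
                                  wall_thickness_mm = c(0.2, 0.45),
                                  portal_radius_mm = c(0.5, 1.2),
                                  margin_mm = 0.5, max_tries = 200L) {
  stopifnot(n_vessels >= 0, n_portal >= 0)
  with_seed(seed, {
    placed <- list()   # c(x, y, outer_r)
    regions <- list()
    place <- function(outer_r) {
      for (t in seq_len(max_tries)) {
        x <- runif(1, frame_mm[1] + outer_r, frame_mm[3] - outer_r)
        y <- runif(1, frame_mm[2] + outer_r, frame_mm[4] - outer_r)
        ok <- TRUE
        for (p in placed) {
          if (sqrt((x - p[1])^2 + (y - p[2])^2) < outer_r + p[3] + margin_mm) {
            ok <- FALSE; break
          }
        }
        if (ok) return(c(x, y, outer_r))
      }
      NULL
    }
    for (k in seq_len(n_vessels)) {
      rl <- runif(1, lumen_radius_mm[1], lumen_radius_mm[2])
      wt <- runif(1, wall_thickness_mm[1], wall_thickness_mm[2])
      pos <- place(rl + wt)
      if (is.null(pos)) stopf("could not place vessel %d after %d tries", k, max_tries)
      placed[[length(placed) + 1L]] <- pos
      lum <- circle_polygon(pos[1:2], rl)
      out <- circle_polygon(pos[1:2], rl + wt)
      regions[[length(regions) + 1L]] <- region("blood", lum)
      regions[[length(regions) + 1L]] <- region("vessel_wall", out, holes = list(lum))
    }
    for (k in seq_len(n_portal)) {
      rp <- runif(1, portal_radius_mm[1], portal_radius_mm[2])
      pos <- place(rp)
      if (is.null(pos)) stopf("could not place portal space %d after %d tries", k, max_tries)
      placed[[length(placed) + 1L]] <- pos
      regions[[length(regions) + 1L]] <- region("portal_space", circle_polygon(pos[1:2], rp))
    }
    regions
  })
}

#' Synthetic-case specification
#'
#' Describes a fully synthetic fitting case: electrode layout, optional
#' vessel scene, ground-truth Zone A/B field thresholds, and the boundary
#' noise applied to the emitted masks.
#'
#' @param layout `"hexagonal"` (7-needle array) or `"linear"` (2 needles).
#' @param thresholds_V_per_cm named c(A =, B =) ground-truth thresholds;
#'   A must exceed B (Zone A is the inner, higher-field zone).
#' @param noise_px boundary-noise amplitude in pixels (0 = noiseless).
#' @param seed RNG seed; mandatory when `noise_px > 0` or vessels are drawn.
#' @param vessels list of vessel regions (e.g. from
#'   [generate_vessel_scene()]), or an integer: the number of vessels to draw.
#' @param px_mm raster pixel size, mm (default 0.05, i.e. 50 um).
#' @param frame_mm raster frame half-width, mm (raster spans +/- frame about
#'   the layout center; default 20, i.e. a 40 x 40 mm frame).
#' @param center layout center, mm.
#' @return object of class `synthetic_case_spec`.
#' @export
synthetic_case_spec <- function(layout = c("hexagonal", "linear"),
                                thresholds_V_per_cm = c(A = 1225, B = 805),
                                noise_px = 0, seed = NULL, vessels = list(),
                                px_mm = 0.05, frame_mm = 20, center = c(0, 0)) {
  layout <- match.arg(layout)
  if (is.null(names(thresholds_V_per_cm)))
    names(thresholds_V_per_cm) <- c("A", "B")
  if (thresholds_V_per_cm[["A"]] <= thresholds_V_per_cm[["B"]])
    stopf("Zone A threshold must exceed Zone B threshold")
  if ((noise_px > 0 || is.numeric(vessels)) && is.null(seed))
    stopf("a seed is mandatory when noise or random vessels are requested")
  structure(list(layout = layout, thresholds = thresholds_V_per_cm,
                 noise_px = noise_px, seed = seed, vessels = vessels,
                 px_mm = px_mm, frame_mm = frame_mm, center = center),
            class = "synthetic_case_spec")
}

#' Generate a synthetic fitting case
#'
#' Builds the geometry, solves the field for the layout's full pair sequence,
#' rasterizes the superposed field, thresholds it at the ground-truth Zone A
#' and Zone B values to obtain filled zone masks, perturbs the mask
#' boundaries with seeded radial noise, and returns everything together with
#' a manifest recording the ground truth.
#'
#' @param spec a [synthetic_case_spec()].
#' @param tissues a [tissue_table()] (default [default_tissue_table()]).
#' @param protocol a [pulse_protocol()]; defaults to the preset matching the
#'   layout.
#' @param h_mm mesh size (default 0.5 mm away from electrodes).
#' @param control solver controls.
#' @param out_dir if non-NULL, write the case artifacts (geometry config,
#'   field raster, masks, manifest) into this directory.
#' @return list: `geometry` (regions + electrodes + pairs), `mesh`, `field`
#'   (`field_solution`), `raster`, `masks` (list `A`, `B`), `manifest`.
#' @export
generate_case <- function(spec, tissues = default_tissue_table(),
                          protocol = NULL, h_mm = 0.5, control = list(),
                          out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_case_spec"))
  protocol <- protocol %||%
    protocol_presets(if (spec$layout == "hexagonal") "hexagonal_ect" else "linear_ect")
  lay <- if (spec$layout == "hexagonal") {
    place_hexagonal_array(spec$center)
  } else {
    place_linear_pair(spec$center)
  }
  vessels <- spec$vessels
  if (is.numeric(vessels)) {
    vessels <- generate_vessel_scene(spec$seed, n_vessels = vessels,
                                     frame_mm = c(spec$center[1] - spec$frame_mm / 2,
                                                  spec$center[2] - spec$frame_mm / 2,
                                                  spec$center[1] + spec$frame_mm / 2,
                                                  spec$center[2] + spec$frame_mm / 2))
  }
  dd <- default_domain(lay$electrodes)
  regions <- c(list(rect_region("liver", dd[1], dd[2], dd[3], dd[4])), vessels)
  mesh <- triangulate(regions, lay$electrodes, h_max = h_mm,
                      h_far = max(h_mm, (dd[3] - dd[1]) / 40),
                      roi_pad_mm = spec$frame_mm / 2)
  field <- run_pair_sequence(mesh, tissues, lay$pairs, protocol, control = control)
  grid <- raster_grid(spec$center[1] + c(-1, 1) * spec$frame_mm,
                      spec$center[2] + c(-1, 1) * spec$frame_mm, spec$px_mm)
  ras <- export_field(field, grid)
  masks <- list()
  for (z in c("A", "B")) {
    thr <- spec$thresholds[[z]]
    mv <- field_mask(ras, thr)
    tissue_px <- if (is.null(ras$electrode)) mv else mv & !ras$electrode
    if (!any(tissue_px))
      stopf("Zone %s threshold %g V/cm is outside the field's range (empty zone)", z, thr)
    mk <- zone_mask(mv, spec$px_mm, grid$origin_mm, label = z)
    if (spec$noise_px > 0) {
      sub_seed <- (spec$seed + match(z, c("A", "B"))) %% 2147483647
      mk <- perturb_mask_boundary(mk, spec$noise_px, seed = sub_seed)
    }
    masks[[z]] <- mk
  }
  manifest <- list(
    generator = "ectfield::generate_case",
    package_version = as.character(utils::packageVersion("ectfield")),
    layout = spec$layout,
    ground_truth_thresholds_V_per_cm = as.list(spec$thresholds),
    noise_px = spec$noise_px, seed = spec$seed,
    px_mm = spec$px_mm, frame_mm = spec$frame_mm,
    protocol = unclass(protocol), h_mm = h_mm,
    n_vessel_regions = length(vessels))
  out <- list(geometry = c(lay, list(regions = regions)), mesh = mesh,
              field = field, raster = ras, masks = masks, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_geometry(regions, lay$electrodes, file.path(out_dir, "geometry.yml"))
    write_raster(ras, file.path(out_dir, "field"))
    write_raster(masks$A, file.path(out_dir, "zoneA"))
    write_raster(masks$B, file.path(out_dir, "zoneB"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
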