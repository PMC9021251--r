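#' Tissue region
#'
#' A labeled 2-D tissue region: a simple closed boundary polygon with optional
#' holes. All coordinates are in millimetres. Boundaries are stored
#' counter-clockwise, holes clockwise.
#'
#' @param label tissue name (must match an entry of the tissue table used for
#'   solving, e.g. `"liver"`, `"blood"`, `"septa"`).
#' @param boundary numeric matrix (n x 2) of vertices in mm, not repeated at
#'   the end.
#' @param holes list of hole polygons (each an n x 2 matrix) lying strictly
#'   inside `boundary`.
#' @return an object of class `ect_region`.
#' @export
region <- function(label, boundary, holes = list()) {
  stopifnot(is.character(label), length(label) == 1L)
  boundary <- as.matrix(boundary)
  dimnames(boundary) <- NULL
  if (ncol(boundary) != 2L || nrow(boundary) < 3L)
    stopf("region '%s': boundary must be an n x 2 matrix with n >= 3", label)
  if (abs(polygon_area(boundary)) < 1e-12)
    stopf("region '%s': degenerate boundary polygon", label)
  if (polygon_area(boundary) < 0) boundary <- boundary[rev(seq_len(nrow(boundary))), ]
  holes <- lapply(holes, function(h) {
    h <- as.matrix(h)
    dimnames(h) <- NULL
    if (polygon_area(h) > 0) h <- h[rev(seq_len(nrow(h))), ]
    h
  })
  structure(list(label = label, boundary = boundary, holes = holes),
            class = "ect_region")
}

#' @export
print.ect_region <- function(x, ...) {
  cat(sprintf("<region '%s': %d boundary vertices, %d hole(s), area %.4g mm^2>\n",
              x$label, nrow(x$boundary), length(x$holes), region_area(x)))
  invisible(x)
}

region_area <- function(r) {
  abs(polygon_area(r$boundary)) - sum(vapply(r$holes, function(h) abs(polygon_area(h)), 0))
}

rect_region <- function(label, x0, y0, x1, y1) {
  region(label, rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)))
}

#' Needle electrode (2-D cross section)
#'
#' @param center electrode axis position, c(x, y) in mm.
#' @param diameter electrode diameter in mm (> 0).
#' @param id integer electrode identifier, unique within a model.
#' @param invert if `TRUE` the electrode occupies the *exterior* of the circle
#'   (used to model an outer coaxial conductor).
#' @return object of class `ect_electrode`.
#' @export
electrode <- function(center, diameter, id = 1L, invert = FALSE) {
  check_number(diameter, "diameter", lower = 1e-9)
  stopifnot(length(center) == 2L, is.finite(center))
  structure(list(center = as.numeric(center), diameter = diameter,
                 id = as.integer(id), invert = isTRUE(invert)),
            class = "ect_electrode")
}

#' @export
print.ect_electrode <- function(x, ...) {
  cat(sprintf("<electrode %d: center (%.3f, %.3f) mm, diameter %.2f mm%s>\n",
              x$id, x$center[1], x$center[2], x$diameter,
              if (x$invert) ", outer shell" else ""))
  invisible(x)
}

check_electrodes_disjoint <- function(electrodes) {
  n <- length(electrodes)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- electrodes[[i]]; b <- electrodes[[j]]
    if (a$invert || b$invert) next
    d <- sqrt(sum((a$center - b$center)^2))
    if (d < (a$diameter + b$diameter) / 2)
      stopf("electrodes %d and %d overlap", a$id, b$id)
  }
  invisible(TRUE)
}

#' Hexagonal-lattice microstructure specification
#'
#' Dimensions of the hepatic-lobule lattice: hexagonal lobules separated by
#' interlobular septa, one centrilobular vein (CV) per lobule. The lobule
#' "diameter" is the across-flats pitch of the lobule-plus-half-septum tile,
#' so the lattice pitch equals `lobule_diameter_um` exactly.
#'
#' @param lobule_diameter_um lobule tile across-flats diameter, micrometres
#'   (default 1950).
#' @param cv_diameter_um centrilobular-vein diameter, micrometres (default 150).
#' @param septum_thickness_um interlobular septum thickness, micrometres
#'   (default 50).
#' @param extent_mm lattice extent as c(x0, y0, x1, y1) in mm.
#' @return object of class `microstructure_spec`.
#' @export
microstructure_spec <- function(lobule_diameter_um = 1950,
                                cv_diameter_um = 150,
                                septum_thickness_um = 50,
                                extent_mm = c(0, 0, 10, 10)) {
  check_number(lobule_diameter_um, "lobule_diameter_um", lower = 1e-6)
  check_number(cv_diameter_um, "cv_diameter_um", lower = 0)
  check_number(septum_thickness_um, "septum_thickness_um", lower = 1e-9)
  if (cv_diameter_um >= lobule_diameter_um)
    stopf("cv_diameter_um must be smaller than lobule_diameter_um")
  stopifnot(length(extent_mm) == 4L, extent_mm[3] > extent_mm[1], extent_mm[4] > extent_mm[2])
  structure(list(lobule_diameter_um = lobule_diameter_um,
                 cv_diameter_um = cv_diameter_um,
                 septum_thickness_um = septum_thickness_um,
                 extent_mm = as.numeric(extent_mm)),
            class = "microstructure_spec")
}

## Vertices of a regular flat-top hexagon with across-flats distance `flats`,
## centered at `center` (mm).
hexagon <- function(center, flats) {
  R <- flats / sqrt(3)   # circumradius
  th <- (0:5) * pi / 3
  cbind(center[1] + R * cos(th), center[2] + R * sin(th))
}

#' Build the hepatic-lobule lattice
#'
#' Tiles the extent with regular hexagonal lobules at the pitch given by the
#' lobule diameter. Each lobule hexagon has across-flats diameter
#' `lobule_diameter - septum_thickness`, so adjacent lobules are separated by
#' a septum band of exactly the septum thickness. The remaining space is the
#' `septa` region (extent rectangle with the lobules as holes); each complete
#' (un-clipped) lobule carries one circular centrilobular vein, labeled `cv`.
#'
#' @param spec a [microstructure_spec()].
#' @return list of `ect_region`: one `septa` region, then `lobule` regions
#'   (clipped to the extent), then `cv` circles. The attribute
#'   `n_complete_lobules` counts lobules fully inside the extent.
#' @export
build_hex_lobule_lattice <- function(spec) {
  stopifnot(inherits(spec, "microstructure_spec"))
  pitch <- spec$lobule_diameter_um / 1000           # mm, tile across-flats
  flats <- (spec$lobule_diameter_um - spec$septum_thickness_um) / 1000
  if (flats <= 0) stopf("septum thickness must be smaller than lobule diameter")
  ext <- spec$extent_mm
  if ((ext[3] - ext[1]) < pitch || (ext[4] - ext[2]) < pitch)
    stopf("lattice extent must cover at least one lobule: need >= %.3f mm in each direction", pitch)
  R <- pitch / sqrt(3)                              # tile circumradius
  ## flat-top hexagon lattice centered on the extent: columns at 1.5 R, rows
  ## at `pitch`, odd columns offset by pitch/2; nearest-neighbor distance =
  ## pitch. Centering maximizes the number of complete boundary lobules.
  dx <- 1.5 * R; dy <- pitch
  cx0 <- (ext[1] + ext[3]) / 2; cy0 <- (ext[2] + ext[4]) / 2
  i0 <- floor((ext[1] - cx0 - R) / dx) - 1L; i1 <- ceiling((ext[3] - cx0 + R) / dx) + 1L
  j0 <- floor((ext[2] - cy0 - R) / dy) - 1L; j1 <- ceiling((ext[4] - cy0 + R) / dy) + 1L
  lobules <- list(); cvs <- list(); holes <- list()
  centers <- matrix(numeric(0), ncol = 2)
  complete_flags <- logical(0)
  n_complete <- 0L
  for (i in i0:i1) for (j in j0:j1) {
    cx <- cx0 + i * dx
    cy <- cy0 + j * dy + if (i %% 2 == 0) 0 else dy / 2
    hx <- hexagon(c(cx, cy), flats)
    complete <- all(hx[, 1] >= ext[1] & hx[, 1] <= ext[3] &
                    hx[, 2] >= ext[2] & hx[, 2] <= ext[4])
    clipped <- if (complete) hx else clip_polygon_rect(hx, ext)
    if (nrow(clipped) < 3L || abs(polygon_area(clipped)) < 1e-12) next
    if (complete && spec$cv_diameter_um > 0) {
      n_complete <- n_complete + 1L
      cvp <- circle_polygon(c(cx, cy), spec$cv_diameter_um / 2000)
      cvs[[length(cvs) + 1L]] <- region("cv", cvp)
      lobules[[length(lobules) + 1L]] <- region("lobule", clipped, holes = list(cvp))
    } else {
      lobules[[length(lobules) + 1L]] <- region("lobule", clipped)
    }
    holes[[length(holes) + 1L]] <- clipped
    centers <- rbind(centers, c(cx, cy))
    complete_flags <- c(complete_flags, complete)
  }
  septa <- region("septa", rbind(c(ext[1], ext[2]), c(ext[3], ext[2]),
                                 c(ext[3], ext[4]), c(ext[1], ext[4])),
                  holes = holes)
  out <- c(list(septa), lobules, cvs)
  attr(out, "n_complete_lobules") <- n_complete
  attr(out, "pitch_mm") <- pitch
  attr(out, "lobule_centers_mm") <- centers
  attr(out, "lobule_complete") <- complete_flags
  out
}

#' Place the 7-needle hexagonal electrode array
#'
#' One central electrode plus six at the vertices of a regular hexagon whose
#' side equals the spacing, so that every nearest-neighbor distance (center to
#' periphery and adjacent periphery) equals `spacing_mm`. The activation
#' sequence has 12 anode-cathode pairs: six center-periphery pairs followed by
#' six adjacent-periphery pairs.
#'
#' @param center array center c(x, y) in mm.
#' @param spacing_mm nearest-neighbor electrode distance in mm (default 7.3).
#' @param diameter_mm electrode diameter in mm (default 0.7).
#' @param angle_deg rigid rotation of the array about its center, degrees.
#' @return list with `electrodes` (7 [electrode()]s, id 1 = center, ids 2-7
#'   counter-clockwise periphery) and `pairs` (12 x 2 integer matrix of
#'   anode/cathode ids, in activation order).
#' @export
place_hexagonal_array <- function(center = c(0, 0), spacing_mm = 7.3,
                                  diameter_mm = 0.7, angle_deg = 0) {
  check_number(spacing_mm, "spacing_mm", lower = 1e-9)
  check_number(diameter_mm, "diameter_mm", lower = 1e-9)
  if (spacing_mm <= diameter_mm) stopf("spacing must exceed electrode diameter")
  th <- (0:5) * pi / 3
  pts <- rbind(c(0, 0), cbind(spacing_mm * cos(th), spacing_mm * sin(th)))
  pts <- rotate_points(pts, angle_deg)
  pts <- sweep(pts, 2, center, `+`)
  electrodes <- lapply(seq_len(7L), function(i)
    electrode(pts[i, ], diameter_mm, id = i))
  check_electrodes_disjoint(electrodes)
  pairs <- rbind(
    cbind(1L, 2:7),                       # center (anode) vs each periphery
    cbind(2:7, c(3:7, 2L)))               # adjacent periphery pairs
  colnames(pairs) <- c("anode", "cathode")
  list(electrodes = electrodes, pairs = pairs)
}

#' Place a linear electrode pair
#'
#' Two parallel needle electrodes seen in cross section: circles of the given
#' diameter with centers `spacing_mm` apart along direction `angle_deg`.
#'
#' @param midpoint pair midpoint c(x, y) in mm.
#' @param angle_deg direction from electrode 1 (anode) to electrode 2, degrees.
#' @param spacing_mm center-to-center distance, mm (default 20).
#' @param diameter_mm electrode diameter, mm (default 1.2).
#' @return list with `electrodes` (2) and `pairs` (1 x 2 matrix, anode = id 1).
#' @export
place_linear_pair <- function(midpoint = c(0, 0), angle_deg = 0,
                              spacing_mm = 20, diameter_mm = 1.2) {
  check_number(spacing_mm, "spacing_mm", lower = 1e-9)
  check_number(diameter_mm, "diameter_mm", lower = 1e-9)
  if (spacing_mm <= diameter_mm) stopf("spacing must exceed electrode diameter")
  a <- angle_deg * pi / 180
  d <- c(cos(a), sin(a)) * spacing_mm / 2
  electrodes <- list(electrode(midpoint - d, diameter_mm, id = 1L),
                     electrode(midpoint + d, diameter_mm, id = 2L))
  pairs <- matrix(c(1L, 2L), 1, 2, dimnames = list(NULL, c("anode", "cathode")))
  list(electrodes = electrodes, pairs = pairs)
}

#' Default padded model domain for an electrode layout
#'
#' Rectangle centered on the electrode layout, padded on every side by
#' `pad_factor` times the diagonal of the electrode bounding box, so the
#' outer (insulating) boundary does not perturb the field near the
#' electrodes.
#'
#' @param electrodes list of [electrode()].
#' @param pad_factor padding as a multiple of the array bounding-box diagonal
#'   (default 3).
#' @return c(x0, y0, x1, y1) in mm.
#' @export
default_domain <- function(electrodes, pad_factor = 3) {
  ctr <- do.call(rbind, lapply(electrodes, `[[`, "center"))
  r <- vapply(electrodes, function(e) e$diameter / 2, 0)
  x0 <- min(ctr[, 1] - r); x1 <- max(ctr[, 1] + r)
  y0 <- min(ctr[, 2] - r); y1 <- max(ctr[, 2] + r)
  diag <- max(sqrt((x1 - x0)^2 + (y1 - y0)^2), max(2 * r))
  pad <- pad_factor * diag
  c(x0 - pad, y0 - pad, x1 + pad, y1 + pad)
}
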