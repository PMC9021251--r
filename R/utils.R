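#' @importFrom stats median sd runif approx setNames
#' @importFrom utils write.csv read.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_number(x) || x < lower || x > upper)
    stopf("`%s` must be a finite number in [%g, %g]", name, lower, upper)
  x
}

## Signed area of a closed polygon (vertices as n x 2 matrix, not repeated).
## Positive for counter-clockwise orientation. Coordinates in mm -> mm^2.
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

## Vectorized even-odd point-in-polygon (ray crossing). Points on an edge are
## classified by the crossing rule; adequate for centroid labeling.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  x <- poly[, 1]; y <- poly[, 2]
  j <- n
  for (i in seq_len(n)) {
    yi <- y[i]; yj <- y[j]; xi <- x[i]; xj <- x[j]
    cross <- ((yi > py) != (yj > py))
    if (any(cross)) {
      xin <- xi + (py[cross] - yi) / (yj - yi) * (xj - xi)
      inside[cross] <- xor(inside[cross], px[cross] < xin)
    }
    j <- i
  }
  inside
}

point_in_region <- function(px, py, region) {
  inside <- points_in_polygon(px, py, region$boundary)
  for (h in region$holes) inside <- inside & !points_in_polygon(px, py, h)
  inside
}

## Sutherland-Hodgman clipping of a convex-or-simple polygon against an
## axis-aligned rectangle c(x0, y0, x1, y1). Returns matrix (possibly 0 rows).
clip_polygon_rect <- function(poly, rect) {
  clip_edge <- function(p, keep, intersect) {
    if (nrow(p) == 0L) return(p)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(p)
    for (i in seq_len(n)) {
      a <- p[i, ]; b <- p[if (i == n) 1L else i + 1L, ]
      ka <- keep(a); kb <- keep(b)
      if (ka) out <- rbind(out, a)
      if (xor(ka, kb)) out <- rbind(out, intersect(a, b))
    }
    out
  }
  ix <- function(a, b, v, k) { t <- (v - a[k]) / (b[k] - a[k]); a + t * (b - a) }
  p <- poly
  p <- clip_edge(p, function(q) q[1] >= rect[1], function(a, b) ix(a, b, rect[1], 1))
  p <- clip_edge(p, function(q) q[2] >= rect[2], function(a, b) ix(a, b, rect[2], 2))
  p <- clip_edge(p, function(q) q[1] <= rect[3], function(a, b) ix(a, b, rect[3], 1))
  p <- clip_edge(p, function(q) q[2] <= rect[4], function(a, b) ix(a, b, rect[4], 2))
  p
}

## Regular polygon approximation of a circle (counter-clockwise).
circle_polygon <- function(center, radius, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

## Rotation by angle (degrees) about a point.
rotate_points <- function(p, angle_deg, about = c(0, 0)) {
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(sweep(p, 2, about) %*% t(R), 2, about, `+`)
}
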