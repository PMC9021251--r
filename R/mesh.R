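## Graded tensor-product triangular meshing.
##
## The mesher lays a rectangular grid over the domain with axis spacings that
## refine near electrodes (and inside per-label refinement boxes), splits each
## cell into two triangles, snaps grid nodes onto electrode circles, and labels
## every element by the region containing its centroid. Tissue-tissue
## interfaces are therefore resolved at the local element size; electrode
## boundaries are resolved exactly (snapped nodes lie on the circle).

## 1-D graded point sequence on [a, b]: spacing h_base, refined to the sizes
## of `intervals` (list of c(lo, hi, h)), growing away from refinement zones
## at gradient `g`.
grade_axis <- function(a, b, h_base, intervals = list(), g = 0.3) {
  size_at <- function(x) {
    h <- rep(h_base, length(x))
    for (iv in intervals) {
      d <- pmax(0, pmax(iv[1] - x, x - iv[2]))
      h <- pmin(h, iv[3] + g * d)
    }
    h
  }
  pts <- a
  x <- a
  repeat {
    h <- size_at(x + size_at(x) / 2)
    if (x + 1.5 * h >= b) break
    x <- x + h
    pts <- c(pts, x)
  }
  ## the remaining gap (between h and 1.5 h) is closed by the end point, so
  ## refinement bands keep their exact positions
  c(pts, b)
}

#' Triangulate a 2-D model
#'
#' Builds a conforming triangular mesh of the rectangular hull of `regions`:
#' a graded tensor-product grid (refined near electrodes and inside per-label
#' refinement boxes), each cell split into two triangles, with nodes snapped
#' onto electrode circles. Every element is labeled by the region containing
#' its centroid (smallest containing region wins, so nested regions behave as
#' expected); elements inside an electrode get the label `"electrode"` and are
#' excluded from field/thermal solves.
#'
#' @param regions list of [region()] tiling the domain; their rectangular hull
#'   defines the meshed domain.
#' @param electrodes list of [electrode()] (may be empty).
#' @param h_max target element size (grid spacing) away from refinement
#'   zones, mm.
#' @param refinement named list of per-label element-size limits in mm; the
#'   special name `"electrode"` sets the size near electrode boundaries
#'   (default `min(h_max, diameter / 6)`).
#' @param h_far optional far-field element size, mm. When given (and larger
#'   than `h_max`), `h_max` applies inside the region of interest — the
#'   electrode bounding box padded by `roi_pad_mm` — and element sizes grow
#'   toward `h_far` away from it. Keeps generously padded outer domains cheap.
#' @param roi_pad_mm padding of the region-of-interest box, mm (default 5).
#' @return object of class `ect_mesh`: nodes (mm), triangles, element labels,
#'   per-element electrode id (0 = tissue), electrode boundary-node sets, and
#'   the generating grid.
#' @export
triangulate <- function(regions, electrodes = list(), h_max,
                        refinement = list(), h_far = NULL, roi_pad_mm = 5) {
  check_number(h_max, "h_max", lower = 1e-9)
  stopifnot(length(regions) >= 1L)
  bx <- do.call(rbind, lapply(regions, function(r) {
    rbind(apply(r$boundary, 2, range))
  }))
  dom <- c(min(bx[c(TRUE, FALSE), 1]), min(bx[c(TRUE, FALSE), 2]),
           max(bx[c(FALSE, TRUE), 1]), max(bx[c(FALSE, TRUE), 2]))
  ## refinement intervals per axis
  ivx <- list(); ivy <- list()
  h_base <- h_max
  if (!is.null(h_far) && h_far > h_max) {
    h_base <- h_far
    if (length(electrodes)) {
      ctr <- do.call(rbind, lapply(electrodes, `[[`, "center"))
      r <- vapply(electrodes, function(e) e$diameter / 2, 0)
      ivx[[1]] <- c(min(ctr[, 1] - r) - roi_pad_mm, max(ctr[, 1] + r) + roi_pad_mm, h_max)
      ivy[[1]] <- c(min(ctr[, 2] - r) - roi_pad_mm, max(ctr[, 2] + r) + roi_pad_mm, h_max)
    }
  }
  h_elec_default <- refinement[["electrode"]]
  for (e in electrodes) {
    r <- e$diameter / 2
    he <- h_elec_default %||% min(h_max, e$diameter / 6)
    pad <- r + 2 * he
    ivx[[length(ivx) + 1L]] <- c(e$center[1] - pad, e$center[1] + pad, he)
    ivy[[length(ivy) + 1L]] <- c(e$center[2] - pad, e$center[2] + pad, he)
  }
  for (nm in setdiff(names(refinement), "electrode")) {
    hl <- refinement[[nm]]
    for (rg in regions) {
      if (rg$label != nm) next
      rr <- apply(rg$boundary, 2, range)
      ivx[[length(ivx) + 1L]] <- c(rr[1, 1], rr[2, 1], hl)
      ivy[[length(ivy) + 1L]] <- c(rr[1, 2], rr[2, 2], hl)
    }
  }
  xs <- grade_axis(dom[1], dom[3], h_base, ivx)
  ys <- grade_axis(dom[2], dom[4], h_base, ivy)
  nx <- length(xs); ny <- length(ys)
  if (nx < 2L || ny < 2L) stopf("h_max too large for the domain")
  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  nid <- function(i, j) (j - 1L) * nx + i
  ## two triangles per cell, alternating diagonal for isotropy
  ncell <- (nx - 1L) * (ny - 1L)
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  n00 <- nid(i, j); n10 <- nid(i + 1L, j); n01 <- nid(i, j + 1L); n11 <- nid(i + 1L, j + 1L)
  alt <- (i + j) %% 2L == 0L
  ## diagonal n00-n11 when alt, else n10-n01
  triA <- cbind(n00, n10, ifelse(alt, n11, n01))
  triB <- cbind(ifelse(alt, n00, n10), n11, n01)
  tri <- matrix(0L, 2L * ncell, 3L)
  tri[seq(1L, 2L * ncell, by = 2L), ] <- triA
  tri[seq(2L, 2L * ncell, by = 2L), ] <- triB
  ## snap nodes onto electrode circles, edge-based: for every triangle edge
  ## crossing a circle, move the endpoint closer to the circle onto the
  ## edge-circle intersection. Guarantees active elements keep no vertex
  ## strictly inside an electrode (no spurious Dirichlet spikes).
  hx <- c(diff(xs), tail(diff(xs), 1)); hy <- c(diff(ys), tail(diff(ys), 1))
  local_h <- pmin(rep(hx, times = ny), rep(hy, each = nx))
  e_all <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(1L, 3L)])
  edges <- unique(cbind(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2])))
  interior <- nodes[, 1] > dom[1] & nodes[, 1] < dom[3] &
              nodes[, 2] > dom[2] & nodes[, 2] < dom[4]
  for (e in electrodes) {
    r <- e$diameter / 2
    dx <- nodes[, 1] - e$center[1]; dy <- nodes[, 2] - e$center[2]
    d <- sqrt(dx^2 + dy^2)
    inside <- d < r - 1e-12
    cross <- which(inside[edges[, 1]] != inside[edges[, 2]])
    if (!length(cross)) next
    best_disp <- rep(Inf, nrow(nodes))
    best_xy <- matrix(NA_real_, nrow(nodes), 2L)
    for (k in cross) {
      a <- edges[k, 1]; b <- edges[k, 2]
      p <- nodes[a, ]; q <- nodes[b, ]
      dirv <- q - p
      A <- sum(dirv^2)
      B <- 2 * sum((p - e$center) * dirv)
      C <- sum((p - e$center)^2) - r^2
      disc <- B^2 - 4 * A * C
      if (disc < 0) next
      roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
      t_ok <- roots[roots >= -1e-9 & roots <= 1 + 1e-9]
      if (!length(t_ok)) next
      tgt <- p + min(max(t_ok[1], 0), 1) * dirv
      mv <- if (abs(d[a] - r) <= abs(d[b] - r)) a else b
      if (!interior[mv]) mv <- if (mv == a) b else a
      if (!interior[mv]) next
      disp <- sqrt(sum((nodes[mv, ] - tgt)^2))
      if (disp < best_disp[mv]) { best_disp[mv] <- disp; best_xy[mv, ] <- tgt }
    }
    sel <- which(is.finite(best_disp) & best_disp < 0.9 * local_h)
    if (length(sel)) nodes[sel, ] <- best_xy[sel, , drop = FALSE]
  }
  ## collapse sliver edges: two nodes snapped onto the same circle at nearly
  ## the same point produce degenerate boundary triangles that would carry
  ## spurious field spikes; merge them (union-find) at their circle midpoint
  parent <- seq_len(nrow(nodes))
  find_root <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in electrodes) {
    r <- e$diameter / 2
    d <- sqrt((nodes[, 1] - e$center[1])^2 + (nodes[, 2] - e$center[2])^2)
    on_circ <- abs(d - r) < 1e-7
    cand <- which(on_circ[edges[, 1]] & on_circ[edges[, 2]])
    if (!length(cand)) next
    len <- sqrt((nodes[edges[cand, 1], 1] - nodes[edges[cand, 2], 1])^2 +
                (nodes[edges[cand, 1], 2] - nodes[edges[cand, 2], 2])^2)
    short <- cand[len < 0.35 * pmin(local_h[edges[cand, 1]], local_h[edges[cand, 2]])]
    for (k in short[order(len[match(short, cand)])]) {
      a <- find_root(edges[k, 1]); b <- find_root(edges[k, 2])
      if (a == b) next
      parent[b] <- a
      mid <- (nodes[a, ] + nodes[b, ]) / 2 - e$center
      nodes[a, ] <- e$center + mid * r / sqrt(sum(mid^2))
    }
  }
  if (any(parent != seq_len(nrow(nodes)))) {
    root <- vapply(seq_len(nrow(nodes)), find_root, 1L)
    tri <- matrix(root[tri], ncol = 3L)
  }
  ## guard against inverted triangles from snapping: revert offending nodes
  orig <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  for (pass in 1:3) {
    ar <- tri_signed_areas(nodes, tri)
    ok3 <- tri[, 1] != tri[, 2] & tri[, 2] != tri[, 3] & tri[, 1] != tri[, 3]
    bad <- which(ar <= 1e-14 & ok3)
    if (!length(bad)) break
    bad_nodes <- unique(as.vector(tri[bad, ]))
    bad_nodes <- bad_nodes[parent[bad_nodes] == bad_nodes &
                           vapply(bad_nodes, function(i) !any(parent == i & seq_along(parent) != i), TRUE)]
    if (!length(bad_nodes)) break
    nodes[bad_nodes, ] <- orig[bad_nodes, ]
  }
  ## drop degenerate triangles (collapsed slivers), keeping the cell ->
  ## element lookup used for fast point location
  cell_elem <- matrix(seq_len(2L * ncell), ncell, 2L, byrow = TRUE)
  ar <- tri_signed_areas(nodes, tri)
  keep <- which(tri[, 1] != tri[, 2] & tri[, 2] != tri[, 3] & tri[, 1] != tri[, 3] &
                ar > 1e-14)
  if (length(keep) < nrow(tri)) {
    newid <- rep(NA_integer_, nrow(tri))
    newid[keep] <- seq_along(keep)
    tri <- tri[keep, , drop = FALSE]
    cell_elem[] <- newid[cell_elem]
  }
  ## element centroids and labels
  cx <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
  cy <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
  elec_id <- integer(nrow(tri))
  for (e in electrodes) {
    r <- e$diameter / 2
    d2 <- (cx - e$center[1])^2 + (cy - e$center[2])^2
    inside <- if (e$invert) d2 > r^2 else d2 < r^2
    elec_id[inside] <- e$id
  }
  label <- rep(NA_character_, nrow(tri))
  areas <- vapply(regions, region_area, 0)
  for (k in order(areas)) {
    todo <- which(is.na(label))
    if (!length(todo)) break
    hit <- point_in_region(cx[todo], cy[todo], regions[[k]])
    label[todo[hit]] <- regions[[k]]$label
  }
  un <- is.na(label)
  if (mean(un) > 0.01)
    stopf("regions do not tile the domain: %.1f%% of elements unlabeled", 100 * mean(un))
  if (any(un)) label[un] <- regions[[which.max(areas)]]$label
  label[elec_id > 0L] <- "electrode"
  ## electrode boundary-node sets: nodes on the circle that touch an active element
  active_nodes <- unique(as.vector(tri[elec_id == 0L, ]))
  on_active <- logical(nrow(nodes)); on_active[active_nodes] <- TRUE
  bnodes <- list()
  for (e in electrodes) {
    r <- e$diameter / 2
    d <- sqrt((nodes[, 1] - e$center[1])^2 + (nodes[, 2] - e$center[2])^2)
    sel <- if (e$invert) (d >= r - 1e-7) else (d <= r + 1e-7)
    ids <- which(sel & on_active)
    if (!length(ids))
      stopf("electrode %d has no mesh boundary nodes; refine the mesh near it", e$id)
    bnodes[[as.character(e$id)]] <- ids
  }
  structure(list(nodes = nodes, tri = tri, label = label, elec_id = elec_id,
                 electrodes = electrodes, electrode_nodes = bnodes,
                 xs = xs, ys = ys, domain = dom, h_max = h_max,
                 cell_elem = cell_elem),
            class = "ect_mesh")
}

tri_signed_areas <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' Total mesh area (mm^2)
#' @param mesh an `ect_mesh`.
#' @param active_only if `TRUE`, exclude electrode-interior elements.
#' @export
mesh_area <- function(mesh, active_only = FALSE) {
  a <- abs(tri_signed_areas(mesh$nodes, mesh$tri))
  if (active_only) a <- a[mesh$elec_id == 0L]
  sum(a)
}

#' @export
print.ect_mesh <- function(x, ...) {
  cat(sprintf("<ect_mesh: %d nodes, %d elements (%d tissue), labels: %s>\n",
              nrow(x$nodes), nrow(x$tri), sum(x$elec_id == 0L),
              paste(sort(unique(x$label)), collapse = ", ")))
  invisible(x)
}

element_centroids <- function(mesh) {
  cbind((mesh$nodes[mesh$tri[, 1], 1] + mesh$nodes[mesh$tri[, 2], 1] + mesh$nodes[mesh$tri[, 3], 1]) / 3,
        (mesh$nodes[mesh$tri[, 1], 2] + mesh$nodes[mesh$tri[, 2], 2] + mesh$nodes[mesh$tri[, 3], 2]) / 3)
}

## Locate the element containing each query point (mm). Uses the generating
## grid for candidate lookup, then an exact barycentric test over the 3x3 cell
## neighborhood (snapping moves nodes by < half a cell). Returns element index
## or NA for points outside the mesh.
locate_elements <- function(mesh, px, py) {
  nx <- length(mesh$xs); ny <- length(mesh$ys)
  ci <- findInterval(px, mesh$xs, rightmost.closed = TRUE)
  cj <- findInterval(py, mesh$ys, rightmost.closed = TRUE)
  out <- rep(NA_integer_, length(px))
  valid <- ci >= 1L & ci <= nx - 1L & cj >= 1L & cj <= ny - 1L
  idx <- which(valid)
  if (!length(idx)) return(out)
  nodes <- mesh$nodes; tri <- mesh$tri
  remaining <- idx
  for (dj in c(0L, -1L, 1L)) for (di in c(0L, -1L, 1L)) {
    if (!length(remaining)) break
    i2 <- ci[remaining] + di; j2 <- cj[remaining] + dj
    ok <- i2 >= 1L & i2 <= nx - 1L & j2 >= 1L & j2 <= ny - 1L
    cell <- (j2 - 1L) * (nx - 1L) + i2
    for (t in 1:2) {
      el <- rep(NA_integer_, length(cell))
      el[ok] <- mesh$cell_elem[cell[ok], t]
      sub <- which(ok & !is.na(el) & is.na(out[remaining]))
      if (!length(sub)) next
      e <- el[sub]; q <- remaining[sub]
      ax <- nodes[tri[e, 1], 1]; ay <- nodes[tri[e, 1], 2]
      bx2 <- nodes[tri[e, 2], 1]; by2 <- nodes[tri[e, 2], 2]
      cx2 <- nodes[tri[e, 3], 1]; cy2 <- nodes[tri[e, 3], 2]
      d <- (by2 - cy2) * (ax - cx2) + (cx2 - bx2) * (ay - cy2)
      l1 <- ((by2 - cy2) * (px[q] - cx2) + (cx2 - bx2) * (py[q] - cy2)) / d
      l2 <- ((cy2 - ay) * (px[q] - cx2) + (ax - cx2) * (py[q] - cy2)) / d
      l3 <- 1 - l1 - l2
      tol <- -1e-9
      hit <- l1 >= tol & l2 >= tol & l3 >= tol
      out[q[hit]] <- e[hit]
    }
    remaining <- idx[is.na(out[idx])]
  }
  out
}

## Element adjacency (shared edges) as a sparse pattern matrix including the
## diagonal; used for patch-averaging element quantities.
element_adjacency <- function(mesh) {
  tri <- mesh$tri
  m <- nrow(tri)
  e_all <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(1L, 3L)])
  key <- paste(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  elem <- rep(seq_len(m), times = 3L)
  o <- order(key)
  key <- key[o]; elem <- elem[o]
  same <- which(key[-1] == key[-length(key)])
  i <- c(seq_len(m), elem[same], elem[same + 1L])
  j <- c(seq_len(m), elem[same + 1L], elem[same])
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(m, m))
}

#' Export a mesh (with optional element data) as legacy ASCII VTK
#'
#' @param mesh an `ect_mesh`.
#' @param path output file path (`.vtk`).
#' @param cell_data named list of per-element numeric vectors to attach.
#' @export
export_mesh_vtk <- function(mesh, path, cell_data = list()) {
  con <- file(path, "w"); on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  writeLines(c("# vtk DataFile Version 3.0", "ectfield mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L, mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  labs <- sort(unique(mesh$label))
  lab_id <- match(mesh$label, labs) - 1L
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS tissue_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", lab_id), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", cell_data[[nm]]), con)
  }
  invisible(path)
}
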