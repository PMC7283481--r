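# Planar geometry for polygon annotations and tiling.
#
# Polygons are n x 2 matrices of (x, y) vertices in pixel coordinates
# (0-based, x = column, y = row), open form (last vertex != first).
# The generator emits convex polygons only, for which the Sutherland-Hodgman
# clip below is exact; areas are signed-shoelace absolute values.

#' Polygon area (shoelace formula)
#'
#' @param poly n x 2 vertex matrix, open form.
#' @return non-negative area in square pixels.
#' @export
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Vectorised over query points; boundary points may fall either way, which
#' is immaterial for area-fraction uses.
#'
#' @param px,py numeric vectors of query coordinates.
#' @param poly n x 2 vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

# Clip a polygon by the half-plane a*x + b*y <= c (Sutherland-Hodgman step).
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), ncol = 2L)
  d <- a * poly[, 1] + b * poly[, 2] - c
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, poly[i, ])
    if ((di <= 0) != (dj <= 0)) {
      t <- di / (di - dj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Exact for convex polygons (the only kind the synthetic generator emits);
#' the rectangle is the half-open tile window `[x0, x1) x [y0, y1)` treated
#' as closed for area purposes (the boundary has measure zero).
#'
#' @param poly n x 2 vertex matrix.
#' @param x0,y0,x1,y1 rectangle bounds.
#' @return clipped vertex matrix (possibly 0 rows).
#' @export
clip_polygon_rect <- function(poly, x0, y0, x1, y1) {
  p <- clip_halfplane(poly, -1, 0, -x0)
  p <- clip_halfplane(p, 1, 0, x1)
  p <- clip_halfplane(p, 0, -1, -y0)
  clip_halfplane(p, 0, 1, y1)
}

# Intersection area of a polygon with a rectangle.
polygon_rect_area <- function(poly, x0, y0, x1, y1) {
  polygon_area(clip_polygon_rect(poly, x0, y0, x1, y1))
}

# Random convex polygon: convex hull of points on a jittered circle.
# Draws from the current RNG stream.
random_convex_polygon <- function(cx, cy, r_min, r_max, n_points = 12L) {
  ang <- sort(stats::runif(n_points, 0, 2 * pi))
  rad <- stats::runif(n_points, r_min, r_max)
  pts <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
  pts[rev(grDevices::chull(pts)), , drop = FALSE]  # counter-clockwise hull
}

# Voronoi cells of seed points, clipped to a convex bounding polygon.
# Cell i is the bounding polygon intersected with the half-planes closer to
# seed i than to any other seed (perpendicular-bisector clips).
voronoi_cells <- function(seeds, bound) {
  m <- nrow(seeds)
  lapply(seq_len(m), function(i) {
    cell <- bound
    for (j in seq_len(m)) {
      if (j == i || nrow(cell) < 3L) next
      # keep points x with |x - s_i|^2 <= |x - s_j|^2
      a <- 2 * (seeds[j, 1] - seeds[i, 1])
      b <- 2 * (seeds[j, 2] - seeds[i, 2])
      c <- sum(seeds[j, ]^2) - sum(seeds[i, ]^2)
      cell <- clip_halfplane(cell, a, b, c)
    }
    cell
  })
}

# Rasterise a polygon onto a height x width logical matrix; a pixel (row r,
# col c) (1-based) is inside when its centre (c - 0.5, r - 0.5) is inside.
rasterize_polygon <- function(poly, width, height) {
  out <- matrix(FALSE, nrow = height, ncol = width)
  if (is.null(nrow(poly)) || nrow(poly) < 3L) return(out)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  c0 <- max(1L, floor(xr[1] + 0.5) + 1L); c1 <- min(width, ceiling(xr[2] + 0.5))
  r0 <- max(1L, floor(yr[1] + 0.5) + 1L); r1 <- min(height, ceiling(yr[2] + 0.5))
  if (c0 > c1 || r0 > r1) return(out)
  cols <- c0:c1; rows <- r0:r1
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  ins <- point_in_polygon(px, py, poly)
  out[rows, cols] <- matrix(ins, nrow = length(rows))
  out
}
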