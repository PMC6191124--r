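# Planar polygon primitives. All coordinates are projected metres; at the
# study extents this package targets (~10-20 km) Euclidean geometry is exact
# enough that no geodesic correction is applied.

#' Polygon area by the shoelace formula
#'
#' @param ring numeric matrix with two columns (x, y); the ring may be open or
#'   explicitly closed, and either orientation.
#' @return area in square metres (non-negative).
#' @keywords internal
polygon_area_m2 <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# ensure the last vertex repeats the first
close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) < 3L) stop("polygon ring needs at least 3 vertices", call. = FALSE)
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' Point-in-polygon test (even-odd rule, ray casting)
#'
#' Points exactly on an edge may be assigned to either side; patch mosaics in
#' this package tile the plane, so boundary points land in exactly one patch
#' in practice.
#'
#' @param x,y point coordinates (scalars).
#' @param ring polygon ring as a two-column matrix.
#' @return logical.
#' @keywords internal
point_in_polygon <- function(x, y, ring) {
  ring <- close_ring(ring)
  n <- nrow(ring)
  px <- ring[, 1]; py <- ring[, 2]
  inside <- FALSE
  j <- n - 1L
  for (i in seq_len(n - 1L)) {
    if ((py[i] > y) != (py[j] > y)) {
      xint <- (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

ring_bbox <- function(ring) {
  c(xmin = min(ring[, 1]), ymin = min(ring[, 2]),
    xmax = max(ring[, 1]), ymax = max(ring[, 2]))
}

#' Uniform random point inside a polygon
#'
#' Rejection sampling from the bounding box; consumes the current RNG stream.
#'
#' @param ring polygon ring.
#' @param max_tries attempts before giving up (degenerate polygons).
#' @return numeric c(x, y).
#' @keywords internal
sample_point_in_polygon <- function(ring, max_tries = 10000L) {
  bb <- ring_bbox(ring)
  for (i in seq_len(max_tries)) {
    x <- stats::runif(1, bb["xmin"], bb["xmax"])
    y <- stats::runif(1, bb["ymin"], bb["ymax"])
    if (point_in_polygon(x, y, ring)) return(c(x = unname(x), y = unname(y)))
  }
  stop("failed to sample a point inside polygon after ", max_tries, " tries",
       call. = FALSE)
}

# axis-aligned rectangle ring (used by the grid-mosaic generator)
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin, xmin),
        y = c(ymin, ymin, ymax, ymax, ymin))
}
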