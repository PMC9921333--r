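# Internal planar-geometry helpers. All coordinates are projected metres;
# polylines are n x 2 matrices with >= 2 vertices.

#' Arc length of a polyline
#' @param geom numeric matrix (n x 2) of vertices.
#' @return total length in metres.
#' @keywords internal
#' @noRd
polyline_length <- function(geom) {
  d <- diff(geom)
  sum(sqrt(rowSums(d^2)))
}

# Cumulative arc-length at each vertex (first element 0).
polyline_cumlen <- function(geom) {
  d <- diff(geom)
  c(0, cumsum(sqrt(rowSums(d^2))))
}

#' Points at given arc-length positions along a polyline
#'
#' Positions are clamped to [0, length]. Parametrisation is by arc length,
#' so inserting collinear vertices does not change the result.
#' @keywords internal
#' @noRd
points_along <- function(geom, at) {
  cl <- polyline_cumlen(geom)
  total <- cl[length(cl)]
  at <- pmin(pmax(at, 0), total)
  seg <- findInterval(at, cl, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(geom) - 1L)
  seglen <- cl[seg + 1L] - cl[seg]
  frac <- ifelse(seglen > 0, (at - cl[seg]) / seglen, 0)
  cbind(
    geom[seg, 1L] + frac * (geom[seg + 1L, 1L] - geom[seg, 1L]),
    geom[seg, 2L] + frac * (geom[seg + 1L, 2L] - geom[seg, 2L])
  )
}

# Midpoints of n equal arc-length subdivisions (used for length-weighted
# sampling: each midpoint represents length/n metres of the line).
midpoints_along <- function(geom, n) {
  total <- polyline_length(geom)
  points_along(geom, (seq_len(n) - 0.5) * total / n)
}

# Minimum distance from one point to a polyline.
point_polyline_distance <- function(x, y, geom) {
  min(points_segments_distance(x, y, geom))
}

# Distances from points (vectors x, y) to the nearest segment of `geom`;
# returns a vector of length(x).
points_polyline_distance <- function(x, y, geom) {
  n <- nrow(geom) - 1L
  d <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    ax <- geom[i, 1L]; ay <- geom[i, 2L]
    bx <- geom[i + 1L, 1L]; by <- geom[i + 1L, 2L]
    vx <- bx - ax; vy <- by - ay
    l2 <- vx * vx + vy * vy
    if (l2 == 0) {
      di <- sqrt((x - ax)^2 + (y - ay)^2)
    } else {
      t <- pmin(pmax(((x - ax) * vx + (y - ay) * vy) / l2, 0), 1)
      di <- sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2)
    }
    d <- pmin(d, di)
  }
  d
}

# Distance from a single point to every segment of a polyline.
points_segments_distance <- function(x, y, geom) {
  points_polyline_distance(x, y, geom)
}

# Signed area of a single ring given as list(x=, y=) (shoelace).
ring_signed_area <- function(ring) {
  x <- ring$x; y <- ring$y
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# Area of a polyclip-style polygon (list of rings, holes carry opposite
# orientation so the signed sum is the net area).
polygon_area <- function(rings) {
  if (length(rings) == 0) return(0)
  abs(sum(vapply(rings, ring_signed_area, numeric(1))))
}

# Bounding box c(xmin, xmax, ymin, ymax) of a coordinate matrix.
coords_bbox <- function(geom) {
  c(min(geom[, 1L]), max(geom[, 1L]), min(geom[, 2L]), max(geom[, 2L]))
}

bbox_overlaps <- function(a, b) {
  a[1L] <= b[2L] && b[1L] <= a[2L] && a[3L] <= b[4L] && b[3L] <= a[4L]
}

# Length-weighted median: smallest value whose cumulative weight reaches
# half of the total.
weighted_median <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  o <- order(values)
  v <- values[o]; w <- weights[o]
  cw <- cumsum(w)
  v[which(cw >= sum(w) / 2)[1L]]
}
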