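# Low-level 2D polygon helpers shared by the outline, augmentation and mesh
# modules.  All polygons are n x 2 matrices of (x, y) in image coordinates:
# origin top-left, x rightward, y downward, 0-based continuous pixels.

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the state, so seeded package internals never disturb user RNG
#' streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

deg2rad <- function(d) d * pi / 180

#' Signed shoelace area of a closed polygon
#'
#' Computed in the mathematical convention (positive for counter-clockwise
#' with y upward).  Under the package's y-down image convention a polygon
#' that winds counter-clockwise *as drawn* has negative mathematical signed
#' area.
#'
#' @param xy n x 2 coordinate matrix.
#' @return Signed area (mathematical convention).
#' @keywords internal
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

polygon_area <- function(xy) abs(polygon_signed_area(xy))

# TRUE when the polygon winds counter-clockwise in image (y-down) coordinates.
is_ccw_image <- function(xy) polygon_signed_area(xy) < 0

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Proper / improper intersection test for two closed segments, excluding
# shared endpoints handled by the caller.
segments_intersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
  d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
  d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  on_seg <- function(p, a, b) {
    cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cr) > eps) return(FALSE)
    p[1] >= min(a[1], b[1]) - eps && p[1] <= max(a[1], b[1]) + eps &&
      p[2] >= min(a[2], b[2]) - eps && p[2] <= max(a[2], b[2]) + eps
  }
  if (abs(d1) <= eps && on_seg(p1, p3, p4)) return(TRUE)
  if (abs(d2) <= eps && on_seg(p2, p3, p4)) return(TRUE)
  if (abs(d3) <= eps && on_seg(p3, p1, p2)) return(TRUE)
  if (abs(d4) <= eps && on_seg(p4, p1, p2)) return(TRUE)
  FALSE
}

#' Find self-intersecting edge pairs of a closed polygon
#'
#' Brute-force O(n^2) test over all non-adjacent edge pairs.
#'
#' @param xy n x 2 coordinate matrix (closed implicitly).
#' @return Integer matrix with one row per intersecting pair of edge indices
#'   (1-based, edge i runs from vertex i to vertex i+1); zero rows when the
#'   polygon is simple.
#' @keywords internal
polygon_self_intersections <- function(xy) {
  n <- nrow(xy)
  nxt <- c(seq_len(n)[-1], 1L)
  hits <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # skip adjacent edges (they share a vertex by construction)
      if (j == i || j == i %% n + 1L || i == j %% n + 1L) next
      if (segments_intersect(xy[i, ], xy[nxt[i], ], xy[j, ], xy[nxt[j], ]))
        hits <- rbind(hits, c(i, j))
    }
  }
  if (is.null(hits)) matrix(integer(0), ncol = 2) else hits
}

polygon_is_simple <- function(xy) nrow(polygon_self_intersections(xy)) == 0

#' Even-odd point-in-polygon test
#'
#' @param px,py Coordinates of query points (vectors of equal length).
#' @param xy Polygon as n x 2 matrix.
#' @return Logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- logical(length(px))
  for (e in seq_len(n)) {
    crosses <- ((y[e] > py) != (yn[e] > py))
    if (any(crosses)) {
      xint <- x[e] + (py[crosses] - y[e]) * (xn[e] - x[e]) / (yn[e] - y[e])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

#' Closed uniform Catmull-Rom spline through control points
#'
#' Interpolating cubic through every control point, uniform parameterization.
#' Sampling excludes each segment's end point (it opens the next segment), so
#' the result has `nrow(xy) * samples_per_seg` vertices and passes through
#' control point `i` at output row `(i-1)*samples_per_seg + 1`.
#'
#' @param xy n x 2 control-point matrix (closed).
#' @param samples_per_seg Samples per control segment.
#' @return Dense polygon matrix.
#' @keywords internal
catmull_rom_closed <- function(xy, samples_per_seg = 8L) {
  n <- nrow(xy)
  t <- seq(0, 1, length.out = samples_per_seg + 1L)[-(samples_per_seg + 1L)]
  t2 <- t * t; t3 <- t2 * t
  b0 <- -0.5 * t + t2 - 0.5 * t3
  b1 <- 1 - 2.5 * t2 + 1.5 * t3
  b2 <- 0.5 * t + 2 * t2 - 1.5 * t3
  b3 <- -0.5 * t2 + 0.5 * t3
  out <- matrix(0, n * samples_per_seg, 2)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    p0 <- xy[idx(i - 1L), ]; p1 <- xy[idx(i), ]
    p2 <- xy[idx(i + 1L), ]; p3 <- xy[idx(i + 2L), ]
    rows <- ((i - 1L) * samples_per_seg + 1L):(i * samples_per_seg)
    out[rows, 1] <- b0 * p0[1] + b1 * p1[1] + b2 * p2[1] + b3 * p3[1]
    out[rows, 2] <- b0 * p0[2] + b1 * p1[2] + b2 * p2[2] + b3 * p3[2]
  }
  out
}

# Minimum distance from each query point to a closed polyline.
point_polyline_dist <- function(px, py, poly) {
  n <- nrow(poly)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  len2[len2 < 1e-300] <- 1e-300
  d <- rep(Inf, length(px))
  for (e in seq_len(n)) {
    t <- ((px - ax[e]) * dx[e] + (py - ay[e]) * dy[e]) / len2[e]
    t <- pmin(1, pmax(0, t))
    qx <- ax[e] + t * dx[e]; qy <- ay[e] + t * dy[e]
    d <- pmin(d, sqrt((px - qx)^2 + (py - qy)^2))
  }
  d
}

# Similarity transform about a fixed centre (angle in degrees, y-down frame).
rotate_scale_about <- function(xy, center, angle_deg, scale) {
  a <- deg2rad(angle_deg)
  ca <- cos(a); sa <- sin(a)
  dx <- xy[, 1] - center[1]; dy <- xy[, 2] - center[2]
  cbind(center[1] + scale * (ca * dx - sa * dy),
        center[2] + scale * (sa * dx + ca * dy))
}
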