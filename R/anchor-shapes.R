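# Parametric 2D anchor outlines: the 34-point-primitive contour type, eight
# shape-category presets, seeded exemplar generation and smooth perturbation.
#
# Index semantics (1-based, fixed across every category so that index-wise
# correspondence holds for interpolation and mesh binding):
#   1..10  base / root region (1 = inner base corner, 10 = outer base corner)
#   11..22 outer edge of the shaft, base to point
#   23..28 the recurved point (26 = tip apex)
#   29..34 inner edge returning to the base; fan-like extrusions (categories
#          5 and 7) and the accessory hook (category 8) live on 29..31

CANVAS_SIZE <- 96

#' Construct an anchor outline
#'
#' An `outline2d` is an ordered set of exactly 34 point primitives tracing a
#' simple closed anchor contour on the canonical 96 x 96 canvas, plus a shape
#' category in 1..8.  Vertex order is forced counter-clockwise in image
#' (y-down) coordinates; if the supplied points wind clockwise they are
#' reversed (keeping point 1 first).
#'
#' @param points 34 x 2 numeric matrix of (x, y) image coordinates.
#' @param category Integer shape category in 1..8.
#' @return An object of class `outline2d` with elements `points` and
#'   `category`.
#' @export
outline2d <- function(points, category) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2) stop("`points` must have two columns (x, y)")
  category <- as.integer(category)
  if (nrow(points) == 34 && !is_ccw_image(points)) {
    points <- points[c(1L, 34:2), , drop = FALSE]
  }
  structure(list(points = points, category = category), class = "outline2d")
}

#' @export
print.outline2d <- function(x, ...) {
  cat(sprintf("<outline2d> category %d, %d points, area %.1f px^2\n",
              x$category, nrow(x$points), polygon_area(x$points)))
  invisible(x)
}

#' Shape-category parameter presets
#'
#' Eight named presets, one per shape category, controlling the parametric
#' anchor construction: base width and root length (px), shaft length (px)
#' and total shaft curvature (degrees), the additional recurve turn of the
#' point (degrees), and the relative sizes of the optional fan-like extrusion
#' (categories 5 and 7) and accessory hook (category 8); 0 disables a
#' feature.
#'
#' @param category Integer in 1..8.
#' @return Named list of shape parameters.
#' @export
shape_category_params <- function(category) {
  category <- as.integer(category)
  if (length(category) != 1L || is.na(category) || category < 1L || category > 8L)
    stop("unknown shape category: must be an integer in 1..8")
  presets <- list(
    list(base_width = 14, root_length = 10, shaft_length = 46,
         shaft_curvature = 25, point_recurve_angle = 95,
         extrusion_size = 0, hook_size = 0),
    list(base_width = 10, root_length = 8, shaft_length = 54,
         shaft_curvature = 18, point_recurve_angle = 110,
         extrusion_size = 0, hook_size = 0),
    list(base_width = 18, root_length = 12, shaft_length = 40,
         shaft_curvature = 30, point_recurve_angle = 85,
         extrusion_size = 0, hook_size = 0),
    list(base_width = 13, root_length = 9, shaft_length = 48,
         shaft_curvature = 45, point_recurve_angle = 120,
         extrusion_size = 0, hook_size = 0),
    list(base_width = 14, root_length = 10, shaft_length = 46,
         shaft_curvature = 28, point_recurve_angle = 95,
         extrusion_size = 1.3, hook_size = 0),
    list(base_width = 12, root_length = 9, shaft_length = 50,
         shaft_curvature = 22, point_recurve_angle = 140,
         extrusion_size = 0, hook_size = 0),
    list(base_width = 16, root_length = 11, shaft_length = 44,
         shaft_curvature = 35, point_recurve_angle = 100,
         extrusion_size = 1.1, hook_size = 0),
    list(base_width = 13, root_length = 10, shaft_length = 47,
         shaft_curvature = 26, point_recurve_angle = 100,
         extrusion_size = 0, hook_size = 1.2)
  )
  presets[[category]]
}

# Scale and translate a point set isotropically so its bounding box fits
# centred in [lo, hi]^2.
fit_to_canvas <- function(xy, lo = 8, hi = 88) {
  rng_x <- range(xy[, 1]); rng_y <- range(xy[, 2])
  span <- max(rng_x[2] - rng_x[1], rng_y[2] - rng_y[1], 1e-9)
  s <- (hi - lo) / span
  cx <- mean(rng_x); cy <- mean(rng_y)
  mid <- (lo + hi) / 2
  cbind(mid + s * (xy[, 1] - cx), mid + s * (xy[, 2] - cy))
}

# Deterministic parametric construction of the 34 primitives from a preset.
build_anchor_points <- function(p) {
  point_length <- 0.38 * p$shaft_length
  L <- p$shaft_length + point_length
  n_c <- 400L
  ds <- L / n_c
  s_mid <- seq(ds / 2, L - ds / 2, length.out = n_c)
  turn <- ifelse(s_mid <= p$shaft_length,
                 p$shaft_curvature * s_mid / p$shaft_length,
                 p$shaft_curvature +
                   p$point_recurve_angle * (s_mid - p$shaft_length) / point_length)
  phi <- deg2rad(-90 + turn)
  cx <- cumsum(cos(phi) * ds)
  cy <- cumsum(sin(phi) * ds)
  # centreline and frame at arbitrary arc length s
  at <- function(s) {
    s <- pmin(pmax(s, 0), L)
    i <- pmin(pmax(ceiling(s / ds), 1L), n_c)
    tu <- ifelse(s <= p$shaft_length,
                 p$shaft_curvature * s / p$shaft_length,
                 p$shaft_curvature +
                   p$point_recurve_angle * (s - p$shaft_length) / point_length)
    ph <- deg2rad(-90 + tu)
    list(x = c(0, cx)[i] + (s - (i - 1) * ds) * cos(ph),
         y = c(0, cy)[i] + (s - (i - 1) * ds) * sin(ph),
         nx = -sin(ph), ny = cos(ph))
  }
  w0 <- p$base_width / 2
  half_width <- function(s) pmax(w0 * (1 - 0.85 * (s / L)^1.2), 0.8)
  edge <- function(s, side, wmult = 1) {
    f <- at(s)
    w <- half_width(s) * wmult
    cbind(f$x + side * f$nx * w, f$y + side * f$ny * w)
  }

  Ls <- p$shaft_length; Lp <- point_length
  # outer edge of the shaft (11..22)
  outer <- edge(Ls * seq(0.12, 1, length.out = 12), +1)
  # around the recurved point (23..28)
  tip_out <- edge(Ls + Lp * c(0.30, 0.55, 0.78), +1)
  apex_f <- at(L)
  apex <- cbind(apex_f$x + cos(deg2rad(-90 + p$shaft_curvature + p$point_recurve_angle)),
                apex_f$y + sin(deg2rad(-90 + p$shaft_curvature + p$point_recurve_angle)))
  tip_in <- edge(Ls + Lp * c(0.75, 0.45), -1)
  # inner edge back to the base (29..34), carrying extrusion / hook bumps
  s_in <- Ls * seq(0.95, 0.10, length.out = 6)
  wmult_in <- rep(1, 6)
  if (p$extrusion_size > 0) wmult_in[1:3] <- 1 + p$extrusion_size * c(0.55, 1, 0.45)
  if (p$hook_size > 0) wmult_in[1:3] <- 1 + p$hook_size * c(0.15, 1.5, 0.15)
  inner <- edge(s_in, -1, wmult_in)
  # base / root region (1..10): inner corner, root lobes, outer corner
  A <- edge(0, -1); B <- edge(0, +1)
  ab <- B - A
  ab_len <- sqrt(sum(ab^2))
  u_ab <- ab / ab_len
  d_dn <- c(-u_ab[2], u_ab[1])              # perpendicular, oriented downward
  if (d_dn[2] < 0) d_dn <- -d_dn
  M <- (A + B) / 2
  u <- seq(0, 1, length.out = 10)
  lobes <- 0.55 * sin(pi * u) + 0.45 * abs(sin(2 * pi * u))
  lobes <- lobes / max(lobes)
  spread <- (u - 0.5) * ab_len * (1 + 0.55 * sin(pi * u))
  base <- cbind(M[1] + spread * u_ab[1] + d_dn[1] * p$root_length * lobes,
                M[2] + spread * u_ab[2] + d_dn[2] * p$root_length * lobes)
  pts <- rbind(base, outer, tip_out, apex, tip_in, inner)
  fit_to_canvas(pts)
}

#' Generate a synthetic anchor exemplar outline
#'
#' Builds the parametric outline for one of the eight shape categories, with a
#' small seeded jitter (about +/-3 percent) on the shape parameters so
#' different seeds yield distinct but structurally identical exemplars.
#' Deterministic for a fixed (category, seed) pair.
#'
#' @param category Integer shape category in 1..8.  Categories 5 and 7 carry
#'   a fan-like extrusion; category 8 carries an accessory hook.
#' @param seed Integer seed.
#' @return A valid [outline2d()].
#' @export
generate_exemplar <- function(category, seed = 0L) {
  p <- shape_category_params(category)  # validates category
  out <- with_seed(1000003 * (as.integer(seed) %% 131071L) + category, {
    for (attempt in 1:20) {
      q <- p
      for (nm in names(q)) {
        if (q[[nm]] > 0) q[[nm]] <- q[[nm]] * stats::runif(1, 0.97, 1.03)
      }
      cand <- outline2d(build_anchor_points(q), category)
      if (length(validate_outline(cand)) == 0) break
      cand <- NULL
    }
    cand
  })
  if (is.null(out)) stop("degenerate exemplar: could not build a simple outline")
  out
}

#' Perturb an outline with a smooth random displacement field
#'
#' Draws independent Gaussian displacements per primitive, smooths them with a
#' circular Gaussian kernel along the contour (so neighbouring primitives move
#' coherently rather than jittering independently), rescales the field so the
#' largest point displacement equals `magnitude`, and applies it.  Candidates
#' violating the outline invariants (self-intersection, out of canvas) are
#' resampled up to `max_retries` times.
#'
#' @param outline An [outline2d()].
#' @param magnitude Maximum point displacement in pixels (>= 0); 0 returns
#'   the input unchanged.
#' @param seed Integer seed.
#' @param max_retries Resampling attempts before giving up.
#' @return A valid perturbed [outline2d()] of the same category.
#' @export
perturb_exemplar <- function(outline, magnitude, seed = 0L, max_retries = 50L) {
  stopifnot(inherits(outline, "outline2d"), magnitude >= 0)
  if (magnitude == 0) return(outline)
  n <- nrow(outline$points)
  kern <- stats::dnorm(-5:5, sd = 2.2)
  kern <- kern / sum(kern)
  with_seed(2000003 * (as.integer(seed) %% 131071L) + 17L, {
    for (attempt in seq_len(max_retries)) {
      d <- matrix(stats::rnorm(2 * n), n, 2)
      sm <- matrix(0, n, 2)
      for (k in seq_along(kern)) {
        sh <- k - 6L
        idx <- ((seq_len(n) - 1L + sh) %% n) + 1L
        sm <- sm + kern[k] * d[idx, ]
      }
      norms <- sqrt(rowSums(sm^2))
      sm <- sm * (magnitude / max(norms))
      cand <- outline2d(outline$points + sm, outline$category)
      if (length(validate_outline(cand)) == 0) return(cand)
    }
    stop("degenerate shape: perturbation retries exhausted")
  })
}

#' Check an outline against its structural invariants
#'
#' Violations are returned as data, not raised: point count 34, category in
#' 1..8, all coordinates inside the 96 x 96 canvas, simple (non
#' self-intersecting) closed polygon with positive area, counter-clockwise
#' vertex order in image coordinates.
#'
#' @param outline An `outline2d` (possibly malformed).
#' @return A list of violations, empty when all invariants hold.  Each
#'   violation is a list with elements `invariant`, `index` (offending point
#'   or edge index, NA when global) and `message`.
#' @export
validate_outline <- function(outline) {
  v <- list()
  add <- function(invariant, index, message)
    v[[length(v) + 1L]] <<- list(invariant = invariant, index = index,
                                 message = message)
  pts <- outline$points
  if (!is.matrix(pts) || ncol(pts) != 2 || nrow(pts) != 34) {
    add("point-count", NA_integer_,
        sprintf("expected 34 points, found %d", if (is.matrix(pts)) nrow(pts) else length(pts)))
    return(v)
  }
  if (is.null(outline$category) || is.na(outline$category) ||
      outline$category < 1L || outline$category > 8L)
    add("category-range", NA_integer_,
        sprintf("category must be in 1..8, found %s", format(outline$category)))
  bad <- which(!is.finite(pts[, 1]) | !is.finite(pts[, 2]) |
                 pts[, 1] < 0 | pts[, 1] >= CANVAS_SIZE |
                 pts[, 2] < 0 | pts[, 2] >= CANVAS_SIZE)
  for (i in bad)
    add("out-of-canvas", i,
        sprintf("point %d = (%.3f, %.3f) outside [0, %d)", i, pts[i, 1], pts[i, 2], CANVAS_SIZE))
  if (length(bad) == 0 || all(is.finite(pts))) {
    xs <- polygon_self_intersections(pts)
    for (r in seq_len(nrow(xs)))
      add("self-intersection", xs[r, 1],
          sprintf("edges %d and %d cross", xs[r, 1], xs[r, 2]))
    area <- polygon_area(pts)
    if (area <= 1e-9)
      add("zero-area", NA_integer_, "polygon has non-positive area")
    if (area > 1e-9 && !is_ccw_image(pts))
      add("orientation", NA_integer_,
          "vertex order is clockwise in image coordinates")
  }
  v
}

#' Write an outline to CSV
#'
#' 34 rows, columns `x,y`, header emitted, 6-decimal fixed-point values.
#'
#' @param outline An [outline2d()] (or bare 34 x 2 matrix).
#' @param path Output file path.
#' @export
write_outline_csv <- function(outline, path) {
  pts <- if (inherits(outline, "outline2d")) outline$points else as.matrix(outline)
  lines <- c("x,y", sprintf("%.6f,%.6f", pts[, 1], pts[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an outline from CSV
#'
#' Accepts 34 rows of `x,y` with or without a header line.
#'
#' @param path CSV file path.
#' @param category Shape category to attach (default 1).
#' @return An [outline2d()].
#' @export
read_outline_csv <- function(path, category = 1L) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  df <- utils::read.csv(path, header = has_header,
                        col.names = c("x", "y"), colClasses = "numeric")
  outline2d(cbind(df$x, df$y), category)
}
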