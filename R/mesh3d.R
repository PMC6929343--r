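# Generic 3D anchor model and landmark-driven deformation.  The mesh is a
# watertight two-sheet inflation of the outline's spline contour: the contour
# interior is triangulated, each sheet gets z = +/- thickness*sqrt(d/d_max)
# (d = distance to the contour), and the sheets share the z = 0 boundary
# ring.  Every vertex carries mean-value-coordinate weights over the 34
# control primitives, so moving the primitives onto predicted landmarks
# deforms the whole solid.

point_in_triangle <- function(px, py, a, b, c, eps = 1e-9) {
  d1 <- (px - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (py - b[2])
  d2 <- (px - c[1]) * (b[2] - c[2]) - (b[1] - c[1]) * (py - c[2])
  d3 <- (px - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (py - a[2])
  neg <- (d1 < -eps) | (d2 < -eps) | (d3 < -eps)
  pos <- (d1 > eps) | (d2 > eps) | (d3 > eps)
  !(neg & pos)
}

# Ear-clipping triangulation of a simple polygon (any orientation).
# Returns an m x 3 matrix of vertex indices wound like the input polygon.
ear_clip <- function(xy) {
  n <- nrow(xy)
  orient <- sign(polygon_signed_area(xy))
  idx <- seq_len(n)
  tris <- matrix(0L, n - 2L, 3L)
  nt <- 0L
  while (length(idx) > 3L) {
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      a <- idx[((k - 2L) %% m) + 1L]
      b <- idx[((k - 1L) %% m) + 1L]
      cc <- idx[(k %% m) + 1L]
      cr <- (xy[b, 1] - xy[a, 1]) * (xy[cc, 2] - xy[b, 2]) -
        (xy[b, 2] - xy[a, 2]) * (xy[cc, 1] - xy[b, 1])
      if (cr * orient <= 1e-12) next
      others <- idx[!(idx %in% c(a, b, cc))]
      if (length(others) &&
          any(point_in_triangle(xy[others, 1], xy[others, 2],
                                xy[a, ], xy[b, ], xy[cc, ])))
        next
      nt <- nt + 1L
      tris[nt, ] <- c(a, b, cc)
      idx <- idx[idx != b]
      clipped <- TRUE
      break
    }
    if (!clipped) stop("geometry error: ear clipping failed on the contour")
  }
  nt <- nt + 1L
  tris[nt, ] <- idx
  tris[seq_len(nt), , drop = FALSE]
}

# Conforming longest-edge bisection until no edge exceeds hmax.  Vertex and
# face tables are preallocated and edge lengths updated incrementally; every
# face sharing the split edge is split too, so the triangulation stays
# conforming at each step.
refine_triangulation <- function(V, F, hmax) {
  grow_v <- max(4096L, 8L * nrow(V))
  grow_f <- 2L * grow_v
  Vb <- rbind(V, matrix(0, grow_v, 2))
  Fb <- rbind(F, matrix(0L, grow_f, 3L))
  nV <- nrow(V); nF <- nrow(F)
  alive <- c(rep(TRUE, nF), rep(FALSE, grow_f))
  elen <- matrix(0, nF + grow_f, 3L)
  edge_len <- function(f) {
    tr <- Fb[f, ]
    c(sqrt(sum((Vb[tr[1], ] - Vb[tr[2], ])^2)),
      sqrt(sum((Vb[tr[2], ] - Vb[tr[3], ])^2)),
      sqrt(sum((Vb[tr[3], ] - Vb[tr[1], ])^2)))
  }
  for (f in seq_len(nF)) elen[f, ] <- edge_len(f)
  longest <- rep(-Inf, nF + grow_f)
  longest[seq_len(nF)] <- apply(elen[seq_len(nF), , drop = FALSE], 1, max)
  add_face <- function(tr) {
    nF <<- nF + 1L
    if (nF > nrow(Fb)) {
      Fb <<- rbind(Fb, matrix(0L, grow_f, 3L))
      alive <<- c(alive, rep(FALSE, grow_f))
      elen <<- rbind(elen, matrix(0, grow_f, 3L))
      longest <<- c(longest, rep(-Inf, grow_f))
    }
    Fb[nF, ] <<- tr
    alive[nF] <<- TRUE
    e <- edge_len(nF)
    elen[nF, ] <<- e
    longest[nF] <<- max(e)
  }
  repeat {
    f <- which.max(longest)
    if (longest[f] <= hmax) break
    le <- which.max(elen[f, ])
    a <- Fb[f, le]; b <- Fb[f, (le %% 3L) + 1L]
    nV <- nV + 1L
    if (nV > nrow(Vb)) Vb <- rbind(Vb, matrix(0, grow_v, 2))
    Vb[nV, ] <- (Vb[a, ] + Vb[b, ]) / 2
    act <- which(alive)
    Fa <- Fb[act, , drop = FALSE]
    share <- act[(Fa[, 1] == a | Fa[, 2] == a | Fa[, 3] == a) &
                   (Fa[, 1] == b | Fa[, 2] == b | Fa[, 3] == b)]
    for (fi in share) {
      tr <- Fb[fi, ]
      while (!((tr[1] == a && tr[2] == b) || (tr[1] == b && tr[2] == a)))
        tr <- tr[c(2L, 3L, 1L)]
      alive[fi] <- FALSE
      longest[fi] <- -Inf
      add_face(c(tr[1], nV, tr[3]))
      add_face(c(nV, tr[2], tr[3]))
    }
  }
  list(V = Vb[seq_len(nV), , drop = FALSE],
       F = Fb[alive, , drop = FALSE])
}

tri_signed_area2 <- function(V, F) {
  (V[F[, 2], 1] - V[F[, 1], 1]) * (V[F[, 3], 2] - V[F[, 1], 2]) -
    (V[F[, 2], 2] - V[F[, 1], 2]) * (V[F[, 3], 1] - V[F[, 1], 1])
}

# Jacobi-style Laplacian smoothing of interior vertices with fold-over
# rejection: after each sweep, vertices incident to any flipped or collapsed
# face are reverted (repeatedly, until no flips remain).
smooth_interior <- function(V, F, boundary, iters = 8) {
  n <- nrow(V)
  is_int <- rep(TRUE, n)
  is_int[boundary] <- FALSE
  if (!any(is_int)) return(V)
  from <- c(F[, 1], F[, 2], F[, 2], F[, 3], F[, 3], F[, 1])
  to <- c(F[, 2], F[, 1], F[, 3], F[, 2], F[, 1], F[, 3])
  deg <- tabulate(from, nbins = n)
  orient <- sign(sum(tri_signed_area2(V, F)))
  for (it in seq_len(iters)) {
    sums <- rowsum(V[to, , drop = FALSE], from, reorder = TRUE)
    cand <- V
    cand[is_int, ] <- sums[is_int, , drop = FALSE] / deg[is_int]
    for (pass in 1:10) {
      bad <- tri_signed_area2(cand, F) * orient <= 1e-9
      if (!any(bad)) break
      revert <- unique(as.vector(F[bad, ]))
      cand[revert, ] <- V[revert, ]
    }
    if (!any(bad)) V <- cand
  }
  V
}

#' Build the generic watertight 3D anchor mesh from an outline
#'
#' The outline's closed Catmull-Rom contour is resampled at roughly the
#' target edge length (keeping the 34 primitives as exact boundary
#' vertices), its interior triangulated and refined, and two mirrored sheets
#' are inflated with per-vertex z = +/- thickness * sqrt(d / d_max), where d
#' is the distance to the contour; the sheets share the z = 0 boundary ring,
#' giving a closed (watertight) solid whose silhouette is the outline.
#'
#' @param outline A valid [outline2d()].
#' @param thickness Maximum half-thickness of the solid (pixels).
#' @param refinement Target triangle edge length (pixels).
#' @return An `anchor_mesh` with `vertices` (V x 3), `faces` (F x 3, 1-based,
#'   outward orientation), `boundary_map` (indices of the 34 control
#'   vertices) and the source `outline`.
#' @export
build_generic_mesh <- function(outline, thickness = 6, refinement = 2) {
  stopifnot(inherits(outline, "outline2d"))
  if (length(validate_outline(outline)) > 0)
    stop("geometry error: outline fails validation")
  dense <- catmull_rom_closed(outline$points, 8L)
  # resample the contour at ~`refinement` spacing, keeping the primitives
  keep <- integer(0)
  prim_rows <- integer(34)
  for (i in 1:34) {
    seg <- dense[((i - 1L) * 8L + 1L):(i * 8L), , drop = FALSE]
    seg_len <- sum(sqrt(rowSums((seg[-1, , drop = FALSE] - seg[-8, , drop = FALSE])^2)))
    n_keep <- max(1L, min(8L, ceiling(seg_len / refinement)))
    rows <- (i - 1L) * 8L + unique(round(seq(1L, 8L, length.out = n_keep + 1L)[-(n_keep + 1L)]))
    prim_rows[i] <- length(keep) + 1L
    keep <- c(keep, rows)
  }
  ring <- dense[keep, , drop = FALSE]
  nb <- nrow(ring)
  F0 <- ear_clip(ring)
  ref <- refine_triangulation(ring, F0, hmax = refinement * 1.6)
  V2 <- ref$V; F2 <- ref$F
  # boundary = every vertex on an edge used by exactly one face
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  boundary_verts <- function(F) {
    edges <- c(ekey(F[, 1], F[, 2]), ekey(F[, 2], F[, 3]), ekey(F[, 3], F[, 1]))
    tab <- table(edges)
    bedges <- names(tab)[tab == 1L]
    unique(as.integer(unlist(strsplit(bedges, " "))))
  }
  # interior chords joining two boundary vertices would be shared by four
  # faces once the two sheets are glued; split them (their midpoints lie
  # strictly inside, becoming interior vertices)
  repeat {
    bverts <- boundary_verts(F2)
    is_b <- seq_len(nrow(V2)) %in% bverts
    edges <- rbind(F2[, 1:2], F2[, 2:3], F2[, c(3, 1)])
    keys <- ekey(edges[, 1], edges[, 2])
    tab <- table(keys)
    chord <- is_b[edges[, 1]] & is_b[edges[, 2]] & tab[keys] == 2L
    if (!any(chord)) break
    ab <- edges[which(chord)[1], ]
    a <- ab[1]; b <- ab[2]
    V2 <- rbind(V2, (V2[a, ] + V2[b, ]) / 2)
    mv <- nrow(V2)
    share <- which((F2[, 1] == a | F2[, 2] == a | F2[, 3] == a) &
                     (F2[, 1] == b | F2[, 2] == b | F2[, 3] == b))
    newF <- NULL
    for (fi in share) {
      tr <- F2[fi, ]
      while (!((tr[1] == a && tr[2] == b) || (tr[1] == b && tr[2] == a)))
        tr <- tr[c(2L, 3L, 1L)]
      newF <- rbind(newF, c(tr[1], mv, tr[3]), c(mv, tr[2], tr[3]))
    }
    F2 <- rbind(F2[-share, , drop = FALSE], newF)
  }
  V2 <- smooth_interior(V2, F2, bverts)
  # inflation profile from distance to the sheet's own boundary ring
  d <- point_polyline_dist(V2[, 1], V2[, 2], ring)
  d[bverts] <- 0
  dmax <- max(d)
  z <- if (dmax > 0) thickness * sqrt(d / dmax) else rep(0, nrow(V2))
  nV <- nrow(V2)
  is_b <- seq_len(nV) %in% bverts
  # top sheet keeps every vertex; bottom sheet duplicates interior vertices
  bot_id <- integer(nV)
  bot_id[is_b] <- which(is_b)  # placeholder, remapped below
  map_bot <- integer(nV)
  map_bot[is_b] <- seq_len(nV)[is_b]
  extra <- which(!is_b)
  map_bot[extra] <- nV + seq_along(extra)
  Vtop <- cbind(V2, z)
  Vbot <- cbind(V2[extra, , drop = FALSE], -z[extra])
  vertices <- rbind(Vtop, Vbot)
  Ftop <- F2
  Fbot <- cbind(map_bot[F2[, 1]], map_bot[F2[, 3]], map_bot[F2[, 2]])
  faces <- rbind(Ftop, Fbot)
  mesh <- structure(list(vertices = vertices, faces = faces,
                         boundary_map = prim_rows,
                         outline = outline),
                    class = "anchor_mesh")
  # enforce outward orientation (positive signed volume)
  if (mesh_signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' @export
print.anchor_mesh <- function(x, ...) {
  cat(sprintf("<anchor_mesh> %d vertices, %d faces, %d control primitives\n",
              nrow(x$vertices), nrow(x$faces), length(x$boundary_map)))
  invisible(x)
}

mesh_signed_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
        a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
        a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

tri_area3d <- function(V, F) {
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Check mesh invariants
#'
#' Watertightness (every edge shared by exactly two faces), Euler
#' characteristic V - E + F = 2, consistent orientation (each shared edge
#' traversed once in each direction), no degenerate faces, and — when the
#' mesh carries its source outline — boundary vertices realizing the 34
#' primitives at z = 0.
#'
#' @param mesh An `anchor_mesh`.
#' @return List of violations (same shape as [validate_outline()]'s), empty
#'   when the mesh is sound.
#' @export
validate_mesh <- function(mesh) {
  v <- list()
  add <- function(invariant, index, message)
    v[[length(v) + 1L]] <<- list(invariant = invariant, index = index, message = message)
  V <- mesh$vertices; F <- mesh$faces
  he <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  tab <- table(und)
  if (any(tab != 2L))
    add("watertight", NA_integer_,
        sprintf("%d edges not shared by exactly two faces", sum(tab != 2L)))
  dir_key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(dir_key))
    add("orientation", NA_integer_,
        "a directed edge is traversed twice (inconsistent winding)")
  nE <- length(tab)
  chi <- nrow(V) - nE + nrow(F)
  if (chi != 2L)
    add("euler-characteristic", NA_integer_,
        sprintf("V - E + F = %d (expected 2)", chi))
  areas <- tri_area3d(V, F)
  for (f in which(areas < 1e-9))
    add("degenerate-face", f, sprintf("face %d has near-zero area", f))
  if (length(mesh$boundary_map) == 0L) {
    # imported meshes carry no control metadata; geometric checks only
  } else if (length(mesh$boundary_map) != 34L) {
    add("boundary-map", NA_integer_,
        sprintf("expected 34 control vertices, found %d", length(mesh$boundary_map)))
  } else {
    bz <- V[mesh$boundary_map, 3]
    for (j in which(abs(bz) > 1e-9))
      add("boundary-map", j, sprintf("control vertex %d has z = %g", j, bz[j]))
    if (!is.null(mesh$outline)) {
      dxy <- sqrt(rowSums((V[mesh$boundary_map, 1:2, drop = FALSE] -
                             mesh$outline$points)^2))
      for (j in which(dxy > 1e-6))
        add("boundary-map", j,
            sprintf("control vertex %d off its primitive by %.2g px", j, dxy[j]))
    }
  }
  v
}

#' Is a mesh watertight and consistently oriented?
#' @param mesh An `anchor_mesh`.
#' @return TRUE when [validate_mesh()] reports no violations.
#' @export
is_watertight <- function(mesh) length(validate_mesh(mesh)) == 0

# General mean value coordinates (Hormann-Floater tangent formula), defined
# for arbitrary points not on the polygon boundary; points within `tol` of a
# vertex or edge get the exact boundary rule (indicator / edge-linear).
# Vectorized over query points: P is m x 2, polygon n x 2; returns m x n.
mvc_weights_matrix <- function(P, polygon, tol = 1e-9) {
  m <- nrow(P); n <- nrow(polygon)
  W <- matrix(0, m, n)
  sx <- outer(rep(1, m), polygon[, 1]) - P[, 1]
  sy <- outer(rep(1, m), polygon[, 2]) - P[, 2]
  r <- sqrt(sx^2 + sy^2)
  nxt <- c(2:n, 1L)
  A <- sx * sy[, nxt] - sy * sx[, nxt]        # 2 * signed triangle area
  D <- sx * sx[, nxt] + sy * sy[, nxt]
  at_vertex <- r < tol
  on_edge <- (abs(A) < tol * pmax(1, r * r[, nxt])) & (D < 0)
  special <- rowSums(at_vertex) > 0 | rowSums(on_edge) > 0
  reg <- which(!special)
  if (length(reg)) {
    # tan(alpha/2) = A / (r r' + D): stable for small angles; the D < 0
    # (on-edge) singularity is handled by the special-case branch above
    t_half <- A[reg, , drop = FALSE] /
      (r[reg, , drop = FALSE] * r[reg, nxt, drop = FALSE] +
         D[reg, , drop = FALSE])
    prv <- c(n, 1:(n - 1L))
    Wr <- (t_half[, prv, drop = FALSE] + t_half) / r[reg, , drop = FALSE]
    W[reg, ] <- Wr / rowSums(Wr)
  }
  for (i in which(special)) {
    if (any(at_vertex[i, ])) {
      j <- which.min(r[i, ])
      W[i, j] <- 1
    } else {
      e <- which(on_edge[i, ])[1]
      j <- e; j2 <- nxt[e]
      W[i, j] <- r[i, j2] / (r[i, j] + r[i, j2])
      W[i, j2] <- r[i, j] / (r[i, j] + r[i, j2])
    }
  }
  W
}

#' Mean value coordinates of a point with respect to a control polygon
#'
#' Generalized barycentric weights with linear precision: the weighted sum
#' of the polygon vertices reproduces the query point.  On an edge the
#' weights interpolate the edge's endpoints linearly; at a vertex they are
#' the indicator.  The point must lie inside or on the polygon.
#'
#' @param point Numeric (x, y).
#' @param polygon n x 2 control-point matrix (simple closed polygon).
#' @return Numeric weight vector of length n summing to 1.
#' @export
mean_value_weights <- function(point, polygon) {
  polygon <- as.matrix(polygon)
  P <- matrix(point, 1, 2)
  on_bd <- point_polyline_dist(P[1], P[2], polygon) < 1e-9
  if (!on_bd && !point_in_polygon(P[1], P[2], polygon))
    stop("point outside polygon")
  as.numeric(mvc_weights_matrix(P, polygon))
}

#' Bind every mesh vertex to the 34 control primitives
#'
#' Computes mean-value-coordinate weights of each vertex's (x, y) with
#' respect to the outline's control polygon.  Vertices realizing a control
#' primitive get exact indicator weights.
#'
#' @param mesh An `anchor_mesh` built from `outline`.
#' @param outline The [outline2d()] the mesh was built from (defaults to the
#'   one stored in the mesh).
#' @return A V x 34 weight matrix (rows sum to 1), class `control_binding`.
#' @export
bind_mesh <- function(mesh, outline = mesh$outline) {
  W <- mvc_weights_matrix(mesh$vertices[, 1:2, drop = FALSE], outline$points)
  W[mesh$boundary_map, ] <- diag(34)
  class(W) <- c("control_binding", class(W))
  W
}

#' Deform a mesh by moving its control primitives onto landmarks
#'
#' Each vertex's new (x, y) is the binding-weighted combination of the
#' landmark positions; z, faces and the boundary map are untouched, so the
#' topology (and watertightness) is preserved and the boundary ring lands on
#' the landmark polygon.
#'
#' @param mesh An `anchor_mesh`.
#' @param binding The [bind_mesh()] weight matrix.
#' @param landmarks 34 x 2 matrix of target landmark positions forming a
#'   simple polygon.
#' @return The deformed `anchor_mesh`.
#' @export
deform_mesh <- function(mesh, binding, landmarks) {
  landmarks <- as.matrix(landmarks)
  stopifnot(nrow(landmarks) == 34L, ncol(landmarks) == 2L)
  if (!polygon_is_simple(landmarks))
    stop("deformation degeneracy: landmark polygon self-intersects")
  xy <- unclass(binding) %*% landmarks
  out <- mesh
  out$vertices[, 1:2] <- xy
  out$outline <- outline2d(landmarks, mesh$outline$category)
  out
}

#' Export a mesh as Wavefront OBJ or ASCII PLY
#'
#' OBJ uses `v`/`f` records with 1-based indices; PLY uses the ASCII 1.0
#' format with 0-based indices.  Coordinates are written with 6 decimals, so
#' re-importing reproduces vertices to 1e-6 and faces exactly.
#'
#' @param mesh An `anchor_mesh`.
#' @param path Output file path.
#' @param format `"obj"` or `"ply"` (default guessed from the extension).
#' @export
export_mesh <- function(mesh, path, format = c("obj", "ply")) {
  if (length(format) > 1L) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("obj", "ply")) ext else "obj"
  }
  format <- match.arg(format)
  V <- mesh$vertices; F <- mesh$faces
  lines <- if (format == "obj") {
    c("# anchor3d watertight anchor mesh",
      sprintf("v %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]),
      sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]))
  } else {
    c("ply", "format ascii 1.0", "comment anchor3d watertight anchor mesh",
      sprintf("element vertex %d", nrow(V)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(F)),
      "property list uchar int vertex_indices", "end_header",
      sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]),
      sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Import a mesh written by [export_mesh()]
#'
#' @param path OBJ or PLY file path.
#' @return An `anchor_mesh` (without boundary map or outline).
#' @export
import_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) > 0 && lines[1] == "ply") {
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
    body <- seq(which(lines == "end_header") + 1L, length(lines))
    vl <- lines[body[seq_len(nv)]]
    fl <- lines[body[nv + seq_len(nf)]]
    V <- do.call(rbind, lapply(strsplit(vl, " "), as.numeric))
    F <- do.call(rbind, lapply(strsplit(fl, " "),
                               function(x) as.integer(x[2:4]) + 1L))
  } else {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    V <- do.call(rbind, lapply(strsplit(sub("^v ", "", vl), " "), as.numeric))
    F <- do.call(rbind, lapply(strsplit(sub("^f ", "", fl), " "), as.integer))
  }
  structure(list(vertices = V, faces = F, boundary_map = integer(0),
                 outline = NULL), class = "anchor_mesh")
}
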