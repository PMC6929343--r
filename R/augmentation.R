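# Semi-automated data augmentation: morph a source outline to a perturbed
# target, capture the in-between frames, randomly rotate/scale each frame and
# rasterize it to an annotated 96 x 96 grayscale training record.

#' Canvas specification for rasterization
#'
#' @param width,height Canvas size in pixels (both fixed at 96).
#' @param background_intensity,foreground_intensity Grayscale fill levels in
#'   0..255 (white background, black shape by default).
#' @param margin Pixels kept clear of the shape after random transforms.
#' @return A `canvas_spec` object.
#' @export
canvas_spec <- function(width = 96L, height = 96L,
                        background_intensity = 255L,
                        foreground_intensity = 0L, margin = 2) {
  stopifnot(width == 96L, height == 96L,
            background_intensity >= 0, background_intensity <= 255,
            foreground_intensity >= 0, foreground_intensity <= 255,
            margin >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 background_intensity = as.integer(background_intensity),
                 foreground_intensity = as.integer(foreground_intensity),
                 margin = margin),
            class = "canvas_spec")
}

#' Linearly interpolate between two corresponding outlines
#'
#' Morphs `source` into `target` by index-wise linear interpolation,
#' capturing `n_frames` shapes strictly between the endpoints: frame i uses
#' blending weight t_i = i / (n_frames + 1).
#'
#' @param source,target Valid [outline2d()] objects of the same category.
#' @param n_frames Number of captured frames (default 24).
#' @return List of `n_frames` outlines.
#' @export
interpolate_shapes <- function(source, target, n_frames = 24L) {
  stopifnot(inherits(source, "outline2d"), inherits(target, "outline2d"),
            n_frames >= 1)
  if (source$category != target$category)
    stop("source and target outlines have different shape categories")
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    t <- i / (n_frames + 1)
    f <- outline2d((1 - t) * source$points + t * target$points,
                   source$category)
    viol <- validate_outline(f)
    if (length(viol) > 0)
      stop(sprintf("interpolation degeneracy at frame %d: %s", i,
                   viol[[1]]$message))
    frames[[i]] <- f
  }
  frames
}

#' Apply a random similarity transform to an outline
#'
#' Rotation is drawn uniformly from [0, 360) degrees and the isotropic scale
#' uniformly from [0.6, 1.0] times the largest scale that keeps the rotated
#' shape inside the canvas minus `margin`; both are applied about the outline
#' centroid.  Candidates violating the outline invariants are resampled.
#'
#' @param outline A valid [outline2d()].
#' @param margin Margin kept clear at every canvas edge (pixels).
#' @param angle,scale Optional fixed values overriding the random draws
#'   (`scale` is the absolute scale factor); used for deterministic testing.
#' @param max_retries Resampling attempts before giving up.
#' @return Transformed [outline2d()].
#' @export
random_similarity_transform <- function(outline, margin = 2,
                                        angle = NULL, scale = NULL,
                                        max_retries = 50L) {
  stopifnot(inherits(outline, "outline2d"))
  ctr <- colMeans(outline$points)
  lo <- margin
  hi <- CANVAS_SIZE - margin
  if (ctr[1] <= lo || ctr[1] >= hi || ctr[2] <= lo || ctr[2] >= hi)
    stop("transform placement error: outline centroid outside usable canvas")
  for (attempt in seq_len(max_retries)) {
    a <- if (is.null(angle)) stats::runif(1, 0, 360) else angle
    rot <- rotate_scale_about(outline$points, ctr, a, 1)
    dx <- rot[, 1] - ctr[1]; dy <- rot[, 2] - ctr[2]
    s_max <- Inf
    pos <- dx > 0; neg <- dx < 0
    if (any(pos)) s_max <- min(s_max, (hi - 1e-6 - ctr[1]) / max(dx[pos]))
    if (any(neg)) s_max <- min(s_max, (lo - ctr[1]) / min(dx[neg]))
    pos <- dy > 0; neg <- dy < 0
    if (any(pos)) s_max <- min(s_max, (hi - 1e-6 - ctr[2]) / max(dy[pos]))
    if (any(neg)) s_max <- min(s_max, (lo - ctr[2]) / min(dy[neg]))
    s <- if (is.null(scale)) stats::runif(1, 0.6, 1.0) * s_max else scale
    cand <- outline2d(rotate_scale_about(outline$points, ctr, a, s),
                      outline$category)
    if (length(validate_outline(cand)) == 0) return(cand)
    if (!is.null(angle) && !is.null(scale)) break
  }
  stop("transform placement error: retries exhausted")
}

#' Rasterize an outline to a 96 x 96 grayscale pixel array
#'
#' The closed contour through the 34 primitives is smoothed by a uniform
#' closed Catmull-Rom spline (8 samples per segment) and filled with the
#' foreground intensity on the background, 4x supersampled and box
#' down-sampled.  The result is flattened row-major (row = y) to 9216
#' integers in 0..255.
#'
#' @param outline An [outline2d()] lying fully inside the canvas.
#' @param canvas A [canvas_spec()].
#' @return Integer vector of length 9216.
#' @export
rasterize <- function(outline, canvas = canvas_spec()) {
  pts <- if (inherits(outline, "outline2d")) outline$points else as.matrix(outline)
  if (any(!is.finite(pts)) || any(pts < 0) || any(pts >= CANVAS_SIZE))
    stop("outline outside canvas: cannot rasterize")
  dense <- catmull_rom_closed(pts, 8L)
  dense[dense < 0] <- 0
  dense[dense > CANVAS_SIZE - 1e-9] <- CANVAS_SIZE - 1e-9
  .fill_polygon_raster(dense[, 1], dense[, 2], canvas$width, 4L,
                       canvas$foreground_intensity,
                       canvas$background_intensity)
}

#' Construct a synthetic training record
#'
#' @param name Identifier string (non-empty, at most 100 characters).
#' @param shape_id Integer shape category in 1..8.
#' @param pixels Integer vector of 9216 grayscale values in 0..255.
#' @param coordinate_x,coordinate_y Numeric vectors of 34 landmark
#'   coordinates in [0, 96).
#' @return A `synthetic_record` object.
#' @export
synthetic_record <- function(name, shape_id, pixels, coordinate_x, coordinate_y) {
  rec <- structure(list(name = as.character(name),
                        shape_id = as.integer(shape_id),
                        pixels = as.integer(pixels),
                        coordinate_x = as.numeric(coordinate_x),
                        coordinate_y = as.numeric(coordinate_y)),
                   class = "synthetic_record")
  bad <- validate_record(rec)
  if (length(bad) > 0)
    stop(sprintf("invalid synthetic record (field `%s`): %s",
                 bad[[1]]$field, bad[[1]]$message))
  rec
}

# Record invariant checks shared by the constructor and the datastore.
validate_record <- function(rec) {
  v <- list()
  add <- function(field, message)
    v[[length(v) + 1L]] <<- list(field = field, message = message)
  if (!is.character(rec$name) || length(rec$name) != 1L ||
      !nzchar(rec$name) || nchar(rec$name) > 100)
    add("name", "must be a non-empty string of at most 100 characters")
  if (is.na(rec$shape_id) || rec$shape_id < 1L || rec$shape_id > 8L)
    add("shape_id", "must be an integer in 1..8")
  if (length(rec$pixels) != 9216L)
    add("pixels", sprintf("expected 9216 pixel values, found %d", length(rec$pixels)))
  else if (anyNA(rec$pixels) || any(rec$pixels < 0L) || any(rec$pixels > 255L))
    add("pixels", "pixel values must lie in 0..255")
  if (length(rec$coordinate_x) != 34L || length(rec$coordinate_y) != 34L)
    add("landmarks", sprintf("expected 34 coordinate pairs, found %d/%d",
                             length(rec$coordinate_x), length(rec$coordinate_y)))
  else if (any(!is.finite(c(rec$coordinate_x, rec$coordinate_y))) ||
           any(c(rec$coordinate_x, rec$coordinate_y) < 0) ||
           any(c(rec$coordinate_x, rec$coordinate_y) >= CANVAS_SIZE))
    add("landmarks", "coordinates must lie in [0, 96)")
  v
}

#' Generate a seeded synthetic training dataset
#'
#' Draws categories round-robin over `categories` (record i gets category
#' `categories[(i - 1) %% k + 1]`, so balanced counts are exact whenever
#' `n_total` is a multiple of the category count).  Each category runs its
#' own morph stream: a seeded exemplar is perturbed into a target shape,
#' `n_frames` interpolated frames are captured, and every frame is randomly
#' rotated/scaled and rasterized; the transformed primitive coordinates are
#' stored as the landmark annotation, so annotations and pixels come from the
#' same outline.  Record names are `"<category>_<batch>_<frame>"`.  Fully
#' deterministic for a fixed seed.
#'
#' @param n_total Number of records to generate (>= 1).
#' @param seed Integer seed.
#' @param categories Integer vector of shape categories to cycle over.
#' @param magnitude Perturbation magnitude for morph targets (pixels).
#' @param n_frames Frames captured per morph (default 24).
#' @param canvas A [canvas_spec()].
#' @return List of `n_total` [synthetic_record()] objects.
#' @export
generate_dataset <- function(n_total, seed = 0L, categories = 1:8,
                             magnitude = 5, n_frames = 24L,
                             canvas = canvas_spec()) {
  stopifnot(n_total >= 1, length(categories) >= 1)
  k <- length(categories)
  counters <- integer(k)
  streams <- vector("list", k)
  records <- vector("list", n_total)
  with_seed(seed, {
    for (i in seq_len(n_total)) {
      ci <- ((i - 1L) %% k) + 1L
      cat_id <- categories[ci]
      counters[ci] <- counters[ci] + 1L
      batch <- (counters[ci] - 1L) %/% n_frames + 1L
      frame <- (counters[ci] - 1L) %% n_frames + 1L
      if (frame == 1L) {
        src_seed <- (as.integer(seed) %% 65536L) * 4096L + cat_id * 512L + batch
        src <- generate_exemplar(cat_id, src_seed)
        tgt <- perturb_exemplar(src, magnitude, src_seed + 262144L)
        streams[[ci]] <- interpolate_shapes(src, tgt, n_frames)
      }
      rec <- tryCatch({
        shape <- random_similarity_transform(streams[[ci]][[frame]],
                                             margin = canvas$margin)
        synthetic_record(sprintf("%d_%d_%d", cat_id, batch, frame),
                         cat_id, rasterize(shape, canvas),
                         shape$points[, 1], shape$points[, 2])
      }, error = function(e)
        stop(sprintf("record %d (%d_%d_%d): %s", i, cat_id, batch, frame,
                     conditionMessage(e)), call. = FALSE))
      records[[i]] <- rec
    }
  })
  records
}

#' Export a record's pixel array as a lossless grayscale PNG
#'
#' @param record A [synthetic_record()] (or bare 9216-vector of pixels).
#' @param path Output PNG path.
#' @export
write_record_png <- function(record, path) {
  px <- if (inherits(record, "synthetic_record")) record$pixels else as.integer(record)
  stopifnot(length(px) == 9216L)
  img <- matrix(px, nrow = 96, ncol = 96, byrow = TRUE) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' Read a 96 x 96 grayscale PNG back to a pixel array
#'
#' @param path PNG path written by [write_record_png()].
#' @return Integer vector of 9216 pixel values.
#' @export
read_record_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  stopifnot(all(dim(img) == c(96L, 96L)))
  as.integer(round(as.vector(t(img)) * 255))
}
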