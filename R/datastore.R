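# Embedded document collection for training records: one JSON document per
# line, UTF-8, with the key layout used throughout the pipeline:
#   {"_id": 1, "name": "...", "shape": 3, "pixels": [...9216 ints...],
#    "landmark": {"coordinate_X": [...34...], "coordinate_Y": [...34...]}}
# "_id" is a monotonically increasing integer assigned on insert.

#' Open (or create) an illustration document store
#'
#' With a `path` the collection is file-backed: existing documents are loaded
#' and every insert is appended to the file immediately, so closing and
#' reopening the store reproduces identical documents in identical order.
#' With `path = NULL` the collection lives in memory only.
#'
#' @param path JSON Lines file path, or NULL for an in-memory collection.
#' @return An `illustration_store` object.
#' @export
ds_open <- function(path = NULL) {
  store <- new.env(parent = emptyenv())
  store$docs <- list()
  store$next_id <- 1L
  store$path <- path
  if (!is.null(path) && file.exists(path)) {
    for (line in readLines(path, warn = FALSE)) {
      if (!nzchar(line)) next
      doc <- jsonlite::fromJSON(line, simplifyVector = TRUE)
      doc$`_id` <- as.integer(doc$`_id`)
      doc$shape <- as.integer(doc$shape)
      doc$pixels <- as.integer(doc$pixels)
      store$docs[[length(store$docs) + 1L]] <- doc
      store$next_id <- max(store$next_id, doc$`_id` + 1L)
    }
  }
  class(store) <- "illustration_store"
  store
}

#' @export
print.illustration_store <- function(x, ...) {
  cat(sprintf("<illustration_store> %d documents (%s)\n", length(x$docs),
              if (is.null(x$path)) "in-memory" else x$path))
  invisible(x)
}

# Exact JSON serialization of one document: doubles are written with %.17g
# so the file round-trips bit-exactly through R's strtod-based parser.
doc_json <- function(doc) {
  int_arr <- function(v) paste0("[", paste(as.integer(v), collapse = ","), "]")
  dbl_arr <- function(v) paste0("[", paste(sprintf("%.17g", v), collapse = ","), "]")
  sprintf(paste0('{"_id":%d,"name":%s,"shape":%d,"pixels":%s,',
                 '"landmark":{"coordinate_X":%s,"coordinate_Y":%s}}'),
          doc$`_id`, jsonlite::toJSON(doc$name, auto_unbox = TRUE),
          doc$shape, int_arr(doc$pixels),
          dbl_arr(doc$landmark$coordinate_X),
          dbl_arr(doc$landmark$coordinate_Y))
}

record_to_doc <- function(record, id) {
  list(`_id` = as.integer(id), name = record$name,
       shape = as.integer(record$shape_id), pixels = record$pixels,
       landmark = list(coordinate_X = record$coordinate_x,
                       coordinate_Y = record$coordinate_y))
}

doc_to_record <- function(doc) {
  synthetic_record(doc$name, doc$shape, doc$pixels,
                   doc$landmark$coordinate_X, doc$landmark$coordinate_Y)
}

#' Insert a training record into a store
#'
#' The record is validated against the synthetic-record invariants before
#' insertion; violations are rejected naming the offending field.  Duplicate
#' names raise a warning but are stored (names are labels, not keys).
#'
#' @param store An [ds_open()] collection.
#' @param record A [synthetic_record()].
#' @return The integer `_id` assigned to the document.
#' @export
ds_insert <- function(store, record) {
  stopifnot(inherits(store, "illustration_store"))
  bad <- validate_record(record)
  if (length(bad) > 0)
    stop(sprintf("record rejected (field `%s`): %s", bad[[1]]$field,
                 bad[[1]]$message))
  if (any(vapply(store$docs, function(d) identical(d$name, record$name), logical(1))))
    warning(sprintf("duplicate record name \"%s\"", record$name))
  id <- store$next_id
  doc <- record_to_doc(record, id)
  store$docs[[length(store$docs) + 1L]] <- doc
  store$next_id <- id + 1L
  if (!is.null(store$path)) {
    cat(doc_json(doc), "\n", sep = "", file = store$path, append = TRUE)
  }
  id
}

#' Number of documents in a store
#' @param store An [ds_open()] collection.
#' @return Integer count.
#' @export
ds_count <- function(store) length(store$docs)

#' Fetch one document by id
#' @param store An [ds_open()] collection.
#' @param id Integer `_id`.
#' @return The document (a list), or NULL when absent.
#' @export
ds_fetch <- function(store, id) {
  for (d in store$docs) if (d$`_id` == id) return(d)
  NULL
}

#' Query documents by shape category
#'
#' @param store An [ds_open()] collection.
#' @param shape_id Integer shape category.
#' @return List of matching documents in insertion order (possibly empty).
#' @export
ds_query_shape <- function(store, shape_id) {
  Filter(function(d) d$shape == shape_id, store$docs)
}

#' Export a store as training matrices
#'
#' Row i of `X` holds document i's 9216 pixel values; row i of `Y` holds its
#' 68 landmark coordinates interleaved as (x1, y1, x2, y2, ...); `names`
#' gives the document names.  Row order is insertion order.
#'
#' @param store A non-empty [ds_open()] collection.
#' @return List with `X` (n x 9216 integer matrix), `Y` (n x 68 numeric
#'   matrix) and `names` (character vector).
#' @export
ds_export_matrices <- function(store) {
  n <- length(store$docs)
  if (n == 0L) stop("cannot export matrices from an empty collection")
  X <- matrix(unlist(lapply(store$docs, `[[`, "pixels"), use.names = FALSE),
              nrow = n, byrow = TRUE)
  Y <- matrix(0, n, 68)
  for (i in seq_len(n)) {
    lm <- store$docs[[i]]$landmark
    Y[i, seq(1, 67, by = 2)] <- lm$coordinate_X
    Y[i, seq(2, 68, by = 2)] <- lm$coordinate_Y
  }
  list(X = X, Y = Y,
       names = vapply(store$docs, `[[`, character(1), "name"))
}
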