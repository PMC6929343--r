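# End-to-end orchestration: fixtures -> augment -> store -> train -> predict
# -> deform -> evaluate, under a single global seed fanned out to
# deterministic per-stage seeds.

# Stage seeds are derived from the global seed so each stage is independently
# reproducible: stage k uses (seed * 131 + k) mod 2^28.
stage_seed <- function(seed, k) (as.integer(seed) %% 2048L) * 131L + k

#' Pipeline configuration
#'
#' @param sizes Training dataset sizes for the dataset-size comparison.
#' @param seed Global seed fanned out to per-stage seeds.
#' @param out_dir Output directory for all artifacts.
#' @param canvas A [canvas_spec()].
#' @param magnitude Perturbation magnitude for morph targets (pixels).
#' @param mlp An [mlp_config()] (its seed is overridden by the global seed).
#' @param thickness,refinement Generic-mesh construction parameters (pixels).
#' @param tolerance_px Landmark-accuracy hit tolerance (pixels).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(sizes = c(1000L, 2500L, 5000L), seed = 1L,
                            out_dir = "anchor3d-out", canvas = canvas_spec(),
                            magnitude = 5, mlp = mlp_config(),
                            thickness = 6, refinement = 2,
                            tolerance_px = 3.0) {
  stopifnot(all(sizes >= 10), tolerance_px > 0)
  structure(list(sizes = sort(as.integer(sizes)), seed = as.integer(seed),
                 out_dir = out_dir, canvas = canvas, magnitude = magnitude,
                 mlp = mlp, thickness = thickness, refinement = refinement,
                 tolerance_px = tolerance_px),
            class = "pipeline_config")
}

pipeline_log <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...)))
}

#' Regularize a predicted landmark polygon
#'
#' Landmark regression is noisy at the scale of the spacing between
#' neighbouring primitives, so a raw predicted 34-gon frequently crosses
#' itself locally.  This step applies gentle circular smoothing along the
#' contour (each point blended 25% towards its neighbour midpoint per pass)
#' until the polygon is simple, keeping displacements minimal.  Used by the
#' pipeline between landmark prediction and mesh deformation; evaluation
#' reports always use the raw predictions.
#'
#' @param landmarks 34 x 2 matrix of predicted landmark positions.
#' @param max_passes Smoothing passes before falling back (or giving up).
#' @param template Optional 34 x 2 simple polygon (the generic outline).
#'   When smoothing alone cannot untangle a severely degraded prediction,
#'   the prediction is blended towards the template by the smallest
#'   sufficient amount; without a template such predictions are an error.
#' @return A 34 x 2 matrix forming a simple polygon.
#' @export
regularize_landmarks <- function(landmarks, max_passes = 20L,
                                 template = NULL) {
  lm <- as.matrix(landmarks)
  for (pass in seq_len(max_passes + 1L)) {
    if (polygon_is_simple(lm)) return(lm)
    prv <- lm[c(34, 1:33), , drop = FALSE]
    nxt <- lm[c(2:34, 1), , drop = FALSE]
    lm <- 0.75 * lm + 0.125 * (prv + nxt)
  }
  if (!is.null(template)) {
    template <- as.matrix(template)
    for (t in seq(0.05, 1, by = 0.05)) {
      cand <- (1 - t) * as.matrix(landmarks) + t * template
      if (polygon_is_simple(cand)) return(cand)
    }
  }
  stop("landmark polygon could not be regularized to a simple polygon")
}

#' Write the eight category exemplar fixtures
#'
#' One outline CSV and one rasterized PNG preview per shape category.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the list of 8 exemplar outlines.
#' @export
run_fixtures <- function(config = pipeline_config()) {
  dir.create(file.path(config$out_dir, "fixtures"), recursive = TRUE,
             showWarnings = FALSE)
  fs <- stage_seed(config$seed, 1L)
  exemplars <- lapply(1:8, function(k) generate_exemplar(k, fs))
  for (k in 1:8) {
    write_outline_csv(exemplars[[k]],
                      file.path(config$out_dir, "fixtures",
                                sprintf("outline_cat%d.csv", k)))
    write_record_png(rasterize(exemplars[[k]], config$canvas),
                     file.path(config$out_dir, "fixtures",
                               sprintf("preview_cat%d.png", k)))
  }
  invisible(exemplars)
}

#' Run the complete automated 3D modelling pipeline
#'
#' Executes every stage in order: exemplar fixtures; one synthetic dataset
#' per configured size (stored to a JSON Lines datastore for the largest
#' size); one MLP training per size with test landmark accuracy (the
#' dataset-size comparison table); landmark prediction on the eight category
#' exemplars with the largest-size model; mean-value-coordinate deformation
#' of the generic mesh into the eight target meshes (exported as OBJ);
#' per-category control-vs-predicted evaluation reports and box plots; a
#' summary table and a run manifest with checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the trained models, accuracy table,
#'   per-category reports, mesh paths and the manifest.
#' @export
run_all <- function(config = pipeline_config()) {
  out <- config$out_dir
  for (sub in c("fixtures", "predicted", "meshes", "eval"))
    dir.create(file.path(out, sub), recursive = TRUE, showWarnings = FALSE)

  pipeline_log("stage fixtures: 8 category exemplars")
  exemplars <- run_fixtures(config)

  models <- list(); logs <- list()
  acc <- data.frame(size = integer(0), train_accuracy = numeric(0),
                    validation_accuracy = numeric(0), test_accuracy = numeric(0))
  largest <- max(config$sizes)
  for (i in seq_along(config$sizes)) {
    n <- config$sizes[i]
    pipeline_log("stage augment: generating %d records", n)
    records <- generate_dataset(n, seed = stage_seed(config$seed, 10L + i),
                                magnitude = config$magnitude,
                                canvas = config$canvas)
    store <- ds_open(if (n == largest) file.path(out, "datastore.jsonl") else NULL)
    for (r in records) ds_insert(store, r)
    mats <- ds_export_matrices(store)
    split <- split_dataset(n, seed = stage_seed(config$seed, 20L + i))
    cfg <- config$mlp
    cfg$seed <- stage_seed(config$seed, 30L + i)
    pipeline_log("stage train: n=%d (%d/%d/%d), %d epochs", n,
                 length(split$train), length(split$validation),
                 length(split$test), cfg$epochs)
    fit <- mlp_train(init_model(cfg), normalize_inputs(mats$X),
                     normalize_targets(mats$Y), split, cfg)
    models[[as.character(n)]] <- fit$model
    logs[[as.character(n)]] <- fit$log
    write_training_log(fit$log, file.path(out, sprintf("training_log_%d.csv", n)))
    acc <- rbind(acc, data.frame(
      size = n,
      train_accuracy = landmark_accuracy(fit$model, records[split$train],
                                         config$tolerance_px),
      validation_accuracy = landmark_accuracy(fit$model, records[split$validation],
                                              config$tolerance_px),
      test_accuracy = landmark_accuracy(fit$model, records[split$test],
                                        config$tolerance_px)))
    pipeline_log("  test landmark accuracy (<= %g px): %.1f%%",
                 config$tolerance_px, 100 * acc$test_accuracy[nrow(acc)])
  }
  model <- models[[as.character(largest)]]
  write_model(model, file.path(out, "model.json"))

  pipeline_log("stage predict + deform: 8 target meshes")
  generic <- exemplars[[1]]
  mesh <- build_generic_mesh(generic, thickness = config$thickness,
                             refinement = config$refinement)
  binding <- bind_mesh(mesh)
  reports <- list(); mesh_paths <- character(0); rmse <- numeric(8)
  for (k in 1:8) {
    pixels <- rasterize(exemplars[[k]], config$canvas)
    landmarks <- predict_landmarks(model, pixels)
    write_control_points(landmarks,
                         file.path(out, "predicted",
                                   sprintf("landmarks_cat%d.csv", k)))
    deformed <- deform_mesh(mesh, binding,
                            regularize_landmarks(landmarks,
                                                 template = generic$points))
    viol <- validate_mesh(deformed)
    viol <- Filter(function(v) v$invariant != "boundary-map", viol)
    if (length(viol) > 0)
      stop(sprintf("stage deform: mesh for category %d violates %s",
                   k, viol[[1]]$invariant))
    p <- file.path(out, "meshes", sprintf("anchor_cat%d.obj", k))
    export_mesh(deformed, p, "obj")
    mesh_paths <- c(mesh_paths, p)
    report <- compare_point_sets(exemplars[[k]]$points, landmarks)
    reports[[k]] <- report
    rmse[k] <- report$rmse
    write_comparison(report, file.path(out, "eval", sprintf("report_cat%d.csv", k)))
    write_comparison(report, file.path(out, "eval", sprintf("report_cat%d.json", k)))
    render_boxplots(report, file.path(out, "eval", sprintf("boxplots_cat%d.svg", k)))
  }

  summary_tab <- acc
  summary_tab[, -1] <- round(100 * summary_tab[, -1], 2)
  utils::write.csv(summary_tab, file.path(out, "summary.csv"), row.names = FALSE)
  utils::write.csv(data.frame(category = 1:8, rmse = rmse),
                   file.path(out, "rmse_by_category.csv"), row.names = FALSE)

  artifacts <- list.files(out, recursive = TRUE, full.names = TRUE)
  artifacts <- setdiff(artifacts, file.path(out, "manifest.json"))
  manifest <- list(seed = config$seed,
                   config = list(sizes = config$sizes,
                                 magnitude = config$magnitude,
                                 epochs = config$mlp$epochs,
                                 batch_size = config$mlp$batch_size,
                                 learning_rate = config$mlp$learning_rate,
                                 momentum = config$mlp$momentum,
                                 nesterov = config$mlp$nesterov,
                                 thickness = config$thickness,
                                 refinement = config$refinement,
                                 tolerance_px = config$tolerance_px),
                   checksums = as.list(tools::md5sum(sort(artifacts))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(out, "manifest.json"))
  pipeline_log("run complete: %d meshes, summary at %s",
               length(mesh_paths), file.path(out, "summary.csv"))
  invisible(list(models = models, logs = logs, accuracy = acc,
                 reports = reports, mesh_paths = mesh_paths,
                 manifest = manifest, exemplars = exemplars))
}
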