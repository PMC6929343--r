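# Multilayer-perceptron landmark regressor: 9216 normalized pixels in, 68
# normalized coordinates out, two ReLU hidden layers (512, 128), identity
# output, trained by mini-batch SGD with Nesterov momentum on mean squared
# error.  The heavy training loop runs in compiled single-precision code;
# forward/backprop are also implemented here in double precision as the
# reference path used for prediction and gradient checking.

#' MLP configuration
#'
#' Defaults follow the pipeline's training protocol: 200 epochs of
#' mini-batch SGD (batch 20) at learning rate 0.01 with Nesterov momentum
#' 0.9, zero decay, MSE loss, fixed architecture 9216-512-128-68.
#'
#' @param epochs Training epochs (>= 1; 0 allowed to mean "no training").
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate SGD learning rate (> 0).
#' @param momentum Momentum coefficient in [0, 1).
#' @param nesterov Use the Nesterov momentum update.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return An `mlp_config` object.
#' @export
mlp_config <- function(epochs = 200L, batch_size = 20L, learning_rate = 0.01,
                       momentum = 0.9, nesterov = TRUE, seed = 0L) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0,
            momentum >= 0, momentum < 1)
  structure(list(layer_sizes = c(9216L, 512L, 128L, 68L),
                 hidden_activation = "relu", output_activation = "identity",
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 decay = 0, nesterov = isTRUE(nesterov), loss = "mse",
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Split record indices into train / validation / test sets
#'
#' A uniformly random permutation under `seed` is partitioned so the test set
#' holds round(0.20 n) indices and the validation set round(0.30 (n - |test|))
#' of the remaining training pool; the rest train.  For n = 5000 this gives
#' 2800 / 1200 / 1000.
#'
#' @param n Number of records (>= 10).
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(n, seed = 0L) {
  if (n < 10) stop("need at least 10 records to form all three parts")
  n_test <- round(0.20 * n)
  n_val <- round(0.30 * (n - n_test))
  n_train <- n - n_test - n_val
  if (n_test < 1 || n_val < 1 || n_train < 1)
    stop("dataset too small: one of the split parts would be empty")
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Normalize pixel intensities to [0, 1]
#' @param pixels Numeric/integer values in 0..255 (vector or matrix).
#' @return Values divided by 255.
#' @export
normalize_inputs <- function(pixels) {
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    stop("pixel values out of range 0..255")
  pixels / 255
}

#' Normalize landmark coordinates to [0, 1)
#' @param coords Coordinates in [0, 96) (vector or matrix).
#' @return Values divided by 96.
#' @export
normalize_targets <- function(coords) {
  if (anyNA(coords) || any(coords < 0) || any(coords >= CANVAS_SIZE))
    stop("coordinates out of range [0, 96)")
  coords / CANVAS_SIZE
}

#' Invert [normalize_targets()]
#' @param coords Normalized coordinates.
#' @return Pixel-scale coordinates (times 96).
#' @export
denormalize_targets <- function(coords) coords * CANVAS_SIZE

#' Initialize an MLP model
#'
#' Weights are drawn i.i.d. N(0, 1/fan_in) per layer under `config$seed`
#' (standard deviation 1/sqrt(fan_in)); biases start at zero.
#'
#' @param config An [mlp_config()].
#' @return An `mlp_model` with weight matrices `W1,W2,W3`, bias vectors
#'   `b1,b2,b3` and the config.
#' @export
init_model <- function(config = mlp_config()) {
  ls <- config$layer_sizes
  params <- with_seed(config$seed, {
    draw <- function(fin, fout) matrix(stats::rnorm(fin * fout, sd = 1 / sqrt(fin)), fin, fout)
    list(W1 = draw(ls[1], ls[2]), b1 = numeric(ls[2]),
         W2 = draw(ls[2], ls[3]), b2 = numeric(ls[3]),
         W3 = draw(ls[3], ls[4]), b3 = numeric(ls[4]))
  })
  structure(c(params, list(config = config)), class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s, %d parameters\n",
              paste(x$config$layer_sizes, collapse = "-"),
              sum(vapply(x[c("W1", "b1", "W2", "b2", "W3", "b3")], length, 0))))
  invisible(x)
}

#' Forward pass (double precision)
#'
#' h1 = relu(X W1 + b1), h2 = relu(h1 W2 + b2), out = h2 W3 + b3.
#'
#' @param model An `mlp_model`.
#' @param inputs n x n_in matrix of normalized inputs (a single vector is
#'   treated as one row).
#' @return n x n_out output matrix.
#' @export
mlp_forward <- function(model, inputs) {
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1)
  if (ncol(inputs) != nrow(model$W1))
    stop(sprintf("input has %d columns, model expects %d",
                 ncol(inputs), nrow(model$W1)))
  h1 <- pmax(sweep(inputs %*% model$W1, 2, model$b1, "+"), 0)
  h2 <- pmax(sweep(h1 %*% model$W2, 2, model$b2, "+"), 0)
  sweep(h2 %*% model$W3, 2, model$b3, "+")
}

# Analytic gradients of the MSE loss, double precision; reference path for
# the compiled trainer and target of the finite-difference check.
mlp_gradients <- function(model, X, Y) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  a1 <- sweep(X %*% model$W1, 2, model$b1, "+"); h1 <- pmax(a1, 0)
  a2 <- sweep(h1 %*% model$W2, 2, model$b2, "+"); h2 <- pmax(a2, 0)
  out <- sweep(h2 %*% model$W3, 2, model$b3, "+")
  d <- out - Y
  loss <- mean(d^2)
  dout <- 2 * d / length(d)
  gW3 <- crossprod(h2, dout); gb3 <- colSums(dout)
  dh2 <- (dout %*% t(model$W3)) * (a2 > 0)
  gW2 <- crossprod(h1, dh2); gb2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(model$W2)) * (a1 > 0)
  gW1 <- crossprod(X, dh1); gb1 <- colSums(dh1)
  list(loss = loss, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Train an MLP by mini-batch SGD with Nesterov momentum
#'
#' Velocity update v <- mu v - eta g; with Nesterov the parameters move by
#' mu v - eta g (using the updated velocity), otherwise by v.  Batch order is
#' reshuffled every epoch under the config seed.  No early stopping, no
#' learning-rate decay.  Training arithmetic is single precision.
#'
#' @param model An [init_model()] MLP.
#' @param X n x 9216 matrix of normalized pixels.
#' @param Y n x 68 matrix of normalized target coordinates.
#' @param split A [split_dataset()] partition of the n rows.
#' @param config An [mlp_config()]; defaults to the model's own.
#' @return List with the trained `model` and a `log` data frame holding one
#'   row per epoch (`epoch`, `train_mse`, `val_mse`).
#' @export
mlp_train <- function(model, X, Y, split, config = model$config) {
  stopifnot(inherits(model, "mlp_model"), nrow(X) == nrow(Y))
  if (config$epochs == 0L)
    return(list(model = model,
                log = data.frame(epoch = integer(0), train_mse = numeric(0),
                                 val_mse = numeric(0))))
  res <- .mlp_train_sgd(model[c("W1", "b1", "W2", "b2", "W3", "b3")],
                        X, Y, as.integer(split$train),
                        as.integer(split$validation),
                        config$epochs, config$batch_size,
                        config$learning_rate, config$momentum,
                        config$nesterov, config$seed + 1L)
  trained <- model
  for (nm in c("W1", "W2", "W3")) trained[[nm]] <- res[[nm]]
  for (nm in c("b1", "b2", "b3")) trained[[nm]] <- as.numeric(res[[nm]])
  trained$config <- config
  list(model = trained,
       log = data.frame(epoch = seq_len(config$epochs),
                        train_mse = res$train_loss, val_mse = res$val_loss))
}

#' Predict the 34 landmark positions on one illustration
#'
#' Normalizes the pixels, runs the forward pass, denormalizes and
#' de-interleaves the 68 outputs into 34 (x, y) pairs in pixel coordinates.
#'
#' @param model A trained `mlp_model`.
#' @param pixels Integer vector of 9216 grayscale values.
#' @return 34 x 2 matrix of landmark coordinates.
#' @export
predict_landmarks <- function(model, pixels) {
  stopifnot(length(pixels) == 9216L)
  out <- denormalize_targets(mlp_forward(model, normalize_inputs(as.numeric(pixels))))
  if (any(!is.finite(out))) stop("non-finite landmark prediction")
  cbind(out[1, seq(1, 67, by = 2)], out[1, seq(2, 68, by = 2)])
}

# Bulk prediction: n x 9216 pixel matrix -> n x 68 pixel-scale coordinates.
predict_landmarks_matrix <- function(model, pixel_matrix) {
  denormalize_targets(.mlp_forward_f32(
    model[c("W1", "b1", "W2", "b2", "W3", "b3")],
    normalize_inputs(pixel_matrix)))
}

#' Landmark hit-rate accuracy of a model over records
#'
#' Fraction of all (record, landmark) pairs whose predicted position lies
#' within `tolerance_px` (Euclidean, pixels) of the annotated position.
#'
#' @param model A trained `mlp_model`.
#' @param records Non-empty list of [synthetic_record()] objects (or store
#'   documents).
#' @param tolerance_px Hit tolerance in pixels (> 0), default 3.
#' @return Fraction in [0, 1].
#' @export
landmark_accuracy <- function(model, records, tolerance_px = 3.0) {
  stopifnot(tolerance_px > 0)
  if (length(records) == 0L) stop("no records to evaluate")
  X <- matrix(unlist(lapply(records, function(r) {
    if (!is.null(r$pixels)) r$pixels else stop("record without pixels")
  }), use.names = FALSE), nrow = length(records), byrow = TRUE)
  pred <- predict_landmarks_matrix(model, X)
  hits <- 0L
  for (i in seq_along(records)) {
    r <- records[[i]]
    cx <- if (!is.null(r$coordinate_x)) r$coordinate_x else r$landmark$coordinate_X
    cy <- if (!is.null(r$coordinate_y)) r$coordinate_y else r$landmark$coordinate_Y
    d <- sqrt((pred[i, seq(1, 67, by = 2)] - cx)^2 +
                (pred[i, seq(2, 68, by = 2)] - cy)^2)
    hits <- hits + sum(d <= tolerance_px)
  }
  hits / (length(records) * 34)
}

#' Serialize a model to a self-describing JSON container
#'
#' @param model An `mlp_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  payload <- list(format = "anchor3d-mlp", version = 1L,
                  config = unclass(model$config),
                  shapes = lapply(model[c("W1", "b1", "W2", "b2", "W3", "b3")],
                                  function(p) if (is.matrix(p)) dim(p) else length(p)),
                  params = lapply(model[c("W1", "b1", "W2", "b2", "W3", "b3")],
                                  as.numeric))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Load a model written by [write_model()]
#' @param path Model file path.
#' @return An `mlp_model`.
#' @export
read_model <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE)
  if (!identical(payload$format, "anchor3d-mlp"))
    stop("not an anchor3d MLP model file")
  cfg <- do.call(mlp_config, payload$config[c("epochs", "batch_size",
                                              "learning_rate", "momentum",
                                              "nesterov", "seed")])
  m <- list()
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    sh <- payload$shapes[[nm]]
    m[[nm]] <- if (length(sh) == 2) matrix(payload$params[[nm]], sh[1], sh[2])
               else as.numeric(payload$params[[nm]])
  }
  structure(c(m, list(config = cfg)), class = "mlp_model")
}

#' Export a training log as CSV (epoch, train_mse, val_mse)
#' @param log Data frame from [mlp_train()].
#' @param path Output CSV path.
#' @export
write_training_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
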