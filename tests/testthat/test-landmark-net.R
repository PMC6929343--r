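# MLP landmark regressor: splits, normalization, initialization, forward,
# gradients, training updates and the accuracy metric.

test_that("dataset splits follow the 80/20 and 30% rules", {
  sp <- split_dataset(5000, 1)
  expect_length(sp$test, 1000)
  expect_length(sp$validation, 1200)
  expect_length(sp$train, 2800)
  expect_identical(split_dataset(5000, 1), sp)
  sp2 <- split_dataset(137, 3)
  all_idx <- sort(c(sp2$train, sp2$validation, sp2$test))
  expect_identical(all_idx, seq_len(137))
  expect_length(intersect(sp2$train, sp2$test), 0)
  expect_length(intersect(sp2$train, sp2$validation), 0)
  expect_error(split_dataset(5, 1), "at least 10")
})

test_that("normalization maps and inverts exactly", {
  expect_equal(normalize_inputs(c(0, 255, 51)), c(0, 1, 0.2))
  expect_error(normalize_inputs(c(-1, 0)), "out of range")
  expect_equal(normalize_targets(48), 0.5)
  expect_equal(normalize_targets(0), 0)
  set.seed(5)
  v <- runif(200, 0, 95.999)
  expect_equal(denormalize_targets(normalize_targets(v)), v, tolerance = 1e-12)
  expect_error(normalize_targets(96), "out of range")
})

test_that("initialization is seeded, zero-biased and fan-in scaled", {
  m1 <- init_model(mlp_config(seed = 7))
  m2 <- init_model(mlp_config(seed = 7))
  expect_identical(m1$W1, m2$W1)
  expect_false(identical(m1$W1, init_model(mlp_config(seed = 8))$W1))
  expect_true(all(m1$b1 == 0) && all(m1$b2 == 0) && all(m1$b3 == 0))
  expect_equal(sd(m1$W1), 1 / sqrt(9216), tolerance = 0.1)
  expect_equal(sd(m1$W2), 1 / sqrt(512), tolerance = 0.1)
  expect_equal(sd(m1$W3), 1 / sqrt(128), tolerance = 0.1)
})

test_that("forward pass matches a hand-computed toy network", {
  m <- structure(list(W1 = rbind(c(1, -1), c(0.5, 2)), b1 = c(0.5, -1),
                      W2 = rbind(c(1, 0), c(-1, 1)), b2 = c(0, 0.5),
                      W3 = matrix(c(2, -1), 2, 1), b3 = 0.5,
                      config = mlp_config()), class = "mlp_model")
  # by hand: h1 = relu((2, 3) + (0.5, -1)) = (2.5, 2)
  #          h2 = relu((0.5, 2) + (0, 0.5)) = (0.5, 2.5)
  #          out = 0.5*2 + 2.5*(-1) + 0.5 = -1
  expect_equal(as.numeric(mlp_forward(m, c(1, 2))), -1)
  zero <- m
  for (nm in c("W1", "W2", "W3")) zero[[nm]] <- zero[[nm]] * 0
  for (nm in c("b1", "b2", "b3")) zero[[nm]] <- zero[[nm]] * 0
  expect_equal(as.numeric(mlp_forward(zero, c(3, -4))), 0)
  X <- matrix(runif(10), 5, 2)
  expect_equal(nrow(mlp_forward(m, X)), 5)
  expect_error(mlp_forward(m, matrix(1, 2, 3)), "columns")
})

test_that("analytic gradients match central finite differences", {
  sizes <- c(10, 5, 3, 2)
  m <- make_toy_model(sizes, seed = 4)
  set.seed(9)
  X <- matrix(runif(6 * 10), 6, 10)
  Y <- matrix(runif(6 * 2), 6, 2)
  g <- anchor3d:::mlp_gradients(m, X, Y)
  eps <- 1e-6
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    theta <- m[[nm]]
    probe <- if (length(theta) > 12) sample(length(theta), 12) else seq_along(theta)
    for (j in probe) {
      mp <- m; mp[[nm]][j] <- theta[j] + eps
      mm <- m; mm[[nm]][j] <- theta[j] - eps
      fd <- (toy_loss(mp, X, Y) - toy_loss(mm, X, Y)) / (2 * eps)
      expect_lt(abs(fd - g[[nm]][j]) / max(abs(fd), abs(g[[nm]][j]), 1e-8), 1e-5)
    }
  }
})

test_that("the compiled trainer reproduces the reference Nesterov update", {
  set.seed(3)
  n <- 20
  X <- matrix(runif(n * 9216), n)
  Y <- matrix(runif(n * 68), n)
  cfg <- mlp_config(epochs = 1, batch_size = 20, seed = 5)
  m <- init_model(cfg)
  split <- list(train = 1:20, validation = integer(0), test = integer(0))
  fit <- mlp_train(m, X, Y, split, cfg)
  # one epoch = one full batch; with v0 = 0: v = -lr g, theta += mu v - lr g
  g <- anchor3d:::mlp_gradients(m, X, Y)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    expected <- m[[nm]] + cfg$momentum * (-cfg$learning_rate * g[[nm]]) -
      cfg$learning_rate * g[[nm]]
    expect_equal(fit$model[[nm]], expected, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
  expect_equal(fit$log$train_mse[1], g$loss, tolerance = 1e-5)
})

test_that("zero epochs leave the model untouched with an empty log", {
  cfg <- mlp_config(epochs = 0, seed = 2)
  m <- init_model(cfg)
  X <- matrix(runif(10 * 9216), 10)
  Y <- matrix(runif(10 * 68), 10)
  fit <- mlp_train(m, X, Y, split_dataset(10, 1), cfg)
  expect_identical(fit$model$W1, m$W1)
  expect_equal(nrow(fit$log), 0)
})

test_that("a 5-record training set is memorized (overfit capacity)", {
  recs <- small_records()[seq(1, 80, by = 16)]  # 5 records
  X <- normalize_inputs(matrix(unlist(lapply(recs, `[[`, "pixels")), 5,
                               byrow = TRUE))
  Y <- matrix(0, 5, 68)
  for (i in 1:5) {
    Y[i, seq(1, 67, by = 2)] <- recs[[i]]$coordinate_x
    Y[i, seq(2, 68, by = 2)] <- recs[[i]]$coordinate_y
  }
  cfg <- mlp_config(epochs = 6000, seed = 6)
  split <- list(train = 1:5, validation = integer(0), test = integer(0))
  fit <- mlp_train(init_model(cfg), X, normalize_targets(Y), split, cfg)
  expect_lt(tail(fit$log$train_mse, 1), 1e-3)
  # memorized records are predicted to within a pixel
  for (i in 1:5) {
    pred <- predict_landmarks(fit$model, recs[[i]]$pixels)
    err <- sqrt((pred[, 1] - recs[[i]]$coordinate_x)^2 +
                  (pred[, 2] - recs[[i]]$coordinate_y)^2)
    expect_lt(max(err), 1)
  }
  expect_equal(landmark_accuracy(fit$model, recs), 1.0)
})

test_that("training is deterministic and loosely monotone", {
  recs <- cached("records_500", generate_dataset(500, seed = 21))
  X <- normalize_inputs(matrix(unlist(lapply(recs, `[[`, "pixels")), 500,
                               byrow = TRUE))
  Y <- matrix(0, 500, 68)
  for (i in 1:500) {
    Y[i, seq(1, 67, by = 2)] <- recs[[i]]$coordinate_x
    Y[i, seq(2, 68, by = 2)] <- recs[[i]]$coordinate_y
  }
  Y <- normalize_targets(Y)
  sp <- split_dataset(500, 8)
  cfg <- mlp_config(epochs = 20, seed = 9)
  f1 <- mlp_train(init_model(cfg), X, Y, sp, cfg)
  f2 <- mlp_train(init_model(cfg), X, Y, sp, cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$W3, f2$model$W3)
  expect_lt(median(tail(f1$log$train_mse, 10)),
            median(head(f1$log$train_mse, 10)))
  expect_true(all(is.finite(f1$log$val_mse)))
})

test_that("landmark accuracy counts within-tolerance hits", {
  recs <- small_records()[1:3]
  m <- init_model(mlp_config(seed = 1))
  # metric arithmetic on hand-built displacements: 17 exact hits out of 34
  offsets <- rbind(matrix(0, 17, 2), matrix(10, 17, 2))
  d <- sqrt(rowSums(offsets^2))
  expect_equal(mean(d <= 3), 0.5)
  expect_error(landmark_accuracy(m, list()), "no records")
  acc <- landmark_accuracy(m, recs, tolerance_px = 3)
  expect_gte(acc, 0); expect_lte(acc, 1)
})

test_that("models serialize and reload exactly", {
  m <- init_model(mlp_config(seed = 12))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3"))
    expect_equal(back[[nm]], m[[nm]], ignore_attr = TRUE)
  log <- data.frame(epoch = 1:3, train_mse = c(3, 2, 1) / 10,
                    val_mse = c(4, 3, 2) / 10)
  lp <- withr::local_tempfile(fileext = ".csv")
  write_training_log(log, lp)
  expect_equal(utils::read.csv(lp), log)
})
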