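# Shape interpolation, similarity transforms, rasterization and dataset
# generation.

test_that("interpolation follows t_i = i/(n+1) index-wise", {
  src <- exemplar(3)
  tgt <- perturb_exemplar(src, 5, 2)
  frames <- interpolate_shapes(src, tgt)
  expect_length(frames, 24)
  for (i in c(1, 5, 24)) {
    t <- i / 25
    expect_equal(frames[[i]]$points, (1 - t) * src$points + t * tgt$points)
  }
  # frame 5 of 24 has t = 0.2: a (0,0) -> (25,50) point lands at (5,10)
  expect_equal((1 - 5 / 25) * c(0, 0) + 5 / 25 * c(25, 50), c(5, 10))
  same <- interpolate_shapes(src, src)
  for (f in same) expect_equal(f$points, src$points)
  other <- exemplar(4)
  expect_error(interpolate_shapes(src, other), "different shape categories")
})

test_that("interpolated frame positions are collinear between endpoints", {
  src <- exemplar(6)
  tgt <- perturb_exemplar(src, 5, 9)
  frames <- interpolate_shapes(src, tgt)
  dirv <- tgt$points - src$points
  for (i in seq_along(frames)) {
    d <- frames[[i]]$points - src$points
    # cross product of each displacement with the chord must vanish
    resid <- abs(d[, 1] * dirv[, 2] - d[, 2] * dirv[, 1])
    expect_lt(max(resid), 1e-9)
  }
})

test_that("similarity transform: identity, containment, area scaling", {
  o <- exemplar(1)
  id <- random_similarity_transform(o, angle = 0, scale = 1)
  expect_equal(id$points, o$points)
  forced <- random_similarity_transform(o, angle = 77, scale = 0.8)
  r <- anchor3d:::polygon_area(forced$points) / anchor3d:::polygon_area(o$points)
  expect_equal(r, 0.8^2, tolerance = 1e-9)
  set.seed(42)
  for (i in 1:20) {
    tr <- random_similarity_transform(o, margin = 2)
    expect_true(all(tr$points >= 2 & tr$points < 94))
    expect_length(validate_outline(tr), 0)
  }
})

test_that("rasterization obeys the pixel contract", {
  o <- exemplar(2)
  px <- rasterize(o)
  expect_length(px, 9216)
  expect_true(all(px >= 0 & px <= 255))
  expect_identical(px, rasterize(o))  # deterministic

  # degenerate zero-area outline (bypassing validation) leaves the canvas white
  degenerate <- matrix(rep(c(48, 48), each = 34), 34, 2)
  expect_true(all(rasterize(degenerate) == 255))

  # a centred square of side 48 covers 25% of the canvas (spline + antialias
  # edge effects allowed 2%)
  sq <- square_outline(48)
  frac <- mean(rasterize(sq) < 128)
  expect_equal(frac, 0.25, tolerance = 0.02)

  outside <- exemplar(2)$points
  outside[1, 1] <- -1
  expect_error(rasterize(outside), "outside canvas")
})

test_that("record PNG export is lossless", {
  rec <- small_records()[[1]]
  path <- withr::local_tempfile(fileext = ".png")
  write_record_png(rec, path)
  expect_identical(read_record_png(path), rec$pixels)
})

test_that("dataset generation is balanced, deterministic and annotated
           consistently", {
  recs <- small_records()  # 80 records over 8 categories
  expect_length(recs, 80)
  counts <- table(vapply(recs, `[[`, 1L, "shape_id"))
  expect_true(all(counts == 10))
  expect_identical(vapply(recs, `[[`, "", "name")[1:9],
                   c("1_1_1", "2_1_1", "3_1_1", "4_1_1", "5_1_1", "6_1_1",
                     "7_1_1", "8_1_1", "1_1_2"))
  again <- generate_dataset(80, seed = 11)
  expect_identical(recs, again)
  other <- generate_dataset(16, seed = 12)
  expect_false(identical(recs[1:16], other))
  # annotation consistency: stored coordinates re-rasterize to stored pixels
  for (rec in recs[seq(1, 80, by = 13)]) {
    o <- outline2d(cbind(rec$coordinate_x, rec$coordinate_y), rec$shape_id)
    expect_identical(rasterize(o), rec$pixels)
  }
})

test_that("record invariants are enforced", {
  rec <- small_records()[[1]]
  expect_error(synthetic_record(rec$name, rec$shape_id, rec$pixels[-1],
                                rec$coordinate_x, rec$coordinate_y),
               "pixels")
  expect_error(synthetic_record("", rec$shape_id, rec$pixels,
                                rec$coordinate_x, rec$coordinate_y),
               "name")
  expect_error(synthetic_record(rec$name, 9, rec$pixels,
                                rec$coordinate_x, rec$coordinate_y),
               "shape_id")
})
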