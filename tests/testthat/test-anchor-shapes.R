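# Parametric outline generation, perturbation and validation.

test_that("exemplar generation is deterministic and canvas-bounded", {
  a <- generate_exemplar(3, 7)
  b <- generate_exemplar(3, 7)
  expect_identical(a, b)
  o <- generate_exemplar(1, 0)
  expect_equal(nrow(o$points), 34)
  expect_true(all(o$points >= 0 & o$points < 96))
  expect_false(identical(generate_exemplar(3, 7), generate_exemplar(3, 8)))
})

test_that("every category preset yields a valid outline with its features", {
  for (k in 1:8) {
    o <- generate_exemplar(k, 0)
    expect_length(validate_outline(o), 0)
    expect_identical(o$category, k)
  }
  p5 <- shape_category_params(5); p7 <- shape_category_params(7)
  p8 <- shape_category_params(8)
  expect_gt(p5$extrusion_size, 0)
  expect_gt(p7$extrusion_size, 0)
  expect_gt(p8$hook_size, 0)
  expect_error(shape_category_params(9), "unknown shape category")
  expect_error(generate_exemplar(0, 1), "unknown shape category")
})

test_that("all categories validate across many seeds", {
  for (k in 1:8) {
    for (s in 0:99) {
      o <- generate_exemplar(k, s)
      expect_length(validate_outline(o), 0)
    }
  }
})

test_that("perturbation respects the displacement bound and stays valid", {
  o <- exemplar(2)
  expect_identical(perturb_exemplar(o, 0, 1), o)
  for (s in 1:100) {
    p <- perturb_exemplar(o, 3, s)
    disp <- sqrt(rowSums((p$points - o$points)^2))
    expect_lte(max(disp), 3 + 1e-12)
    expect_length(validate_outline(p), 0)
  }
  expect_false(identical(perturb_exemplar(o, 3, 1), perturb_exemplar(o, 3, 2)))
})

test_that("validate_outline reports named violations", {
  o <- exemplar(1)
  short <- o
  short$points <- o$points[1:33, ]
  v <- validate_outline(short)
  expect_length(v, 1)
  expect_identical(v[[1]]$invariant, "point-count")

  # bow-tie: two crossing edges, confirmed by the brute-force O(n^2) oracle
  crossed <- o
  crossed$points[c(15, 16), ] <- crossed$points[c(16, 15), ]
  pairs <- anchor3d:::polygon_self_intersections(crossed$points)
  expect_gt(nrow(pairs), 0)
  v <- validate_outline(crossed)
  expect_true(any(vapply(v, function(x) x$invariant == "self-intersection",
                         logical(1))))

  outside <- o
  outside$points[4, 1] <- 120
  v <- validate_outline(outside)
  idx <- vapply(v, `[[`, 0L, "index")
  expect_true(any(vapply(v, `[[`, "", "invariant") == "out-of-canvas" & idx == 4))
})

test_that("outline CSV round-trips through the 6-decimal writer", {
  o <- exemplar(4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_outline_csv(o, path)
  lines <- readLines(path)
  expect_identical(lines[1], "x,y")
  expect_length(lines, 35)
  back <- read_outline_csv(path, category = 4)
  expect_equal(back$points, o$points, tolerance = 1e-6)
  # headerless files are accepted too
  writeLines(lines[-1], path)
  expect_equal(read_outline_csv(path, 4)$points, back$points)
})
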