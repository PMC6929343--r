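# Generic mesh construction, mean value coordinates, deformation and export.

mesh1 <- function() cached("mesh1", build_generic_mesh(exemplar(1)))
binding1 <- function() cached("binding1", bind_mesh(mesh1()))

test_that("the generic mesh satisfies all invariants for every category", {
  for (k in 1:8) {
    mesh <- build_generic_mesh(exemplar(k))
    expect_length(validate_mesh(mesh), 0)
    expect_true(all(mesh$vertices[mesh$boundary_map, 3] == 0))
    expect_lte(max(abs(mesh$vertices[, 3])), 6 + 1e-9)
    expect_equal(mesh$vertices[mesh$boundary_map, 1:2],
                 exemplar(k)$points, ignore_attr = TRUE)
  }
})

test_that("mean value coordinates: symmetry, boundary rules, linear
           precision", {
  sq <- rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0))
  expect_equal(mean_value_weights(c(5, 5), sq), rep(0.25, 4))
  w <- mean_value_weights(c(0, 5), sq)  # midpoint of edge 1-2
  expect_equal(w, c(0.5, 0.5, 0, 0))
  expect_equal(mean_value_weights(c(10, 10), sq), c(0, 0, 1, 0))
  expect_error(mean_value_weights(c(20, 5), sq), "outside")

  poly <- exemplar(5)$points
  set.seed(31)
  n_checked <- 0
  while (n_checked < 100) {
    p <- runif(2, 0, 96)
    if (!anchor3d:::point_in_polygon(p[1], p[2], poly)) next
    n_checked <- n_checked + 1
    w <- mean_value_weights(p, poly)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_lt(sqrt(sum((colSums(w * poly) - p)^2)), 1e-9)
  }
})

test_that("binding has partition of unity, indicators and linear precision", {
  mesh <- mesh1()
  B <- unclass(binding1())
  expect_equal(dim(B), c(nrow(mesh$vertices), 34))
  expect_lt(max(abs(rowSums(B) - 1)), 1e-9)
  expect_equal(B[mesh$boundary_map, ], diag(34), ignore_attr = TRUE)
  rec <- B %*% mesh$outline$points
  resid <- sqrt(rowSums((rec - mesh$vertices[, 1:2])^2))
  expect_lt(max(resid), 1e-9)
})

test_that("identity, translation and uniform-scale deformations are exact", {
  mesh <- mesh1(); B <- binding1()
  o <- mesh$outline
  same <- deform_mesh(mesh, B, o$points)
  expect_lt(max(abs(same$vertices - mesh$vertices)), 1e-9)

  shifted <- deform_mesh(mesh, B, sweep(o$points, 2, c(5, -3), "+"))
  delta <- shifted$vertices[, 1:2] - mesh$vertices[, 1:2]
  expect_lt(max(abs(sweep(delta, 2, c(5, -3), "-"))), 1e-9)
  expect_identical(shifted$faces, mesh$faces)
  expect_identical(shifted$vertices[, 3], mesh$vertices[, 3])

  ctr <- colMeans(o$points)
  scaled <- deform_mesh(mesh, B,
                        sweep(sweep(o$points, 2, ctr, "-") * 1.2, 2, ctr, "+"))
  set.seed(7)
  i <- sample(nrow(mesh$vertices), 50); j <- sample(nrow(mesh$vertices), 50)
  ok <- i != j
  d0 <- sqrt(rowSums((mesh$vertices[i[ok], 1:2] - mesh$vertices[j[ok], 1:2])^2))
  d1 <- sqrt(rowSums((scaled$vertices[i[ok], 1:2] - scaled$vertices[j[ok], 1:2])^2))
  expect_equal(d1 / d0, rep(1.2, sum(ok)), tolerance = 1e-6)
})

test_that("deformation preserves topology and rejects degenerate landmarks", {
  mesh <- mesh1(); B <- binding1()
  target <- perturb_exemplar(mesh$outline, 4, 3)
  moved <- deform_mesh(mesh, B, target$points)
  v <- validate_mesh(moved)
  v <- Filter(function(x) x$invariant != "boundary-map", v)
  expect_length(v, 0)

  bowtie <- mesh$outline$points
  bowtie[c(15, 16), ] <- bowtie[c(16, 15), ]
  expect_error(deform_mesh(mesh, B, bowtie), "self-intersects")
})

test_that("OBJ and PLY exports round-trip and parse in an independent
           reader", {
  mesh <- mesh1()
  obj <- withr::local_tempfile(fileext = ".obj")
  ply <- withr::local_tempfile(fileext = ".ply")
  export_mesh(mesh, obj)
  export_mesh(mesh, ply)
  back_obj <- import_mesh(obj)
  back_ply <- import_mesh(ply)
  expect_identical(back_obj$faces, mesh$faces)
  expect_identical(back_ply$faces, mesh$faces)
  expect_equal(back_obj$vertices, mesh$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(sum(grepl("^v ", readLines(obj))), nrow(mesh$vertices))

  # independent oracle: the Python trimesh reader sees the same watertight mesh
  py <- Sys.which("python")
  if (nzchar(py)) {
    script <- sprintf(
      "import trimesh, sys\nm = trimesh.load('%s', process=False)\nprint(len(m.vertices), len(m.faces), bool(m.is_watertight))", obj)
    out <- tryCatch(system2(py, "-", input = script, stdout = TRUE,
                            stderr = FALSE),
                    error = function(e) character(0), warning = function(w) character(0))
    if (length(out) == 1) {
      parts <- strsplit(trimws(out), " ")[[1]]
      expect_equal(as.integer(parts[1]), nrow(mesh$vertices))
      expect_equal(as.integer(parts[2]), nrow(mesh$faces))
      expect_identical(parts[3], "True")
    }
  }
})
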