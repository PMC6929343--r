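# Box-plot statistics, control-vs-predicted comparison reports and figures.

test_that("control-point CSV parsing enforces the 34-row contract", {
  pts <- exemplar(1)$points
  path <- withr::local_tempfile(fileext = ".csv")
  write_control_points(pts, path)
  back <- read_control_points(path)
  expect_equal(unclass(back), pts, tolerance = 1e-6, ignore_attr = TRUE)

  writeLines(c("x,y", sprintf("%f,%f", 1:33, 1:33)), path)
  expect_error(read_control_points(path), "expected 34, found 33")
  writeLines(c(sprintf("%f,%f", 1:33, 1:33), "a,b"), path)
  expect_error(read_control_points(path), "row 34")
})

test_that("boxplot statistics follow the 1+(n-1)p quartile rule", {
  st <- boxplot_stats(c(1, 2, 3, 4, 5))
  expect_equal(unlist(st),
               c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))
  cst <- boxplot_stats(rep(7.5, 20))
  expect_true(all(unlist(cst) == 7.5))
  set.seed(17)
  v <- rnorm(101)
  expect_equal(unlist(boxplot_stats(sample(v))), unlist(boxplot_stats(v)))
  expect_error(boxplot_stats(numeric(0)))
})

test_that("quartiles match a brute-force interpolation oracle on 1000
           random sequences", {
  brute <- function(x, p) {
    s <- sort(x)
    h <- 1 + (length(x) - 1) * p
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  set.seed(23)
  for (i in 1:1000) {
    n <- sample(2:60, 1)
    x <- runif(n, -50, 50)
    st <- boxplot_stats(x)
    expect_lt(abs(st$q1 - brute(x, 0.25)), 1e-12)
    expect_lt(abs(st$median - brute(x, 0.5)), 1e-12)
    expect_lt(abs(st$q3 - brute(x, 0.75)), 1e-12)
  }
})

test_that("comparison reports behave under identity, shift and swapping", {
  ctrl <- exemplar(3)$points
  same <- compare_point_sets(ctrl, ctrl)
  expect_equal(same$rmse, 0)
  expect_true(all(same$abs_diff_x == 0) && all(same$abs_diff_y == 0))

  shifted <- compare_point_sets(ctrl, sweep(ctrl, 2, c(2, 0), "+"))
  expect_equal(unname(shifted$diff_x["median"]), 2)
  expect_true(all(shifted$diff_y == 0))
  expect_equal(shifted$rmse, 2)

  set.seed(3)
  pred <- ctrl + matrix(rnorm(68), 34, 2)
  fwd <- compare_point_sets(ctrl, pred)
  rev <- compare_point_sets(pred, ctrl)
  expect_equal(rev$diff_x, -fwd$diff_x)
  expect_equal(rev$abs_diff_x, fwd$abs_diff_x)
  expect_equal(fwd$rmse, sqrt(mean(rowSums((pred - ctrl)^2))))
  expect_equal(fwd$max_error, max(sqrt(rowSums((pred - ctrl)^2))))
  expect_error(compare_point_sets(ctrl[1:10, ], pred), "34 points")
})

test_that("report serialization and figures are produced deterministically", {
  ctrl <- exemplar(2)$points
  set.seed(5)
  report <- compare_point_sets(ctrl, ctrl + matrix(rnorm(68, sd = 2), 34, 2))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_comparison(report, csv)
  write_comparison(report, js)
  tab <- utils::read.csv(csv)
  expect_equal(tab$statistic, c("min", "q1", "median", "q3", "max"))
  expect_equal(tab$control_x, unname(unlist(report$stats$control_x)))
  parsed <- jsonlite::fromJSON(readLines(js))
  expect_equal(parsed$rmse, report$rmse)

  svg1 <- withr::local_tempfile(fileext = ".svg")
  svg2 <- withr::local_tempfile(fileext = ".svg")
  render_boxplots(report, svg1)
  render_boxplots(report, svg2)
  expect_identical(readLines(svg1), readLines(svg2))
  expect_gt(file.size(svg1), 0)

  # recover the box geometry from the SVG and invert the declared axis range
  skip_if_not_installed("xml2")
  doc <- xml2::read_xml(svg1)
  panel <- xml2::xml_find_first(doc, "//*[@id='panel-x']")
  vmax <- as.numeric(xml2::xml_text(
    xml2::xml_find_first(panel, ".//*[@class='axis-max']")))
  vmin <- as.numeric(xml2::xml_text(
    xml2::xml_find_first(panel, ".//*[@class='axis-min']")))
  rects <- xml2::xml_find_all(panel, ".//*[local-name()='rect']")
  y <- as.numeric(xml2::xml_attr(rects[[1]], "y"))
  h <- as.numeric(xml2::xml_attr(rects[[1]], "height"))
  to_value <- function(ypx) vmax - (ypx - 40) / 300 * (vmax - vmin)
  expect_equal(to_value(y), report$stats$control_x$q3, tolerance = 1e-3)
  expect_equal(to_value(y + h), report$stats$control_x$q1, tolerance = 1e-3)
})
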