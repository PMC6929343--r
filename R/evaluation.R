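# Quantitative evaluation: manually annotated control points vs predicted
# landmarks, compared through per-axis five-number summaries (the box-plot
# statistics) plus index-wise point error metrics.

#' Read a 34-row control-point CSV
#'
#' Columns `x,y`, header optional.  Exactly 34 numeric rows are required.
#'
#' @param path CSV file path.
#' @return 34 x 2 matrix of (x, y) pairs, class `control_points`.
#' @export
read_control_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0) {
    first <- strsplit(lines[1], ",")[[1]]
    if (is.na(suppressWarnings(as.numeric(first[1])))) lines <- lines[-1]
  }
  n <- length(lines)
  if (n != 34L)
    stop(sprintf("control-point file must have 34 rows: expected 34, found %d", n))
  pts <- matrix(NA_real_, 34, 2)
  for (i in seq_len(34)) {
    cells <- suppressWarnings(as.numeric(strsplit(lines[i], ",")[[1]][1:2]))
    if (anyNA(cells))
      stop(sprintf("non-numeric control-point value at row %d", i))
    pts[i, ] <- cells
  }
  structure(pts, class = c("control_points", class(pts)))
}

#' Write control points as CSV (34 rows, header `x,y`, 6 decimals)
#' @param points 34 x 2 matrix.
#' @param path Output path.
#' @export
write_control_points <- function(points, path) {
  write_outline_csv(as.matrix(unclass(points)), path)
}

#' Five-number summary for a box plot
#'
#' Quartiles use linear interpolation of the order statistics at positions
#' 1 + (n - 1) p (the spreadsheet/type-7 rule).
#'
#' @param values Non-empty numeric vector.
#' @return A `boxplot_stats` list: `min`, `q1`, `median`, `q3`, `max`.
#' @export
boxplot_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) stop("non-empty numeric input required")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(min = min(values), q1 = q[1], median = q[2], q3 = q[3],
                 max = max(values)), class = "boxplot_stats")
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf("min %.3f | Q1 %.3f | median %.3f | Q3 %.3f | max %.3f\n",
              x$min, x$q1, x$median, x$q3, x$max))
  invisible(x)
}

#' Compare a control point set against predicted landmarks
#'
#' Produces the box-plot comparison — five-number summaries for control-X,
#' predicted-X, control-Y and predicted-Y with per-statistic signed and
#' absolute differences — plus index-wise point metrics: mean and maximum
#' Euclidean error and RMSE.  Index-wise metrics assume the control points
#' are annotated in primitive order.
#'
#' @param control 34 x 2 matrix (e.g. from [read_control_points()]).
#' @param predicted 34 x 2 matrix of predicted landmarks.
#' @return A `landmark_comparison` list.
#' @export
compare_point_sets <- function(control, predicted) {
  control <- as.matrix(unclass(control)); predicted <- as.matrix(unclass(predicted))
  if (nrow(control) != 34L || nrow(predicted) != 34L)
    stop(sprintf("both point sets must have 34 points (found %d and %d)",
                 nrow(control), nrow(predicted)))
  stats4 <- list(control_x = boxplot_stats(control[, 1]),
                 predicted_x = boxplot_stats(predicted[, 1]),
                 control_y = boxplot_stats(control[, 2]),
                 predicted_y = boxplot_stats(predicted[, 2]))
  diff_axis <- function(a, b)
    vapply(c("min", "q1", "median", "q3", "max"),
           function(s) b[[s]] - a[[s]], numeric(1))
  d_x <- diff_axis(stats4$control_x, stats4$predicted_x)
  d_y <- diff_axis(stats4$control_y, stats4$predicted_y)
  err <- sqrt(rowSums((predicted - control)^2))
  structure(list(stats = stats4,
                 diff_x = d_x, diff_y = d_y,
                 abs_diff_x = abs(d_x), abs_diff_y = abs(d_y),
                 mean_error = mean(err), max_error = max(err),
                 rmse = sqrt(mean(err^2))),
            class = "landmark_comparison")
}

#' @export
print.landmark_comparison <- function(x, ...) {
  cat("Landmark comparison (control vs predicted)\n")
  for (nm in names(x$stats)) {
    cat(sprintf("  %-12s ", nm)); print(x$stats[[nm]])
  }
  cat(sprintf("  mean error %.3f px | max error %.3f px | RMSE %.3f px\n",
              x$mean_error, x$max_error, x$rmse))
  invisible(x)
}

#' Serialize a comparison report as CSV and/or JSON
#'
#' @param report A [compare_point_sets()] result.
#' @param path Output path ending in `.csv` or `.json`.
#' @export
write_comparison <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  stat_names <- c("min", "q1", "median", "q3", "max")
  tab <- data.frame(statistic = stat_names,
                    control_x = unlist(report$stats$control_x),
                    predicted_x = unlist(report$stats$predicted_x),
                    control_y = unlist(report$stats$control_y),
                    predicted_y = unlist(report$stats$predicted_y),
                    row.names = NULL)
  if (ext == "json") {
    payload <- unclass(report)
    payload$stats <- lapply(report$stats, unclass)
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
               path)
  } else {
    tab$abs_diff_x <- report$abs_diff_x
    tab$abs_diff_y <- report$abs_diff_y
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

# Layout constants for the hand-written SVG box plots; axis limits are
# printed on the y axis so the geometry can be inverted from the file alone.
svg_plot_height <- 300
svg_plot_pad <- 40

svg_box <- function(st, cx, vmin, vmax, fill) {
  y_of <- function(v) svg_plot_pad + (vmax - v) / (vmax - vmin) * svg_plot_height
  w <- 40
  c(sprintf('<line x1="%g" y1="%.3f" x2="%g" y2="%.3f" stroke="black"/>',
            cx, y_of(st$min), cx, y_of(st$q1)),
    sprintf('<line x1="%g" y1="%.3f" x2="%g" y2="%.3f" stroke="black"/>',
            cx, y_of(st$q3), cx, y_of(st$max)),
    sprintf('<rect x="%g" y="%.3f" width="%g" height="%.3f" fill="%s" stroke="black"/>',
            cx - w / 2, y_of(st$q3), w, y_of(st$q1) - y_of(st$q3), fill),
    sprintf('<line x1="%g" y1="%.3f" x2="%g" y2="%.3f" stroke="black" stroke-width="2"/>',
            cx - w / 2, y_of(st$median), cx + w / 2, y_of(st$median)))
}

#' Render the control-vs-predicted box plots
#'
#' One panel per axis with the control and predicted boxes side by side.
#' `.svg` paths get a deterministic hand-written SVG (identical bytes for
#' identical reports); `.png` paths are rendered through the png device.
#'
#' @param report A [compare_point_sets()] result.
#' @param path Output path ending in `.svg` or `.png`.
#' @export
render_boxplots <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    panels <- list(x = list(report$stats$control_x, report$stats$predicted_x),
                   y = list(report$stats$control_y, report$stats$predicted_y))
    body <- character(0)
    for (pi in seq_along(panels)) {
      sts <- panels[[pi]]
      vmin <- min(sts[[1]]$min, sts[[2]]$min)
      vmax <- max(sts[[1]]$max, sts[[2]]$max)
      if (vmax - vmin < 1e-9) vmax <- vmin + 1
      x0 <- (pi - 1) * 260
      body <- c(body,
                sprintf('<g id="panel-%s">', names(panels)[pi]),
                sprintf('<text x="%g" y="20" font-size="14">coordinate-%s</text>',
                        x0 + 90, toupper(names(panels)[pi])),
                sprintf('<text class="axis-max" x="%g" y="%g" font-size="10">%.6f</text>',
                        x0 + 8, svg_plot_pad, vmax),
                sprintf('<text class="axis-min" x="%g" y="%g" font-size="10">%.6f</text>',
                        x0 + 8, svg_plot_pad + svg_plot_height, vmin),
                svg_box(sts[[1]], x0 + 110, vmin, vmax, "#9ecae1"),
                svg_box(sts[[2]], x0 + 190, vmin, vmax, "#fc9272"),
                sprintf('<text x="%g" y="%g" font-size="11">control</text>',
                        x0 + 90, svg_plot_pad + svg_plot_height + 20),
                sprintf('<text x="%g" y="%g" font-size="11">predicted</text>',
                        x0 + 170, svg_plot_pad + svg_plot_height + 20),
                '</g>')
    }
    writeLines(c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="520" height="%g" viewBox="0 0 520 %g">',
                         svg_plot_height + 2 * svg_plot_pad,
                         svg_plot_height + 2 * svg_plot_pad),
                 body, '</svg>'), path)
  } else if (ext == "png") {
    grDevices::png(path, width = 700, height = 400, type = "cairo")
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, 2))
    for (axis in c("x", "y")) {
      sts <- report$stats[paste0(c("control_", "predicted_"), axis)]
      bx <- list(stats = vapply(sts, function(s)
        c(s$min, s$q1, s$median, s$q3, s$max), numeric(5)),
        n = c(34, 34), names = c("control", "predicted"))
      graphics::bxp(bx, main = paste0("coordinate-", toupper(axis)))
    }
  } else stop("unsupported figure format: use .svg or .png")
  invisible(path)
}
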