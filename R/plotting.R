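#' Specify a plot
#'
#' A validated description of a scatter/time-series or box plot over a
#' combined table: variables, optional colour grouping and faceting, an
#' optional LOESS smoother, labels, and the output image parameters.
#'
#' @param x_var,y_var Column names to plot.
#' @param geometry `"scatter"` or `"boxplot"`.
#' @param color_group Optional column used to colour series.
#' @param facet_group Optional column used to split the plot into panels.
#' @param smoother `"none"` or `"loess"` (scatter only).
#' @param span LOESS span, a fraction in (0, 1] of points entering each local
#'   fit (default 0.75).
#' @param title,xlab,ylab Optional labels.
#' @param path Optional output image path; written by [render_plot()].
#' @param format `"png"` or `"svg"`.
#' @param width,height Image size in inches.
#' @param dpi Raster resolution for PNG output.
#' @return An object of class `plot_spec`.
#' @export
plot_spec <- function(x_var, y_var, geometry = c("scatter", "boxplot"),
                      color_group = NULL, facet_group = NULL,
                      smoother = c("none", "loess"), span = 0.75,
                      title = NULL, xlab = NULL, ylab = NULL,
                      path = NULL, format = c("png", "svg"),
                      width = 7, height = 5, dpi = 150) {
  geometry <- match.arg(geometry)
  smoother <- match.arg(smoother)
  format <- match.arg(format)
  if (!is.numeric(span) || length(span) != 1 || is.na(span) ||
      span <= 0 || span > 1) {
    abort_invalid("`span` must be a fraction in (0, 1]")
  }
  structure(list(x_var = x_var, y_var = y_var, geometry = geometry,
                 color_group = color_group, facet_group = facet_group,
                 smoother = smoother, span = span, title = title,
                 xlab = xlab, ylab = ylab, path = path, format = format,
                 width = width, height = height, dpi = dpi),
            class = "plot_spec")
}

# Type-7 quartiles plus the 1.5*IQR whisker rule.
box_summary <- function(v) {
  v <- v[!is.na(v)]
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  tibble(n = length(v), min = min(v), q1 = q[1], median = q[2], q3 = q[3],
         max = max(v),
         whisker_lo = min(v[v >= lo_fence]),
         whisker_hi = max(v[v <= hi_fence]),
         n_outliers = sum(v < lo_fence | v > hi_fence))
}

#' Render a plot and its machine-checkable sidecar
#'
#' Builds the ggplot described by a [plot_spec()], optionally writes it to
#' `spec$path`, and returns alongside it a `plot_data` sidecar recording what
#' was drawn: the panel list, per-panel/series point counts, the smoother
#' curves, and (for boxplots) five-number summaries with the 1.5 IQR whisker
#' rule and type-7 quartiles. The sidecar, not the pixels, is the testable
#' surface. The input table is never modified. LOESS smoothers are drawn per
#' series from [loess_smooth()] and skipped for series with fewer than 3
#' points.
#'
#' @param spec A [plot_spec()].
#' @param table A data frame (e.g. a table of a `combined_data`).
#' @return Invisibly, a list with `plot` (the ggplot object), `data` (the
#'   `plot_data` sidecar: `panels`, `series`, `smooth`, `boxes`) and `path`.
#' @export
render_plot <- function(spec, table) {
  if (!inherits(spec, "plot_spec")) abort_invalid("`spec` must be a plot_spec")
  cols <- c(spec$x_var, spec$y_var, spec$color_group, spec$facet_group)
  for (col in cols) {
    if (!col %in% names(table)) abort_invalid("unknown column \"%s\"", col)
  }
  df <- as_tibble(table)
  df <- df[!is.na(df[[spec$x_var]]) & !is.na(df[[spec$y_var]]), ]
  if (!nrow(df)) abort_invalid("no data to plot")

  if (spec$geometry == "boxplot" && is.numeric(df[[spec$x_var]]) &&
      is.null(spec$color_group)) {
    abort_invalid(
      "boxplot requires a categorical `x_var` or a `color_group`")
  }

  df$.panel <- if (!is.null(spec$facet_group)) {
    as.character(df[[spec$facet_group]])
  } else {
    "(all)"
  }
  df$.series <- if (!is.null(spec$color_group)) {
    as.character(df[[spec$color_group]])
  } else {
    "(all)"
  }

  series <- df |>
    group_by(.data$.panel, .data$.series) |>
    summarise(n_points = n(), .groups = "drop") |>
    rename(panel = ".panel", series = ".series")

  smooth <- NULL
  if (spec$geometry == "scatter" && spec$smoother == "loess") {
    smooth <- df |>
      group_by(.data$.panel, .data$.series) |>
      group_modify(function(d, key) {
        if (nrow(d) < 3 || length(unique(d[[spec$x_var]])) < 2) {
          return(tibble(x = numeric(0), y = numeric(0)))
        }
        loess_smooth(d[[spec$x_var]], d[[spec$y_var]], span = spec$span)
      }) |>
      ungroup() |>
      rename(panel = ".panel", series = ".series")
  }

  boxes <- NULL
  if (spec$geometry == "boxplot") {
    boxes <- df |>
      mutate(.x = as.character(.data[[spec$x_var]])) |>
      group_by(.data$.panel, .data$.series, .data$.x) |>
      group_modify(~ box_summary(.x[[spec$y_var]])) |>
      ungroup() |>
      rename(panel = ".panel", series = ".series", x = ".x")
  }

  aes_base <- aes(x = .data[[spec$x_var]], y = .data[[spec$y_var]])
  p <- ggplot(df, aes_base)
  if (spec$geometry == "scatter") {
    p <- if (!is.null(spec$color_group)) {
      p + geom_point(aes(color = .data[[spec$color_group]]))
    } else {
      p + geom_point()
    }
    if (!is.null(smooth) && nrow(smooth)) {
      p <- p + geom_line(
        data = rename(smooth, .panel = "panel", .series = "series"),
        aes(x = .data$x, y = .data$y, group = .data$.series),
        linewidth = 0.8)
    }
  } else {
    p <- if (!is.null(spec$color_group)) {
      p + geom_boxplot(aes(fill = .data[[spec$color_group]],
                           group = interaction(.data[[spec$x_var]],
                                               .data[[spec$color_group]])))
    } else {
      p + geom_boxplot(aes(group = .data[[spec$x_var]]))
    }
  }
  if (!is.null(spec$facet_group)) {
    p <- p + facet_wrap(~ .panel)
  }
  p <- p + labs(title = spec$title,
                x = spec$xlab %||% spec$x_var,
                y = spec$ylab %||% spec$y_var)

  if (!is.null(spec$path)) {
    if (spec$format == "png") {
      png(spec$path, width = spec$width, height = spec$height, units = "in",
          res = spec$dpi)
    } else {
      svg(spec$path, width = spec$width, height = spec$height)
    }
    print(p)
    dev.off()
  }

  out <- list(plot = p,
              data = structure(list(panels = sort(unique(df$.panel)),
                                    series = series, smooth = smooth,
                                    boxes = boxes),
                               class = "plot_data"),
              path = spec$path)
  invisible(out)
}

#' LOESS smoother (tricube local-linear regression)
#'
#' Locally weighted linear regression: at each of 100 evenly spaced grid
#' points across `[min(x), max(x)]`, a degree-1 polynomial is fitted to the
#' `ceiling(span * n)` nearest points with tricube weights
#' `(1 - (d/d_max)^3)^3`. When the window spans all points the weights are
#' uniform, so the curve reduces to the global OLS line.
#'
#' @param x,y Finite numeric vectors of equal length (n >= 3, at least two
#'   distinct x).
#' @param span Fraction of points in each local window, in (0, 1].
#' @param grid_n Number of evaluation points (default 100).
#' @return A tibble with the fitted curve: columns `x`, `y`.
#' @export
#' @examples
#' loess_smooth(1:10, (1:10)^2, span = 0.75)
loess_smooth <- function(x, y, span = 0.75, grid_n = 100L) {
  if (length(x) != length(y)) abort_invalid("`x` and `y` lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_invalid("`x` and `y` must be finite")
  }
  n <- length(x)
  if (n < 3) abort_invalid("loess smoothing needs at least 3 points, got %d", n)
  if (length(unique(x)) < 2) abort_invalid("`x` must have at least 2 distinct values")
  if (!is.numeric(span) || span <= 0 || span > 1) {
    abort_invalid("`span` must be in (0, 1]")
  }
  q <- ceiling(span * n)
  grid <- seq(min(x), max(x), length.out = grid_n)
  fit_at <- function(x0) {
    d <- abs(x - x0)
    if (q >= n) {
      w <- rep(1, n)
    } else {
      dq <- sort(d, partial = q)[q]
      w <- if (dq == 0) as.numeric(d == 0) else pmax(0, (1 - (d / dq)^3))^3
    }
    sw <- sum(w)
    xb <- sum(w * x) / sw
    yb <- sum(w * y) / sw
    sxx <- sum(w * (x - xb)^2)
    if (sxx == 0) return(yb)
    b <- sum(w * (x - xb) * (y - yb)) / sxx
    yb + b * (x0 - xb)
  }
  tibble(x = grid, y = vapply(grid, fit_at, numeric(1)))
}
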