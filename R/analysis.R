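#' Time-window summary statistics
#'
#' Partitions a dataset along a time variable into consecutive windows of a
#' fixed width and reports, per group and window, the number of non-missing
#' values, their mean, sample standard deviation (n-1 denominator) and
#' coefficient of variation (SD/mean). Windows are anchored at the minimum
#' observed time value and step by `width`; the final window may be partial,
#' which shows in its `window_end` (clamped to the maximum observed time).
#' The CV is reported as missing when the mean is 0 or fewer than two values
#' are available. Rows are emitted for every group x window combination, so
#' empty cells appear with `n = 0`.
#'
#' @param table A data frame.
#' @param value_var Name of the numeric variable to summarise.
#' @param time_var Name of the time variable (e.g. a year column).
#' @param width Window width in units of `time_var` (>= 1).
#' @param group_vars Optional character vector of grouping columns.
#' @return A tibble: group columns, `window_start`, `window_end`, `n`,
#'   `mean`, `sd`, `cv`.
#' @export
#' @examples
#' tb <- tibble::tibble(year = 2020:2029, yield = 1:10)
#' time_window_summary(tb, "yield", "year", width = 5)
time_window_summary <- function(table, value_var, time_var, width,
                                group_vars = character(0)) {
  if (!is.numeric(width) || length(width) != 1 || is.na(width) || width <= 0) {
    abort_invalid("`width` must be a positive number")
  }
  for (col in c(value_var, time_var, group_vars)) {
    if (!col %in% names(table)) abort_invalid("unknown column \"%s\"", col)
  }
  if (!is.numeric(table[[value_var]])) {
    abort_invalid("`value_var` \"%s\" must be numeric", value_var)
  }

  tt <- table[[time_var]]
  ok_time <- !is.na(tt)
  df <- as_tibble(table[ok_time, c(group_vars, time_var, value_var)])
  if (!nrow(df)) {
    out <- tibble(window_start = numeric(0), window_end = numeric(0),
                  n = integer(0), mean = numeric(0), sd = numeric(0),
                  cv = numeric(0))
    return(out)
  }
  t0 <- min(df[[time_var]])
  t1 <- max(df[[time_var]])
  df$.window <- floor((df[[time_var]] - t0) / width)
  n_windows <- max(df$.window) + 1L
  windows <- tibble(
    .window = seq_len(n_windows) - 1,
    window_start = t0 + width * (seq_len(n_windows) - 1),
    window_end = pmin(t0 + width * seq_len(n_windows) - 1, t1)
  )

  grid <- if (length(group_vars)) {
    crossing(distinct(df[group_vars]), windows)
  } else {
    windows
  }

  stats <- df |>
    group_by(across(all_of(c(group_vars, ".window")))) |>
    summarise(
      n = sum(!is.na(.data[[value_var]])),
      mean = if (n > 0) base::mean(.data[[value_var]], na.rm = TRUE) else NA_real_,
      sd = if (n >= 2) stats::sd(.data[[value_var]], na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(cv = if_else(!is.na(sd) & !is.na(mean) & mean != 0, sd / mean,
                        NA_real_))

  out <- left_join(grid, stats, by = c(group_vars, ".window")) |>
    mutate(n = if_else(is.na(n), 0L, as.integer(n))) |>
    select(all_of(group_vars), window_start, window_end, n, mean, sd, cv) |>
    arrange(across(all_of(c(group_vars, "window_start"))))
  out
}

#' Grouped simple linear regression
#'
#' Ordinary least-squares regression of `y_var` on `x_var`, fitted with
#' [stats::lm()] separately within each group. Each row reports the number of
#' complete observations, the slope and intercept, the R-squared (proportion
#' of variance explained) and the two-sided p-value of the t-test that the
#' slope differs from zero (df = n - 2). P-values are raw — no multiplicity
#' correction is applied. Degenerate cases yield missing fields: fewer than 2
#' points, zero-variance x (with a warning), constant y (R-squared undefined)
#' or a perfect zero-residual fit (slope SE is 0, so the t statistic is
#' undefined).
#'
#' @param table A data frame.
#' @param y_var,x_var Names of the dependent and independent variables.
#' @param group_vars Optional character vector of grouping columns.
#' @return A tibble: group columns, `n`, `slope`, `intercept`, `r_squared`,
#'   `p_value`.
#' @export
#' @examples
#' tb <- tibble::tibble(x = 1:3, y = c(1, 3, 2))
#' linear_regression(tb, "y", "x")
linear_regression <- function(table, y_var, x_var,
                              group_vars = character(0)) {
  for (col in c(y_var, x_var, group_vars)) {
    if (!col %in% names(table)) abort_invalid("unknown column \"%s\"", col)
  }
  df <- as_tibble(table[c(group_vars, x_var, y_var)])

  fit_one <- function(d, key) {
    x <- d[[x_var]]
    y <- d[[y_var]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    empty <- tibble(n = n, slope = NA_real_, intercept = NA_real_,
                    r_squared = NA_real_, p_value = NA_real_)
    if (n < 2) return(empty)
    if (length(unique(x)) < 2) {
      warn(sprintf("degenerate x (zero variance) in group %s; slope undefined",
                   if (nrow(key)) paste(unlist(key), collapse = "/") else "<all>"),
           class = "aquabatch_degenerate_x")
      return(empty)
    }
    fit <- lm(y ~ x)
    cf <- coef(fit)
    syy <- sum((y - base::mean(y))^2)
    r2 <- if (syy > 0) {
      rss <- sum(residuals(fit)^2)
      1 - rss / syy
    } else {
      NA_real_
    }
    p <- NA_real_
    if (n >= 3) {
      # a zero-residual fit has no usable slope SE; p stays NA (and base R's
      # "essentially perfect fit" warning is redundant with that rule)
      sm <- withCallingHandlers(
        coef(summary(fit)),
        warning = function(w) {
          if (grepl("essentially perfect fit", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      se <- sm["x", "Std. Error"]
      if (is.finite(se) && se > 0) p <- sm["x", "Pr(>|t|)"]
    }
    tibble(n = n, slope = unname(cf["x"]), intercept = unname(cf["(Intercept)"]),
           r_squared = r2, p_value = p)
  }

  if (length(group_vars)) {
    df |>
      group_by(across(all_of(group_vars))) |>
      group_modify(fit_one) |>
      ungroup() |>
      arrange(across(all_of(group_vars)))
  } else {
    fit_one(df, tibble())
  }
}
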