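# Small, fast fixture builders shared across tests. The toy crop matures at
# 600 GDD (cycle ~60 days), so one season simulates in milliseconds.

tiny_weather <- function(n_years = 2, seed = 1, ...) {
  generate_weather(weather_params(n_years = n_years, seed = seed, ...))
}

tiny_crop <- function(...) {
  args <- utils::modifyList(list(gdd_maturity = 600, max_cycle_days = 90),
                            list(...))
  do.call(toy_crop_params, args)
}

tiny_seasons <- function(n_years = 2, seed = 1, ...) {
  simulate_years(tiny_weather(n_years, seed), tiny_crop(...))
}

tiny_plugin_run <- function(dir, prefix = "Maize_Soroca_RCP26",
                            n_years = 2, seed = 1) {
  write_plugin_fileset(tiny_seasons(n_years, seed), dir, prefix)
}

# A small balanced 2x2 study (4 runs, 2 seasons each).
tiny_study <- function(dir, seed = 1, n_years = 2, mode = "plugin") {
  design <- study_design(
    "Maize",
    list(location = c("Soroca", "Cahul"), scenario = c("RCP26", "RCP85")),
    overrides = list(scenario = list(
      RCP26 = list(weather = list(warming_trend = 0.15)),
      RCP85 = list(weather = list(warming_trend = 0.55))
    ))
  )
  generate_study(design, weather_params(n_years = n_years, seed = seed),
                 tiny_crop(), dir, mode = mode)
}

# Closed-form OLS oracle: normal equations + Student-t tail, independent of
# the lm()-based implementation.
ols_oracle <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  sxy <- sum((x - xb) * (y - yb))
  syy <- sum((y - yb)^2)
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
  rss <- syy - slope * sxy
  se <- sqrt((rss / (n - 2)) / sxx)
  p <- if (n >= 3 && se > 0) 2 * pt(abs(slope / se), df = n - 2,
                                    lower.tail = FALSE) else NA_real_
  list(n = n, slope = slope, intercept = intercept, r_squared = r2,
       p_value = p)
}

# Brute-force window-summary oracle: explicit partition, textbook formulas.
window_oracle <- function(time, value, width) {
  ok <- !is.na(time)
  time <- time[ok]; value <- value[ok]
  t0 <- min(time); t1 <- max(time)
  starts <- seq(t0, t1, by = width)
  lapply(starts, function(s) {
    e <- min(s + width - 1, t1)
    v <- value[time >= s & time <= e & !is.na(value)]
    m <- if (length(v)) mean(v) else NA_real_
    sdv <- if (length(v) >= 2) sqrt(sum((v - m)^2) / (length(v) - 1)) else NA_real_
    list(window_start = s, window_end = e, n = length(v), mean = m, sd = sdv,
         cv = if (!is.na(sdv) && !is.na(m) && m != 0) sdv / m else NA_real_)
  })
}
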