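#' Parameters for the synthetic daily weather generator
#'
#' Bundles the inputs of [generate_weather()]. The defaults sketch a temperate
#' continental climate (warm summers, cold winters) similar to the lowlands of
#' the Republic of Moldova, the setting of the package's worked examples.
#'
#' @param start_year First calendar year of the series.
#' @param n_years Number of 365-day years to generate (>= 1).
#' @param base_tmin,base_tmax Annual-mean daily minimum / maximum air
#'   temperature, degrees C (`base_tmax > base_tmin`).
#' @param seasonal_amplitude Amplitude of the sinusoidal seasonal temperature
#'   cycle, degrees C; the cycle peaks in mid July.
#' @param warming_trend Linear warming, degrees C per decade, applied
#'   continuously over the series.
#' @param eto_base Annual-mean reference evapotranspiration (ETo), mm/day
#'   (> 0); ETo follows the same seasonal phase with half relative amplitude.
#' @param rain_mean Mean daily rainfall, mm/day (>= 0), realised as seeded
#'   wet/dry days with exponentially distributed wet-day amounts.
#' @param noise_sd Standard deviation of the daily temperature noise, degrees
#'   C (>= 0). One draw per day is added to both `tmin` and `tmax`, so the
#'   diurnal range is preserved.
#' @param seed Integer seed; a fixed seed makes the series reproducible.
#' @return An object of class `weather_params` (a validated list).
#' @export
#' @examples
#' wp <- weather_params(n_years = 2, seed = 42)
#' w <- generate_weather(wp)
#' head(w)
weather_params <- function(start_year = 2010, n_years = 30,
                           base_tmin = 6, base_tmax = 16,
                           seasonal_amplitude = 11, warming_trend = 0,
                           eto_base = 3, rain_mean = 1.6,
                           noise_sd = 1.5, seed = 1L) {
  p <- list(start_year = as.integer(start_year), n_years = as.integer(n_years),
            base_tmin = base_tmin, base_tmax = base_tmax,
            seasonal_amplitude = seasonal_amplitude,
            warming_trend = warming_trend, eto_base = eto_base,
            rain_mean = rain_mean, noise_sd = noise_sd, seed = as.integer(seed))
  check_num <- function(field, ok, what) {
    x <- p[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || !ok(x)) {
      abort_invalid("invalid `%s`: must be %s", field, what)
    }
  }
  check_num("n_years", function(x) x >= 1, "at least 1")
  check_num("base_tmin", function(x) TRUE, "a number")
  check_num("base_tmax", function(x) x > p$base_tmin,
            "greater than `base_tmin`")
  check_num("seasonal_amplitude", function(x) x >= 0, "non-negative")
  check_num("eto_base", function(x) x > 0, "positive")
  check_num("rain_mean", function(x) x >= 0, "non-negative")
  check_num("noise_sd", function(x) x >= 0, "non-negative")
  check_num("warming_trend", function(x) TRUE, "a number")
  check_num("seed", function(x) TRUE, "an integer")
  structure(p, class = "weather_params")
}

#' Generate a seeded synthetic daily weather series
#'
#' Produces `n_years` x 365 days (the fixture calendar has no leap days) of
#' daily minimum and maximum air temperature, reference evapotranspiration
#' (ETo) and rainfall — the climate inputs a crop-water model consumes.
#' Temperature is `base + seasonal sinusoid + linear warming + noise`; the
#' same noise draw enters `tmin` and `tmax`, so `tmax - tmin` stays at its
#' base value every day. The series is deterministic for a fixed seed.
#'
#' @param params A [weather_params()] object.
#' @return A tibble with one row per day: `year`, `doy` (1-365), `month`,
#'   `day`, `tmin`, `tmax` (degC), `eto`, `rain` (mm). The generating
#'   parameters are attached as attribute `"params"`.
#' @export
generate_weather <- function(params) {
  if (!inherits(params, "weather_params")) params <- do.call(weather_params, params)
  n <- params$n_years * 365L
  idx <- seq_len(n) - 1L
  year <- params$start_year + idx %/% 365L
  doy <- idx %% 365L + 1L
  md <- doy_to_md(doy)

  # seasonal cycle peaking mid July (doy ~196)
  phase <- sin(2 * pi * (doy - 105) / 365)
  seasonal <- params$seasonal_amplitude * phase
  warming <- params$warming_trend / 10 * idx / 365

  draws <- with_seed(params$seed, {
    noise <- rnorm(n, 0, params$noise_sd)
    wet <- rbinom(n, 1L, 0.35)
    amount <- if (params$rain_mean > 0) {
      rexp(n, rate = 0.35 / params$rain_mean)
    } else {
      numeric(n)
    }
    list(noise = noise, rain = wet * amount)
  })

  tibble(
    year = year, doy = doy, month = md$month, day = md$day,
    tmin = params$base_tmin + seasonal + warming + draws$noise,
    tmax = params$base_tmax + seasonal + warming + draws$noise,
    eto = pmax(0, params$eto_base * (1 + 0.5 * phase)),
    rain = draws$rain
  ) |>
    structure(params = params)
}
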