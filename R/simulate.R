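#' Parameters of the toy crop-water simulator
#'
#' The toy simulator is a deliberately simple crop-water model used to
#' generate realistic-looking fixture data. It keeps the canonical AquaCrop
#' relations — biomass proportional to cumulative transpiration through the
#' normalized water productivity (B = WP* x sum(Tr)) and yield as a harvest
#' index fraction of biomass (Y = HI x B) — together with growing degree-day
#' (GDD) phenology and a binary temperature-stress rule, but replaces canopy
#' dynamics with a linear ramp and the soil with a single storage bucket.
#'
#' @param crop Crop label used in file prefixes (no underscores).
#' @param sowing_doy Sowing date as day-of-year in the 365-day calendar
#'   (default 131 = 11 May, the reference sowing date of the examples).
#' @param t_base Base temperature for GDD accumulation, degC. GDD uses the
#'   average method: `max(0, (tmax + tmin)/2 - t_base)`.
#' @param gdd_maturity Thermal time to maturity, degC day (> 0); the season
#'   ends when cumulative GDD reaches it.
#' @param max_cycle_days Hard cap on season length, days.
#' @param kc Crop coefficient scaling ETo to potential transpiration.
#' @param cc_max Maximum canopy cover, fraction in (0, 1].
#' @param cc_ramp_days Days over which canopy ramps linearly from 0 to
#'   `cc_max`, after which it holds.
#' @param wp_star Normalized biomass water productivity WP*, ton/ha per mm of
#'   transpired water (> 0).
#' @param hi Harvest index, fraction in (0, 1].
#' @param t_opt_low,t_opt_high Optimal temperature range for stomatal
#'   function, degC (default 9-30). On days whose mean temperature falls
#'   outside the range the stress coefficient Ks drops from 1 to 0.
#' @param storage_cap Root-zone water-holding capacity of the bucket, mm.
#' @param storage_init Root-zone storage at sowing, mm.
#' @param max_infiltration Daily infiltration cap, mm/day; rain above it runs
#'   off.
#' @return An object of class `toy_crop_params`.
#' @export
#' @examples
#' toy_crop_params(crop = "Maize")
toy_crop_params <- function(crop = "Maize", sowing_doy = 131L, t_base = 10,
                            gdd_maturity = 1300, max_cycle_days = 180L,
                            kc = 1.05, cc_max = 0.9, cc_ramp_days = 45L,
                            wp_star = 0.033, hi = 0.48,
                            t_opt_low = 9, t_opt_high = 30,
                            storage_cap = 150, storage_init = 100,
                            max_infiltration = 40) {
  p <- list(crop = crop, sowing_doy = as.integer(sowing_doy), t_base = t_base,
            gdd_maturity = gdd_maturity,
            max_cycle_days = as.integer(max_cycle_days), kc = kc,
            cc_max = cc_max, cc_ramp_days = as.integer(cc_ramp_days),
            wp_star = wp_star, hi = hi, t_opt_low = t_opt_low,
            t_opt_high = t_opt_high, storage_cap = storage_cap,
            storage_init = storage_init, max_infiltration = max_infiltration)
  bad <- function(field, what) abort_invalid("invalid `%s`: must be %s", field, what)
  if (!is.character(p$crop) || !nzchar(p$crop)) bad("crop", "a nonempty string")
  if (p$sowing_doy < 1 || p$sowing_doy > 365) bad("sowing_doy", "in 1..365")
  if (!(p$hi > 0 && p$hi <= 1)) bad("hi", "in (0, 1]")
  if (!(p$cc_max > 0 && p$cc_max <= 1)) bad("cc_max", "in (0, 1]")
  if (!(p$wp_star > 0)) bad("wp_star", "positive")
  if (!(p$t_opt_low < p$t_opt_high)) bad("t_opt_low", "below `t_opt_high`")
  if (!(p$gdd_maturity > 0)) bad("gdd_maturity", "positive")
  if (p$max_cycle_days < 1) bad("max_cycle_days", "at least 1")
  if (p$cc_ramp_days < 1) bad("cc_ramp_days", "at least 1")
  if (!(p$kc > 0)) bad("kc", "positive")
  if (!(p$storage_cap > 0)) bad("storage_cap", "positive")
  if (p$storage_init < 0 || p$storage_init > p$storage_cap) {
    bad("storage_init", "in [0, storage_cap]")
  }
  if (!(p$max_infiltration > 0)) bad("max_infiltration", "positive")
  structure(p, class = "toy_crop_params")
}

#' Simulate one toy crop season
#'
#' Runs the daily loop of the toy simulator for the season sown in `year`:
#'
#' * thermal time: `GDD_day = max(0, (tmax + tmin)/2 - t_base)`; the season
#'   ends on the day cumulative GDD reaches `gdd_maturity`, or at
#'   `max_cycle_days`, whichever comes first;
#' * canopy cover ramps linearly to `cc_max` over `cc_ramp_days`, then holds;
#' * temperature stress: `ks = 0` when the daily mean temperature is outside
#'   `[t_opt_low, t_opt_high]`, else 1; such days count as stress days;
#' * transpiration `tr = ks * kc * cc * eto`; soil evaporation
#'   `evap = (1 - cc) * 0.5 * eto`; both are scaled down pro rata when the
#'   storage bucket cannot supply them;
#' * water balance, closed exactly every day:
#'   `rain = evap + tr + runoff + drainage + (storage_t - storage_{t-1})`;
#' * production: `biomass = wp_star * sum(tr)`; `yield = hi * biomass`;
#'   `wp_et` converts yield per evapotranspired water to kg/m3.
#'
#' @param weather A weather series from [generate_weather()] covering the
#'   season (at least `max_cycle_days` days from the sowing date).
#' @param crop A [toy_crop_params()] object.
#' @param year Calendar year whose sowing date starts the season.
#' @return An object of class `simulated_season`: a list of seasonal scalars
#'   (`season_year`, `cycle_length`, `sum_tr`, `sum_et`, `biomass`, `yield`,
#'   `wp_et`, `stress_pct`, `gdd_total`, ...) plus `daily`, the day-by-day
#'   trace tibble.
#' @export
#' @examples
#' w <- generate_weather(weather_params(n_years = 1, noise_sd = 0))
#' s <- simulate_season(w, toy_crop_params(), 2010)
#' s$yield == s$biomass * 0.48
simulate_season <- function(weather, crop, year) {
  if (!inherits(crop, "toy_crop_params")) crop <- do.call(toy_crop_params, crop)
  i0 <- which(weather$year == year & weather$doy == crop$sowing_doy)
  if (length(i0) != 1) {
    abort_invalid("weather series has no sowing day %d in year %d",
                  crop$sowing_doy, year)
  }
  if (i0 + crop$max_cycle_days - 1L > nrow(weather)) {
    abort_invalid(
      "weather window from sowing (%d days) is shorter than max_cycle_days (%d)",
      nrow(weather) - i0 + 1L, crop$max_cycle_days)
  }

  n <- crop$max_cycle_days
  w <- weather[i0:(i0 + n - 1L), ]
  tmean <- (w$tmin + w$tmax) / 2
  gdd_day <- pmax(0, tmean - crop$t_base)
  gdd_cum <- cumsum(gdd_day)
  cycle <- which(gdd_cum >= crop$gdd_maturity)[1]
  if (is.na(cycle)) cycle <- n

  dap <- seq_len(cycle)
  cc <- crop$cc_max * pmin(1, dap / crop$cc_ramp_days)
  ks <- as.numeric(tmean[dap] >= crop$t_opt_low & tmean[dap] <= crop$t_opt_high)
  tr_pot <- ks * crop$kc * cc * w$eto[dap]
  evap_pot <- (1 - cc) * 0.5 * w$eto[dap]

  runoff <- pmax(0, w$rain[dap] - crop$max_infiltration)
  infil <- w$rain[dap] - runoff
  tr <- evap <- drain <- storage <- numeric(cycle)
  s_prev <- crop$storage_init
  for (d in dap) {
    avail <- s_prev + infil[d]
    demand <- tr_pot[d] + evap_pot[d]
    if (demand > avail) {
      # bucket empties: scale ET pro rata, keeping tr + evap == avail exactly
      tr[d] <- avail * tr_pot[d] / demand
      evap[d] <- avail - tr[d]
      after_et <- 0
    } else {
      tr[d] <- tr_pot[d]
      evap[d] <- evap_pot[d]
      after_et <- avail - tr[d] - evap[d]
    }
    drain[d] <- max(0, after_et - crop$storage_cap)
    storage[d] <- after_et - drain[d]
    s_prev <- storage[d]
  }

  daily <- tibble(
    year = w$year[dap], doy = w$doy[dap], month = w$month[dap],
    day = w$day[dap], dap = dap,
    tmin = w$tmin[dap], tmax = w$tmax[dap], tavg = tmean[dap],
    eto = w$eto[dap], rain = w$rain[dap],
    gdd_day = gdd_day[dap], gdd_cum = gdd_cum[dap],
    cc = cc, ks = ks, stress_day = ks < 1,
    tr = tr, tr_pot = crop$kc * cc * w$eto[dap], evap = evap,
    runoff = runoff, drainage = drain, infil = infil, storage = storage
  )

  sum_tr <- sum(tr)
  sum_evap <- sum(evap)
  sum_et <- sum_tr + sum_evap
  biomass <- crop$wp_star * sum_tr
  yield <- crop$hi * biomass
  stress_days <- sum(daily$stress_day)

  structure(list(
    season_year = year,
    sow_doy = crop$sowing_doy,
    harvest_doy = crop$sowing_doy + cycle - 1L,
    cycle_length = cycle,
    gdd_total = gdd_cum[cycle],
    sum_tr = sum_tr,
    sum_evap = sum_evap,
    sum_et = sum_et,
    sum_rain = sum(daily$rain),
    sum_eto = sum(daily$eto),
    sum_runoff = sum(runoff),
    sum_drain = sum(drain),
    sum_infil = sum(infil),
    storage_init = crop$storage_init,
    storage_end = storage[cycle],
    biomass = biomass,
    yield = yield,
    # ton/ha = 0.1 kg/m2; mm = 1e-3 m  =>  kg/m3 = 100 * (ton/ha) / mm
    wp_et = if (sum_et > 0) 100 * yield / sum_et else NA_real_,
    wp_tr = if (sum_tr > 0) 100 * yield / sum_tr else NA_real_,
    stress_days = stress_days,
    stress_pct = 100 * stress_days / cycle,
    ks_avg = mean(ks),
    cc_max_reached = max(cc),
    cc_avg = mean(cc),
    cc_end = cc[cycle],
    daily = daily,
    crop = crop
  ), class = "simulated_season")
}

#' @export
print.simulated_season <- function(x, ...) {
  cat(sprintf(
    "<simulated_season> %s %d: cycle %d d, GDD %.0f, Tr %.1f mm, B %.2f t/ha, Y %.2f t/ha, stress %.1f%%\n",
    x$crop$crop, x$season_year, x$cycle_length, x$gdd_total, x$sum_tr,
    x$biomass, x$yield, x$stress_pct))
  invisible(x)
}

#' Simulate every feasible season of a weather series
#'
#' One season per calendar year of the series, skipping years whose sowing
#' window (`max_cycle_days` from the sowing date) extends past the end of the
#' weather record.
#'
#' @inheritParams simulate_season
#' @param years Years to attempt; defaults to all years in `weather`.
#' @return A list of [simulate_season()] results.
#' @export
simulate_years <- function(weather, crop, years = NULL) {
  if (!inherits(crop, "toy_crop_params")) crop <- do.call(toy_crop_params, crop)
  years <- years %||% unique(weather$year)
  feasible <- years[vapply(years, function(y) {
    i0 <- which(weather$year == y & weather$doy == crop$sowing_doy)
    length(i0) == 1 && i0 + crop$max_cycle_days - 1L <= nrow(weather)
  }, logical(1))]
  map(feasible, ~ simulate_season(weather, crop, .x))
}
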