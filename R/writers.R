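#' File-set writers
#'
#' AquaCrop saves results either from its standard GUI program (10 output
#' files per simulation: a `.PRM` project file, eight daily files and the
#' seasonal `Run.OUT`) or from the stand-alone plug-in program (3 files: the
#' project file, `day.OUT` and `season.OUT`). These writers emit fixture file
#' sets in the same suffix conventions and in the package's documented text
#' dialect, from seasons produced by [simulate_season()].
#'
#' @name fileset-writers
NULL

# Master daily table for a list of seasons: keys + all daily variables.
daily_master <- function(seasons) {
  map(seq_along(seasons), function(i) {
    s <- seasons[[i]]
    d <- s$daily
    cap <- s$crop$storage_cap
    tibble(
      season_index = i,
      Day = d$day, Month = d$month, Year = d$year, DAP = d$dap,
      Stage = ifelse(d$dap <= s$crop$cc_ramp_days, 1, 2),
      Rain = d$rain, ETo = d$eto, Tmin = d$tmin, Tmax = d$tmax, Tavg = d$tavg,
      GDD = d$gdd_day, GDDcum = d$gdd_cum, CC = 100 * d$cc, Ks = d$ks,
      Tr = d$tr, Biomass = s$crop$wp_star * cumsum(d$tr),
      StressDay = as.numeric(d$stress_day),
      Evap = d$evap, ET = d$evap + d$tr, Runoff = d$runoff,
      Drain = d$drainage, Infilt = d$infil, Wr = d$storage,
      WrRel = 100 * d$storage / cap,
      Inet = 0,
      SaltZ = NA_real_, ECe = NA_real_,
      EC1 = NA_real_, EC2 = NA_real_, EC3 = NA_real_, EC4 = NA_real_,
      WC1 = d$storage / 4, WC2 = d$storage / 4,
      WC3 = d$storage / 4, WC4 = d$storage / 4
    )
  }) |> list_rbind()
}

daily_units_for <- function(cols) {
  sch <- daily_schema()
  all_units <- setNames(c(DAILY_KEY_UNITS, sch$unit), c(DAILY_KEY_COLS, sch$name))
  unname(all_units[cols])
}

# One 41-variable seasonal row per season (plus Run/Year keys).
seasonal_table <- function(seasons) {
  map(seq_along(seasons), function(i) {
    s <- seasons[[i]]
    tibble(
      Run = i, Year = s$season_year,
      Cycle = s$cycle_length, SowDay = s$sow_doy, HarvDay = s$harvest_doy,
      GDDtot = s$gdd_total, Rain = s$sum_rain, ETo = s$sum_eto,
      Tmin = mean(s$daily$tmin), Tmax = mean(s$daily$tmax),
      Tavg = mean(s$daily$tavg),
      Evap = s$sum_evap, Tr = s$sum_tr, ET = s$sum_et,
      Runoff = s$sum_runoff, Drain = s$sum_drain, Infilt = s$sum_infil,
      dStore = s$storage_end - s$storage_init,
      Wr0 = s$storage_init, WrEnd = s$storage_end,
      Irri = 0, Inet = 0,
      ECmean = NA_real_, SaltIn = NA_real_, SaltOut = NA_real_,
      SaltZ = NA_real_,
      StressSto = s$stress_pct, StressExp = 0, StressSen = 0,
      StressSal = NA_real_, StressFer = 0,
      KsAvg = s$ks_avg, StressDays = s$stress_days,
      CCmax = 100 * s$cc_max_reached, CCavg = 100 * s$cc_avg,
      CCend = 100 * s$cc_end,
      Biomass = s$biomass, Yield = s$yield, HI = 100 * s$crop$hi,
      WPet = s$wp_et, WPtr = s$wp_tr,
      BioDay = 1000 * s$biomass / s$cycle_length,
      TrPot = sum(s$daily$tr_pot)
    )
  }) |> list_rbind()
}

seasonal_units <- function() {
  sch <- seasonal_schema()
  c(SEASONAL_KEY_UNITS, sch$unit)
}

check_prefix <- function(prefix) {
  if (!is.character(prefix) || length(prefix) != 1 || !nzchar(prefix)) {
    abort_invalid("`prefix` must be a nonempty string")
  }
}

as_season_list <- function(season_runs) {
  if (inherits(season_runs, "simulated_season")) season_runs <- list(season_runs)
  if (!length(season_runs) ||
      !all(map_lgl(season_runs, inherits, "simulated_season"))) {
    abort_invalid("`season_runs` must be one or more simulated seasons")
  }
  season_runs
}

write_project_file <- function(path, seasons, prefix, mode, soil_horizons) {
  crop <- seasons[[1]]$crop
  first <- seasons[[1]]
  last <- seasons[[length(seasons)]]
  lines <- c(
    sprintf("aquabatch project file - %s", prefix),
    "",
    sprintf("Mode           : %s", mode),
    sprintf("Seasons        : %d", length(seasons)),
    sprintf("PeriodStart    : %d-%03d", first$season_year, first$sow_doy),
    sprintf("PeriodEnd      : %d-%03d", last$season_year, last$harvest_doy),
    sprintf("SoilHorizons   : %d", soil_horizons),
    sprintf("ClimateFile    : %s.CLI", prefix),
    sprintf("CropFile       : %s.CRO", crop$crop),
    "SoilFile       : Loam.SOL",
    "ManagementFile : Default.MAN",
    sprintf("SowingDay      : %d", crop$sowing_doy),
    sprintf("Tbase          : %.2f", crop$t_base),
    sprintf("GDDmaturity    : %.2f", crop$gdd_maturity),
    sprintf("MaxCycleDays   : %d", crop$max_cycle_days),
    sprintf("Kc             : %.2f", crop$kc),
    sprintf("CCmax          : %.2f", crop$cc_max),
    sprintf("CCrampDays     : %d", crop$cc_ramp_days),
    sprintf("WPstar         : %.4f", crop$wp_star),
    sprintf("HI             : %.2f", crop$hi),
    sprintf("ToptLow        : %.2f", crop$t_opt_low),
    sprintf("ToptHigh       : %.2f", crop$t_opt_high)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

new_runset <- function(prefix, mode, files, unmatched = character(0)) {
  structure(list(prefix = prefix, mode = mode, files = files,
                 unmatched = unmatched),
            class = "runset")
}

#' @export
print.runset <- function(x, ...) {
  cat(sprintf("<runset> %s [%s]: %d file(s): %s\n", x$prefix, x$mode,
              length(x$files), paste(names(x$files), collapse = ", ")))
  invisible(x)
}

#' Write a GUI-mode (10-file) output set
#'
#' Writes the project file plus the eight daily files and the seasonal
#' `Run.OUT` of the standard GUI program, all named `prefix + suffix`. Daily
#' variables are partitioned over files by category: climate to `Clim.OUT`,
#' crop development/production to `Crop.OUT`, the water balance to
#' `Wabal.OUT`, net irrigation to `Inet.OUT`, profile water to `Prof.OUT`,
#' salinity to `Salt.OUT`/`CompEC.OUT` and layer water contents to
#' `CompWC.OUT`. Salinity is not simulated, so its cells hold the `-9.00`
#' sentinel.
#'
#' @param season_runs One [simulate_season()] result or a list of them.
#' @param out_dir Output directory (created if needed).
#' @param prefix Nonempty file-name prefix; underscore-separated segments act
#'   as extractable metadata downstream.
#' @param soil_horizons Number of soil horizons recorded in the project file
#'   (1-5).
#' @return A `runset` object mapping file kinds to the 10 written paths.
#' @export
write_gui_fileset <- function(season_runs, out_dir, prefix, soil_horizons = 3L) {
  check_prefix(prefix)
  seasons <- as_season_list(season_runs)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    abort(sprintf("cannot create output directory %s", out_dir),
          class = "aquabatch_io")
  }
  master <- daily_master(seasons)
  files <- character(0)
  for (kind in names(GUI_DAILY_VARS)) {
    cols <- c(DAILY_KEY_COLS, GUI_DAILY_VARS[[kind]])
    path <- file.path(out_dir, paste0(prefix, GUI_SUFFIXES[[kind]]))
    write_dialect_file(path,
                       sprintf("aquabatch daily output (%s) - %s", kind, prefix),
                       df = master[cols], units = daily_units_for(cols))
    files[[kind]] <- path
  }
  run_path <- file.path(out_dir, paste0(prefix, GUI_SUFFIXES[["run"]]))
  write_dialect_file(run_path,
                     sprintf("aquabatch seasonal output - %s", prefix),
                     df = seasonal_table(seasons), units = seasonal_units())
  files[["run"]] <- run_path
  prm_path <- file.path(out_dir, paste0(prefix, GUI_SUFFIXES[["prm"]]))
  write_project_file(prm_path, seasons, prefix, "gui", soil_horizons)
  files[["prm"]] <- prm_path
  new_runset(prefix, "gui", files)
}

#' Write a plug-in-mode (3-file) output set
#'
#' Writes the stand-alone plug-in program's file set: the project file
#' (`.PRM` for a multi-simulation project, `.PRO` when a single season is
#' written), `day.OUT` with one `Run: N` block per season carrying the union
#' of all daily variables, and `season.OUT` with one 41-variable summary row
#' per season.
#'
#' @inheritParams write_gui_fileset
#' @return A `runset` object mapping the 3 file kinds to paths.
#' @export
write_plugin_fileset <- function(season_runs, out_dir, prefix,
                                 soil_horizons = 3L) {
  check_prefix(prefix)
  seasons <- as_season_list(season_runs)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    abort(sprintf("cannot create output directory %s", out_dir),
          class = "aquabatch_io")
  }
  single <- length(seasons) == 1L
  master <- daily_master(seasons)
  cols <- c(DAILY_KEY_COLS, daily_schema()$name)
  blocks <- map(seq_along(seasons),
                ~ master[master$season_index == .x, cols])
  files <- character(0)

  day_path <- file.path(out_dir, paste0(prefix, PLUGIN_SUFFIXES[["day"]]))
  write_dialect_file(day_path,
                     sprintf("aquabatch daily output - %s", prefix),
                     units = daily_units_for(cols), blocks = blocks)
  files[["day"]] <- day_path

  season_path <- file.path(out_dir, paste0(prefix, PLUGIN_SUFFIXES[["season"]]))
  write_dialect_file(season_path,
                     sprintf("aquabatch seasonal output - %s", prefix),
                     df = seasonal_table(seasons), units = seasonal_units())
  files[["season"]] <- season_path

  proj_kind <- if (single) "pro" else "prm"
  proj_path <- file.path(out_dir, paste0(prefix, PLUGIN_SUFFIXES[[proj_kind]]))
  write_project_file(proj_path, seasons, prefix, "plugin", soil_horizons)
  files[[proj_kind]] <- proj_path
  new_runset(prefix, "plugin", files)
}
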