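#' Discover and match output files into simulation runs
#'
#' All output files of one AquaCrop simulation share a file-name prefix; the
#' part after the prefix is a registered suffix identifying the file kind
#' (GUI mode: `.PRM`, `Clim.OUT`, `CompEC.OUT`, `CompWC.OUT`, `Crop.OUT`,
#' `Inet.OUT`, `Prof.OUT`, `Salt.OUT`, `Wabal.OUT`, `Run.OUT`; plug-in mode:
#' `.PRM`, `.PRO`, `day.OUT`, `season.OUT`). Files are assigned to kinds by
#' longest registered suffix match and grouped by prefix into runs. Partial
#' file sets are allowed (with a warning); paths with no registered suffix
#' are collected, not dropped. The result is independent of the order of
#' `paths`.
#'
#' @param paths Character vector of file paths (>= 1).
#' @param mode `"gui"`, `"plugin"`, or `NULL` (default) to infer per run from
#'   the suffixes present.
#' @return A list of `runset` objects sorted by prefix, with the unassigned
#'   paths in attribute `"unmatched"` (also via [unmatched_paths()]).
#' @export
#' @examples
#' d <- tempfile(); dir.create(d)
#' w <- generate_weather(weather_params(n_years = 1))
#' s <- simulate_season(w, toy_crop_params(), 2010)
#' write_plugin_fileset(s, d, "Maize_Soroca")
#' discover_runs(list.files(d, full.names = TRUE))
discover_runs <- function(paths, mode = NULL) {
  if (!length(paths)) abort_invalid("`paths` must contain at least one path")
  if (!is.null(mode) && !mode %in% c("gui", "plugin")) {
    abort_invalid("`mode` must be \"gui\" or \"plugin\", not \"%s\"", mode)
  }
  sfx <- registered_suffixes(mode)
  base <- basename(paths)
  kinds <- character(length(paths))
  prefixes <- character(length(paths))
  for (i in seq_along(paths)) {
    hit <- NA_character_
    for (k in names(sfx)) {
      s <- sfx[[k]]
      if (endsWith(base[i], s) && nchar(base[i]) > nchar(s)) {
        hit <- k
        prefixes[i] <- substr(base[i], 1L, nchar(base[i]) - nchar(s))
        break
      }
    }
    kinds[i] <- hit
  }
  unmatched <- paths[is.na(kinds)]
  matched <- which(!is.na(kinds))

  gui_only <- setdiff(names(GUI_SUFFIXES), "prm")
  plugin_only <- setdiff(names(PLUGIN_SUFFIXES), "prm")

  runs <- list()
  for (p in sort(unique(prefixes[matched]))) {
    idx <- matched[prefixes[matched] == p]
    kk <- kinds[idx]
    if (anyDuplicated(kk)) {
      abort_invalid("prefix \"%s\": multiple files of kind %s", p,
                    paste(unique(kk[duplicated(kk)]), collapse = ", "))
    }
    has_gui <- any(kk %in% gui_only)
    has_plugin <- any(kk %in% plugin_only)
    if (has_gui && has_plugin) {
      abort_invalid(
        "prefix \"%s\" matches both GUI-only and plug-in-only suffixes", p)
    }
    run_mode <- mode %||% if (has_gui) "gui" else "plugin"
    expected <- names(registered_suffixes(run_mode))
    if (run_mode == "plugin") {
      # a project is .PRM or .PRO, never both required
      expected <- setdiff(expected, if ("pro" %in% kk) "prm" else "pro")
    }
    missing <- setdiff(expected, kk)
    if (length(missing)) {
      warn(sprintf("run \"%s\": %d of %d %s file kinds absent (%s)", p,
                   length(missing), length(expected), run_mode,
                   paste(missing, collapse = ", ")),
           class = "aquabatch_partial_run")
    }
    files <- setNames(paths[idx], kk)[order(kk)]
    runs[[p]] <- new_runset(p, run_mode, files)
  }
  structure(unname(runs), unmatched = unmatched)
}

#' @rdname discover_runs
#' @param runs The result of [discover_runs()].
#' @export
unmatched_paths <- function(runs) attr(runs, "unmatched") %||% character(0)

#' Extract metadata tokens from a run prefix
#'
#' By convention each metadata variable in a file-name prefix is separated by
#' an underscore (e.g. `Maize_Soroca_RCP26` encodes crop, location and
#' scenario). The prefix is split on `_`; with `token_names` the tokens are
#' mapped positionally onto those names, otherwise they are auto-named
#' `token1..tokenN`.
#'
#' @param prefix Nonempty run prefix.
#' @param token_names Optional character vector naming every token in order.
#' @return A list with `run_id` (the prefix), `tokens` (character vector) and
#'   `fields` (named list of token values).
#' @export
#' @examples
#' extract_metadata("Maize_Soroca_RCP26", c("crop", "location", "scenario"))
extract_metadata <- function(prefix, token_names = NULL) {
  if (!is.character(prefix) || length(prefix) != 1 || !nzchar(prefix)) {
    abort_invalid("`prefix` must be a nonempty string")
  }
  tokens <- str_split(prefix, "_")[[1]]
  if (is.null(token_names)) {
    token_names <- paste0("token", seq_along(tokens))
  } else if (length(token_names) != length(tokens)) {
    abort_invalid(
      "prefix \"%s\" has %d token(s) but %d name(s) were supplied",
      prefix, length(tokens), length(token_names))
  }
  list(run_id = prefix, tokens = tokens,
       fields = setNames(as.list(tokens), token_names))
}

# ---------------------------------------------------------------------------

parse_period <- function(value, key, path, line) {
  m <- regmatches(value, regexec("^(\\d{4})-(\\d{1,3})$", value))[[1]]
  if (!length(m)) {
    abort_parse("%s: line %d: %s \"%s\" is not in YYYY-DOY form",
                path, line, key, value)
  }
  list(year = as.integer(m[2]), doy = as.integer(m[3]))
}

#' Read a project file
#'
#' Parses a `.PRM` (multi-simulation) or `.PRO` (single-simulation) project
#' file: growing/simulation period, referenced input file names, soil-horizon
#' count (at most five horizons are supported) and parameter settings.
#' Unknown keys are preserved verbatim in `settings`.
#'
#' @param path Path to a project file in the package dialect.
#' @return An object of class `project_record`: `run_id`, `mode`,
#'   `n_seasons`, `period_start`/`period_end` (lists of `year`, `doy`),
#'   `soil_horizons`, `input_files` (named list) and `settings` (named list,
#'   numeric where possible).
#' @export
read_project <- function(path) {
  if (!file.exists(path)) abort_parse("file not found: %s", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  kv_idx <- grep("^\\s*[A-Za-z][A-Za-z0-9]*\\s*:", lines)
  keys <- str_trim(sub(":.*$", "", lines[kv_idx]))
  values <- str_trim(sub("^[^:]*:", "", lines[kv_idx]))
  named <- setNames(as.list(values), keys)
  line_of <- function(key) kv_idx[match(key, keys)]

  for (k in c("PeriodStart", "PeriodEnd")) {
    if (!k %in% keys) {
      abort_parse("%s: mandatory key %s missing (scanned %d lines)",
                  path, k, length(lines))
    }
  }
  period_start <- parse_period(named$PeriodStart, "PeriodStart", path,
                               line_of("PeriodStart"))
  period_end <- parse_period(named$PeriodEnd, "PeriodEnd", path,
                             line_of("PeriodEnd"))
  if (period_end$year * 365L + period_end$doy <
      period_start$year * 365L + period_start$doy) {
    abort_invalid("%s: PeriodEnd precedes PeriodStart", path)
  }
  soil_horizons <- if ("SoilHorizons" %in% keys) {
    as.integer(named$SoilHorizons)
  } else {
    NA_integer_
  }
  if (!is.na(soil_horizons) && (soil_horizons < 1 || soil_horizons > 5)) {
    abort_invalid(
      "%s: SoilHorizons is %d; AquaCrop profiles have 1 to 5 horizons",
      path, soil_horizons)
  }
  file_keys <- c(climate = "ClimateFile", crop = "CropFile", soil = "SoilFile",
                 management = "ManagementFile")
  input_files <- compact(map(file_keys, ~ named[[.x]]))

  setting_keys <- setdiff(keys, c("PeriodStart", "PeriodEnd", "SoilHorizons",
                                  file_keys, "Mode", "Seasons"))
  settings <- map(named[setting_keys], function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })

  prefix <- basename(path)
  prefix <- sub("\\.(PRM|PRO)$", "", prefix)
  structure(list(
    run_id = prefix,
    mode = named$Mode %||% NA_character_,
    n_seasons = if (!is.null(named$Seasons)) as.integer(named$Seasons) else NA_integer_,
    period_start = period_start,
    period_end = period_end,
    soil_horizons = soil_horizons,
    input_files = input_files,
    settings = settings
  ), class = "project_record")
}

#' @export
print.project_record <- function(x, ...) {
  cat(sprintf("<project_record> %s: %s seasons, %d-%03d to %d-%03d, %s horizons\n",
              x$run_id, x$n_seasons, x$period_start$year, x$period_start$doy,
              x$period_end$year, x$period_end$doy, x$soil_horizons))
  invisible(x)
}

new_fragment <- function(data, kind, dataset_class, units) {
  structure(data, kind = kind, dataset_class = dataset_class, units = units,
            class = c("table_fragment", class(data)))
}

#' Read a daily results file
#'
#' Header-driven parse of any daily output file: column names come from the
#' name header line and units from the units line, so version-to-version
#' column differences are absorbed. Plug-in `day.OUT` files are split on
#' their `Run: N` block headers into seasons; in GUI daily files the season
#' index is inferred from `DAP` resetting to 1. The `-9.00` sentinel becomes
#' `NA`.
#'
#' @param path Path to the file.
#' @param kind Registered daily kind: one of `"clim"`, `"compec"`,
#'   `"compwc"`, `"crop"`, `"inet"`, `"prof"`, `"salt"`, `"wabal"`, `"day"`.
#' @return A tibble (`table_fragment`) with `season_index`, the lowercased
#'   key columns (`day`, `month`, `year`, `doy`, `dap`, `stage`) and the
#'   file's variable columns; units in `attr(, "units")`,
#'   `attr(, "dataset_class") == "daily"`.
#' @export
read_daily <- function(path, kind) {
  if (!kind %in% DAILY_KINDS) {
    abort_invalid("`kind` \"%s\" is not a registered daily kind (%s)", kind,
                  paste(DAILY_KINDS, collapse = ", "))
  }
  blocks <- read_dialect_file(path)
  units <- blocks[[1]]$units
  out <- map(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    d <- b$data
    d$season_index <- if (!is.na(b$run)) b$run else NA_integer_
    d
  }) |> list_rbind()
  if (all(is.na(out$season_index)) && nrow(out)) {
    if ("DAP" %in% names(out)) {
      out$season_index <- cumsum(out$DAP == 1)
    } else {
      out$season_index <- 1L
    }
  }
  if ("Day" %in% names(out) && "Month" %in% names(out)) {
    out$doy <- md_to_doy(as.integer(out$Month), as.integer(out$Day))
  }
  names(out)[names(out) %in% DAILY_KEY_COLS] <-
    tolower(names(out)[names(out) %in% DAILY_KEY_COLS])
  key <- intersect(c("season_index", "day", "month", "year", "doy", "dap",
                     "stage"), names(out))
  out <- out[c(key, setdiff(names(out), key))]
  new_fragment(out, kind, "daily", units)
}

#' Read a seasonal results file
#'
#' Parses `Run.OUT` (GUI) or `season.OUT` (plug-in): one row per simulated
#' season, keyed by run number and year, carrying the seasonal summary
#' variables (41 in fixture-written files).
#'
#' @param path Path to the file.
#' @return A tibble (`table_fragment`) with `season_index`, `year` and the
#'   variable columns; `attr(, "dataset_class") == "seasonal"`.
#' @export
read_seasonal <- function(path) {
  blocks <- read_dialect_file(path)
  b <- blocks[[1]]
  d <- b$data
  if ("Run" %in% names(d)) {
    if (anyDuplicated(d$Run)) {
      abort_parse("%s: duplicate season key Run=%s", path,
                  d$Run[duplicated(d$Run)][1])
    }
    d$season_index <- as.integer(d$Run)
    d$Run <- NULL
  } else {
    d$season_index <- seq_len(nrow(d))
  }
  names(d)[names(d) == "Year"] <- "year"
  key <- intersect(c("season_index", "year"), names(d))
  d <- d[c(key, setdiff(names(d), key))]
  new_fragment(d, "seasonal", "seasonal", b$units)
}
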