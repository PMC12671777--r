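#' Combine parsed runs into tidy project, seasonal and daily tables
#'
#' Reads every file of every run and assembles one clean table per dataset
#' class — project, seasonal and daily — with the run's metadata (its
#' `run_id` and the underscore-delimited filename tokens) as leading columns
#' on every row. Within a run, the daily fragments from different files are
#' merged on their day keys (the first file's copy wins for variables that
#' appear in several files, in registry order); across runs, fragments of the
#' same class are concatenated, with variables missing in some runs becoming
#' `NA`.
#'
#' @param runsets A list of `runset` objects from [discover_runs()],
#'   [generate_study()] or the writers.
#' @param token_names Optional names for the prefix metadata tokens; all
#'   prefixes must then have that token count. Without names, tokens are
#'   auto-named `token1..tokenN` (and all prefixes must agree on N).
#' @return An object of class `combined_data`: a list with tibbles `project`,
#'   `seasonal`, `daily` and the character vector `provenance` of every file
#'   read.
#' @export
#' @examples
#' d <- tempfile(); dir.create(d)
#' w <- generate_weather(weather_params(n_years = 2))
#' s <- simulate_years(w, toy_crop_params())
#' rs <- write_plugin_fileset(s, d, "Maize_Soroca_RCP26")
#' cd <- combine_runs(list(rs), c("crop", "location", "scenario"))
#' cd$seasonal
combine_runs <- function(runsets, token_names = NULL) {
  if (inherits(runsets, "runset")) runsets <- list(runsets)
  if (!length(runsets)) abort_invalid("`runsets` must contain at least one run")
  prefixes <- map_chr(runsets, "prefix")
  if (anyDuplicated(prefixes)) {
    abort_invalid("duplicate run prefix(es): %s",
                  paste(unique(prefixes[duplicated(prefixes)]), collapse = ", "))
  }
  counts <- map_int(prefixes, ~ length(str_split(.x, "_")[[1]]))
  want <- if (is.null(token_names)) max(counts) else length(token_names)
  if (any(counts != want)) {
    abort_invalid("inconsistent metadata token counts (expected %d): %s",
                  want,
                  paste(sprintf("%s (%d)", prefixes[counts != want],
                                counts[counts != want]), collapse = ", "))
  }

  meta_row <- function(prefix) {
    md <- extract_metadata(prefix, token_names)
    as_tibble(c(list(run_id = md$run_id), md$fields))
  }

  project_rows <- list()
  seasonal_rows <- list()
  daily_rows <- list()
  provenance <- character(0)

  for (rs in runsets) {
    meta <- meta_row(rs$prefix)
    provenance <- c(provenance, unname(rs$files))

    proj_kind <- intersect(names(rs$files), PROJECT_KINDS)
    if (length(proj_kind)) {
      pr <- read_project(rs$files[[proj_kind[1]]])
      row <- tibble(
        n_seasons = pr$n_seasons,
        period_start_year = pr$period_start$year,
        period_start_doy = pr$period_start$doy,
        period_end_year = pr$period_end$year,
        period_end_doy = pr$period_end$doy,
        soil_horizons = pr$soil_horizons
      )
      for (nm in names(pr$input_files)) row[[paste0(nm, "_file")]] <- pr$input_files[[nm]]
      for (nm in names(pr$settings)) {
        v <- pr$settings[[nm]]
        if (is.numeric(v)) row[[nm]] <- v
      }
      project_rows[[rs$prefix]] <- bind_cols(meta, row)
    }

    seas_kind <- intersect(names(rs$files), SEASONAL_KINDS)
    if (length(seas_kind)) {
      frag <- read_seasonal(rs$files[[seas_kind[1]]])
      seasonal_rows[[rs$prefix]] <- bind_cols(meta[rep(1, nrow(frag)), ],
                                              as_tibble(frag))
    }

    day_kinds <- intersect(c(names(GUI_DAILY_VARS), "day"), names(rs$files))
    if (length(day_kinds)) {
      merged <- NULL
      keys <- c("season_index", "day", "month", "year", "doy", "dap", "stage")
      for (k in day_kinds) {
        frag <- as_tibble(read_daily(rs$files[[k]], k))
        if (is.null(merged)) {
          merged <- frag
        } else {
          new_vars <- setdiff(names(frag), names(merged))
          merged <- left_join(merged, frag[c(intersect(keys, names(frag)),
                                             new_vars)],
                              by = intersect(keys, names(frag)))
        }
      }
      daily_rows[[rs$prefix]] <- bind_cols(meta[rep(1, nrow(merged)), ],
                                           merged)
    }
  }

  structure(list(
    project = bind_rows(project_rows),
    seasonal = bind_rows(seasonal_rows),
    daily = bind_rows(daily_rows),
    provenance = provenance
  ), class = "combined_data")
}

#' @export
print.combined_data <- function(x, ...) {
  cat(sprintf("<combined_data> project %d x %d, seasonal %d x %d, daily %d x %d (%d files)\n",
              nrow(x$project), ncol(x$project), nrow(x$seasonal),
              ncol(x$seasonal), nrow(x$daily), ncol(x$daily),
              length(x$provenance)))
  invisible(x)
}

FILTER_OPS <- c("==", "!=", "<", "<=", ">", ">=", "in")

#' Filter rows of a combined table
#'
#' Keeps the rows satisfying the conjunction of simple conditions, each a
#' `list(var, op, value)` with `op` one of `==`, `!=`, `<`, `<=`, `>`, `>=`,
#' `in`. Comparisons against `NA` never match. The input table is not
#' modified.
#'
#' @param table A data frame.
#' @param filters One condition, or a list of conditions.
#' @return The filtered tibble.
#' @export
#' @examples
#' tb <- tibble::tibble(scenario = c("RCP26", "RCP85"), yield = c(5, 4))
#' filter_rows(tb, list(var = "scenario", op = "==", value = "RCP85"))
filter_rows <- function(table, filters) {
  if (!is.null(filters$var)) filters <- list(filters)
  keep <- rep(TRUE, nrow(table))
  for (f in filters) {
    if (is.null(f$var) || is.null(f$op)) {
      abort_invalid("each filter needs `var`, `op` and `value`")
    }
    if (!f$op %in% FILTER_OPS) {
      abort_invalid("unknown comparator \"%s\" (use %s)", f$op,
                    paste(FILTER_OPS, collapse = ", "))
    }
    if (!f$var %in% names(table)) {
      abort_invalid("unknown column \"%s\"", f$var)
    }
    x <- table[[f$var]]
    hit <- switch(f$op,
      "in" = x %in% f$value,
      do.call(f$op, list(x, f$value))
    )
    hit[is.na(hit)] <- FALSE
    keep <- keep & hit
  }
  as_tibble(table[keep, , drop = FALSE])
}

#' Rename a variable column
#'
#' Only the header changes; values are untouched.
#'
#' @param table A data frame.
#' @param old Existing column name.
#' @param new New column name; must not collide with an existing one.
#' @return The table with the column renamed.
#' @export
rename_variable <- function(table, old, new) {
  if (!old %in% names(table)) abort_invalid("unknown column \"%s\"", old)
  if (new %in% names(table)) {
    abort_invalid("cannot rename \"%s\" to \"%s\": column already exists",
                  old, new)
  }
  names(table)[names(table) == old] <- new
  table
}

#' Export a table to CSV
#'
#' RFC 4180 CSV with a header row; missing values are written as empty
#' fields, and labels containing commas or quotes are quoted, so the file
#' round-trips through [readr::read_csv()].
#'
#' @param table A data frame.
#' @param path Output path.
#' @param format Only `"csv"` is supported.
#' @return The path, invisibly.
#' @export
export_table <- function(table, path, format = "csv") {
  if (!identical(format, "csv")) {
    abort_invalid("unsupported export format \"%s\"", format)
  }
  write_csv(as_tibble(table), path, na = "")
  invisible(path)
}
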