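#' The aquabatch output-file dialect
#'
#' AquaCrop stores simulation results as whitespace-aligned text tables. The
#' exact byte layout of the engine's files varies between versions, so this
#' package defines one normative dialect that its writers emit and its readers
#' accept:
#'
#' * line 1: a free-text title/comment line;
#' * line 2: blank;
#' * per block (plug-in `day.OUT` carries one block per season, introduced by
#'   a `Run: N` line; all other files hold a single block): one header line of
#'   variable names, one header line of units (`-` for dimensionless), then
#'   numeric rows printed with two decimals;
#' * daily files lead with `Day Month Year DAP Stage`, seasonal files with
#'   `Run Year`;
#' * undefined cells (e.g. salinity variables when salinity is not simulated)
#'   hold the sentinel `-9.00`, which readers surface as `NA`;
#' * years are 365 days long — the fixture calendar has no leap days.
#'
#' @name aquabatch-dialect
#' @keywords internal
NULL

# Sentinel written for undefined cells; readers convert it to NA.
DIALECT_SENTINEL <- -9

MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

# Day-of-year (1..365) -> month and day-of-month in the 365-day calendar.
doy_to_md <- function(doy) {
  ends <- cumsum(MONTH_LENGTHS)
  month <- findInterval(doy - 1L, c(0L, ends[-12L]))
  day <- doy - c(0L, ends)[month]
  list(month = as.integer(month), day = as.integer(day))
}

md_to_doy <- function(month, day) {
  starts <- c(0L, cumsum(MONTH_LENGTHS))[seq_len(12L)]
  as.integer(starts[month] + day)
}

# ---------------------------------------------------------------------------
# File-kind registry: suffix conventions of the two AquaCrop output modes.

GUI_SUFFIXES <- c(
  prm    = ".PRM",
  clim   = "Clim.OUT",
  compec = "CompEC.OUT",
  compwc = "CompWC.OUT",
  crop   = "Crop.OUT",
  inet   = "Inet.OUT",
  prof   = "Prof.OUT",
  salt   = "Salt.OUT",
  wabal  = "Wabal.OUT",
  run    = "Run.OUT"
)

PLUGIN_SUFFIXES <- c(
  prm    = ".PRM",
  pro    = ".PRO",
  day    = "day.OUT",
  season = "season.OUT"
)

DAILY_KINDS <- c("clim", "compec", "compwc", "crop", "inet", "prof", "salt",
                 "wabal", "day")
SEASONAL_KINDS <- c("run", "season")
PROJECT_KINDS <- c("prm", "pro")

# Registered suffixes for a mode ("gui", "plugin", or NULL for the union),
# ordered longest-first so that e.g. "...day.OUT" never shadows "...Wabal.OUT"
# and a prefix ending in "day" cannot swallow the "day.OUT" suffix.
registered_suffixes <- function(mode = NULL) {
  sfx <- switch(
    mode %||% "all",
    gui = GUI_SUFFIXES,
    plugin = PLUGIN_SUFFIXES,
    all = c(GUI_SUFFIXES, PLUGIN_SUFFIXES[c("pro", "day", "season")])
  )
  if (is.null(sfx)) {
    abort_invalid("`mode` must be \"gui\" or \"plugin\", not \"%s\"", mode)
  }
  sfx[order(nchar(sfx), decreasing = TRUE)]
}

# ---------------------------------------------------------------------------
# Canonical variable catalogues.

DAILY_KEY_COLS <- c("Day", "Month", "Year", "DAP", "Stage")
DAILY_KEY_UNITS <- c("-", "-", "-", "days", "-")
SEASONAL_KEY_COLS <- c("Run", "Year")
SEASONAL_KEY_UNITS <- c("-", "-")

# Daily variables and units, in master order.
daily_schema <- function() {
  tibble(
    name = c("Rain", "ETo", "Tmin", "Tmax", "Tavg",
             "GDD", "GDDcum", "CC", "Ks", "Tr", "Biomass", "StressDay",
             "Evap", "ET", "Runoff", "Drain", "Infilt", "Wr", "WrRel",
             "Inet",
             "SaltZ", "ECe", "EC1", "EC2", "EC3", "EC4",
             "WC1", "WC2", "WC3", "WC4"),
    unit = c("mm", "mm", "degC", "degC", "degC",
             "degC.day", "degC.day", "%", "-", "mm", "ton/ha", "-",
             "mm", "mm", "mm", "mm", "mm", "mm", "%",
             "mm",
             "ton/ha", "dS/m", "dS/m", "dS/m", "dS/m", "dS/m",
             "mm", "mm", "mm", "mm")
  )
}

# Partition of the daily variables over the GUI daily files; plug-in day.OUT
# carries the union.
GUI_DAILY_VARS <- list(
  clim   = c("Rain", "ETo", "Tmin", "Tmax", "Tavg"),
  crop   = c("GDD", "GDDcum", "CC", "Ks", "Tr", "Biomass", "StressDay"),
  wabal  = c("Rain", "Evap", "Tr", "ET", "Runoff", "Drain", "Infilt", "Wr"),
  inet   = "Inet",
  prof   = c("Wr", "WrRel"),
  salt   = c("SaltZ", "ECe"),
  compec = c("EC1", "EC2", "EC3", "EC4"),
  compwc = c("WC1", "WC2", "WC3", "WC4")
)

#' Canonical seasonal output schema
#'
#' The 41 seasonal variables written to `Run.OUT` / `season.OUT`, one row per
#' simulated season, after the `Run` and `Year` key columns. The set spans the
#' categories AquaCrop summarises for a season: simulation-period lengths and
#' dates, climatic totals, the soil-water balance, soil-salinity placeholders,
#' average stresses, and final production (biomass, yield, water
#' productivity). Real AquaCrop column names differ between engine versions;
#' this catalogue is normative for the package's own dialect.
#'
#' @return A tibble with columns `name`, `unit`, `category` (41 rows).
#' @export
#' @examples
#' seasonal_schema()
seasonal_schema <- function() {
  tribble(
    ~name,         ~unit,        ~category,
    "Cycle",       "days",       "period",
    "SowDay",      "doy",        "period",
    "HarvDay",     "doy",        "period",
    "GDDtot",      "degC.day",   "climatic",
    "Rain",        "mm",         "climatic",
    "ETo",         "mm",         "climatic",
    "Tmin",        "degC",       "climatic",
    "Tmax",        "degC",       "climatic",
    "Tavg",        "degC",       "climatic",
    "Evap",        "mm",         "soil_water",
    "Tr",          "mm",         "soil_water",
    "ET",          "mm",         "soil_water",
    "Runoff",      "mm",         "soil_water",
    "Drain",       "mm",         "soil_water",
    "Infilt",      "mm",         "soil_water",
    "dStore",      "mm",         "soil_water",
    "Wr0",         "mm",         "soil_water",
    "WrEnd",       "mm",         "soil_water",
    "Irri",        "mm",         "soil_water",
    "Inet",        "mm",         "soil_water",
    "ECmean",      "dS/m",       "soil_salinity",
    "SaltIn",      "ton/ha",     "soil_salinity",
    "SaltOut",     "ton/ha",     "soil_salinity",
    "SaltZ",       "ton/ha",     "soil_salinity",
    "StressSto",   "%",          "stresses",
    "StressExp",   "%",          "stresses",
    "StressSen",   "%",          "stresses",
    "StressSal",   "%",          "stresses",
    "StressFer",   "%",          "stresses",
    "KsAvg",       "-",          "stresses",
    "StressDays",  "days",       "stresses",
    "CCmax",       "%",          "production",
    "CCavg",       "%",          "production",
    "CCend",       "%",          "production",
    "Biomass",     "ton/ha",     "production",
    "Yield",       "ton/ha",     "production",
    "HI",          "%",          "production",
    "WPet",        "kg/m3",      "production",
    "WPtr",        "kg/m3",      "production",
    "BioDay",      "kg/ha/day",  "production",
    "TrPot",       "mm",         "production"
  )
}

# ---------------------------------------------------------------------------
# Fixed-width block writer.

INT_COLS <- c("Day", "Month", "Year", "DAP", "Stage", "Run", "StressDay",
              "SowDay", "HarvDay", "Cycle", "StressDays")

format_column <- function(x, name) {
  miss <- is.na(x)
  x[miss] <- 0
  out <- if (name %in% INT_COLS) {
    sprintf("%d", as.integer(round(x)))
  } else {
    sprintf("%.2f", x)
  }
  out[miss] <- sprintf("%.2f", DIALECT_SENTINEL)
  out
}

# Render a data frame as aligned text lines: names line, units line, rows.
format_block <- function(df, units) {
  stopifnot(ncol(df) == length(units))
  cells <- map(seq_along(df), function(j) format_column(df[[j]], names(df)[j]))
  widths <- vapply(seq_along(df), function(j) {
    max(nchar(names(df)[j]), nchar(units[j]),
        if (nrow(df)) max(nchar(cells[[j]])) else 0L) + 2L
  }, integer(1))
  pad <- function(x, w) formatC(x, width = w, flag = " ")
  hdr <- paste0(map_chr(seq_along(df), ~ pad(names(df)[.x], widths[.x])),
                collapse = "")
  unt <- paste0(map_chr(seq_along(df), ~ pad(units[.x], widths[.x])),
                collapse = "")
  rows <- if (nrow(df)) {
    body <- map(seq_along(df), ~ pad(cells[[.x]], widths[.x]))
    do.call(paste0, body)
  } else {
    character(0)
  }
  c(hdr, unt, rows)
}

# Write a dialect file: title, blank line, then one block (or one "Run: N"
# block per element of `blocks`, a list of data frames sharing `units`).
write_dialect_file <- function(path, title, df = NULL, units = NULL,
                               blocks = NULL) {
  lines <- c(title, "")
  if (!is.null(blocks)) {
    for (i in seq_along(blocks)) {
      lines <- c(lines, sprintf("Run: %d", i),
                 format_block(blocks[[i]], units))
    }
  } else {
    lines <- c(lines, format_block(df, units))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Block parser.

split_fields <- function(line) str_split(str_trim(line), "\\s+")[[1]]

parse_block_rows <- function(lines, col_names, path, line_offset) {
  n_col <- length(col_names)
  if (!length(lines)) {
    mat <- matrix(numeric(0), ncol = n_col, dimnames = list(NULL, col_names))
    return(as_tibble(mat))
  }
  rows <- map(seq_along(lines), function(i) {
    cells <- split_fields(lines[[i]])
    if (length(cells) != n_col) {
      abort_parse("%s: line %d has %d fields, expected %d",
                  path, line_offset + i, length(cells), n_col)
    }
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & !cells %in% c("NA", "NaN"))
    if (length(bad)) {
      abort_parse("%s: non-numeric cell \"%s\" at line %d, column \"%s\"",
                  path, cells[bad[1]], line_offset + i, col_names[bad[1]])
    }
    vals
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- col_names
  out <- as_tibble(mat)
  # sentinel -> missing
  out[] <- map(out, function(x) replace(x, !is.na(x) & x == DIALECT_SENTINEL,
                                        NA_real_))
  out
}

# Parse a dialect file into blocks: list(run = int or NA, names, units, data).
read_dialect_file <- function(path) {
  if (!file.exists(path)) abort_parse("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)  # tolerate CRLF
  if (length(lines) < 3) abort_parse("%s: truncated file", path)
  body_start <- 3L
  run_lines <- which(str_detect(lines, "^\\s*Run:\\s*\\d+\\s*$"))
  run_lines <- run_lines[run_lines >= body_start]
  parse_one <- function(start, end, run) {
    if (end - start + 1 < 2) abort_parse("%s: block at line %d lacks header lines",
                                         path, start)
    col_names <- split_fields(lines[start])
    units <- split_fields(lines[start + 1])
    if (length(units) != length(col_names)) {
      abort_parse("%s: header has %d columns but units line has %d",
                  path, length(col_names), length(units))
    }
    data_lines <- if (end >= start + 2) lines[(start + 2):end] else character(0)
    data_lines <- data_lines[str_trim(data_lines) != ""]
    list(run = run,
         names = col_names,
         units = setNames(units, col_names),
         data = parse_block_rows(data_lines, col_names, path, start + 1))
  }
  if (length(run_lines)) {
    bounds <- c(run_lines, length(lines) + 1L)
    map(seq_along(run_lines), function(i) {
      run <- as.integer(sub("^\\s*Run:\\s*", "", lines[run_lines[i]]))
      parse_one(run_lines[i] + 1L, bounds[i + 1L] - 1L, run)
    })
  } else {
    body <- lines[body_start:length(lines)]
    first <- body_start + which(str_trim(body) != "")[1] - 1L
    list(parse_one(first, length(lines), NA_integer_))
  }
}
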