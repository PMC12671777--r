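#' Define a factorial study design
#'
#' A study is a full factorial over named factors (e.g. location, sowing
#' date, management, emissions scenario, climate model), each with ordered
#' level labels. One output file set is generated per cell of the Cartesian
#' product; its file-name prefix is the crop label and the cell's level
#' labels joined by underscores in factor order, so each design factor is
#' recoverable downstream as filename metadata. Underscores are therefore
#' reserved and may not appear inside labels.
#'
#' @param crop Crop label (first prefix segment; no underscores).
#' @param factors Named list; each element a character vector of >= 1 level
#'   labels without underscores.
#' @param overrides Optional nested list `overrides[[factor]][[level]]`, each
#'   a list with elements `weather` and/or `crop` holding parameter overrides
#'   applied to runs at that level (e.g.
#'   `list(scenario = list(RCP85 = list(weather = list(warming_trend = 0.6))))`).
#' @return An object of class `study_design`.
#' @export
#' @examples
#' study_design("Maize", list(location = c("Soroca", "Cahul"),
#'                            scenario = c("RCP26", "RCP85")))
study_design <- function(crop, factors, overrides = list()) {
  if (!is.character(crop) || length(crop) != 1 || !nzchar(crop)) {
    abort_invalid("`crop` must be a nonempty string")
  }
  if (!is.list(factors) || !length(factors) || is.null(names(factors)) ||
      any(!nzchar(names(factors)))) {
    abort_invalid("`factors` must be a named list of level vectors")
  }
  labels <- c(crop, unlist(factors, use.names = FALSE))
  if (any(grepl("_", labels, fixed = TRUE))) {
    offending <- labels[grepl("_", labels, fixed = TRUE)]
    abort_invalid(
      "level labels must not contain \"_\" (reserved as metadata separator): %s",
      paste(offending, collapse = ", "))
  }
  if (any(lengths(factors) < 1)) {
    abort_invalid("every factor needs at least one level")
  }
  unknown <- setdiff(names(overrides), names(factors))
  if (length(unknown)) {
    abort_invalid("`overrides` names unknown factor(s): %s",
                  paste(unknown, collapse = ", "))
  }
  structure(list(crop = crop, factors = factors, overrides = overrides),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> crop %s; %s = %d runs\n", x$crop,
              paste(lengths(x$factors), collapse = " x "),
              prod(lengths(x$factors))))
  invisible(x)
}

apply_overrides <- function(design, cell, weather_params, crop_params) {
  wp <- unclass(weather_params)
  cp <- unclass(crop_params)
  for (f in names(design$factors)) {
    ov <- design$overrides[[f]][[cell[[f]]]]
    if (!is.null(ov$weather)) wp <- modifyList(wp, ov$weather)
    if (!is.null(ov$crop)) cp <- modifyList(cp, ov$crop)
  }
  list(weather = wp, crop = cp)
}

#' Generate a factorial fixture study
#'
#' Writes one plug-in (or GUI) file set per cell of the design's factor
#' Cartesian product. Each run draws its own weather from a seed derived
#' deterministically from the base seed (base seed + run index in grid
#' order), simulates one season per feasible year, and writes its file set
#' with the underscore-joined prefix.
#'
#' @param design A [study_design()].
#' @param weather_params Base [weather_params()]; per-level overrides from the
#'   design are applied on top.
#' @param crop_params Base [toy_crop_params()]; the design's `crop` label
#'   replaces the parameter's label.
#' @param out_dir Output directory.
#' @param mode `"plugin"` (default) or `"gui"` file sets.
#' @return A list of `runset` objects, one per design cell, in prefix-sorted
#'   order.
#' @export
generate_study <- function(design, weather_params, crop_params, out_dir,
                           mode = c("plugin", "gui")) {
  mode <- match.arg(mode)
  if (!inherits(design, "study_design")) {
    abort_invalid("`design` must be a study_design object")
  }
  grid <- expand.grid(design$factors, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  runsets <- map(seq_len(nrow(grid)), function(i) {
    cell <- as.list(grid[i, , drop = FALSE])
    prefix <- paste(c(design$crop, unlist(cell)), collapse = "_")
    pars <- apply_overrides(design, cell, weather_params, crop_params)
    pars$weather$seed <- weather_params$seed + i
    pars$crop$crop <- design$crop
    w <- generate_weather(do.call(weather_params_new, pars$weather))
    seasons <- simulate_years(w, do.call(toy_crop_params, pars$crop))
    if (!length(seasons)) {
      abort_invalid("design cell %s yields no feasible season", prefix)
    }
    if (mode == "plugin") {
      write_plugin_fileset(seasons, out_dir, prefix)
    } else {
      write_gui_fileset(seasons, out_dir, prefix)
    }
  })
  runsets[order(map_chr(runsets, "prefix"))]
}

# weather_params() with arguments from a plain list (internal shim so that
# do.call sees a clean constructor).
weather_params_new <- function(...) weather_params(...)

#' The worked-example factorial design
#'
#' A single-crop climate-adaptation study patterned on a national assessment
#' for the Republic of Moldova: 3 locations (Soroca, Chisinau, Cahul), 3
#' sowing dates (26 Apr, 11 May, 26 May), 2 management practices, 2 emissions
#' scenarios (RCP 2.6 / 8.5) and 3 global climate models — 108 runs per crop.
#' Overrides encode the factor effects: location temperature offsets, sowing
#' day-of-year, a management hit to harvest index and water productivity, the
#' per-scenario warming trend and small inter-GCM temperature perturbations.
#'
#' @param crop Crop label (default `"Maize"`).
#' @return A [study_design()].
#' @export
#' @examples
#' moldova_design()
moldova_design <- function(crop = "Maize") {
  study_design(
    crop = crop,
    factors = list(
      location = c("Soroca", "Chisinau", "Cahul"),
      sowing = c("26Apr", "11May", "26May"),
      management = c("Optimal", "NonOptimal"),
      scenario = c("RCP26", "RCP85"),
      gcm = c("HadGEM2", "MPIESM", "NorESM1")
    ),
    overrides = list(
      location = list(
        Soroca = list(weather = list(base_tmin = 5, base_tmax = 15)),
        Chisinau = list(weather = list(base_tmin = 6, base_tmax = 16)),
        Cahul = list(weather = list(base_tmin = 7, base_tmax = 17))
      ),
      sowing = list(
        `26Apr` = list(crop = list(sowing_doy = 116L)),
        `11May` = list(crop = list(sowing_doy = 131L)),
        `26May` = list(crop = list(sowing_doy = 146L))
      ),
      management = list(
        Optimal = list(crop = list(hi = 0.48, wp_star = 0.033)),
        NonOptimal = list(crop = list(hi = 0.40, wp_star = 0.028))
      ),
      scenario = list(
        RCP26 = list(weather = list(warming_trend = 0.15)),
        RCP85 = list(weather = list(warming_trend = 0.55))
      ),
      gcm = list(
        HadGEM2 = list(weather = list(seasonal_amplitude = 11.5)),
        MPIESM = list(),
        NorESM1 = list(weather = list(seasonal_amplitude = 10.5))
      )
    )
  )
}
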