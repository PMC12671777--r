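touch <- function(dir, names) {
  paths <- file.path(dir, names)
  for (p in paths) writeLines("x", p)
  paths
}

test_that("files sharing a prefix are matched into one run, partial sets warn", {
  dir <- withr::local_tempdir()
  paths <- touch(dir, c("AClim.OUT", "ACrop.OUT", "A.PRM"))
  expect_warning(runs <- discover_runs(paths), "7 of 10")
  expect_length(runs, 1)
  expect_identical(runs[[1]]$prefix, "A")
  expect_identical(runs[[1]]$mode, "gui")
  expect_setequal(names(runs[[1]]$files), c("clim", "crop", "prm"))
  expect_length(unmatched_paths(runs), 0)
})

test_that("a complete plug-in set matches all 3 kinds without warning", {
  dir <- withr::local_tempdir()
  paths <- touch(dir, c("Mday.OUT", "Mseason.OUT", "M.PRM"))
  expect_no_warning(runs <- discover_runs(paths))
  expect_length(runs, 1)
  expect_identical(runs[[1]]$mode, "plugin")
  expect_setequal(names(runs[[1]]$files), c("day", "season", "prm"))
})

test_that("unregistered suffixes are collected, never silently dropped", {
  dir <- withr::local_tempdir()
  paths <- touch(dir, "notes.txt")
  runs <- discover_runs(paths)
  expect_length(runs, 0)
  expect_identical(unmatched_paths(runs), paths)
})

test_that("every path lands in exactly one run mapping or in unmatched", {
  dir <- withr::local_tempdir()
  paths <- touch(dir, c("AClim.OUT", "ACrop.OUT", "A.PRM", "Bday.OUT",
                        "Bseason.OUT", "B.PRO", "junk.log", "readme.md"))
  runs <- suppressWarnings(discover_runs(paths))
  assigned <- unlist(lapply(runs, function(r) unname(r$files)))
  expect_setequal(c(assigned, unmatched_paths(runs)), paths)
  expect_length(intersect(assigned, unmatched_paths(runs)), 0)
})

test_that("run matching is independent of path order", {
  dir <- withr::local_tempdir()
  paths <- touch(dir, c("AClim.OUT", "A.PRM", "Bday.OUT", "Bseason.OUT",
                        "B.PRM", "zzz.txt"))
  base <- suppressWarnings(discover_runs(paths))
  for (seed in 1:5) {
    shuffled <- withr::with_seed(seed, sample(paths))
    again <- suppressWarnings(discover_runs(shuffled))
    expect_identical(purrr::map_chr(again, "prefix"),
                     purrr::map_chr(base, "prefix"))
    for (i in seq_along(base)) {
      expect_identical(sort(again[[i]]$files), sort(base[[i]]$files))
    }
  }
})

test_that("a prefix mixing GUI-only and plug-in-only suffixes is an error naming it", {
  dir <- withr::local_tempdir()
  paths <- touch(dir, c("AClim.OUT", "Aday.OUT"))
  expect_error(discover_runs(paths), "\"A\"")
})

test_that("metadata tokens split on underscores, positionally named", {
  md <- extract_metadata("Maize_Soroca_RCP26", c("crop", "location", "scenario"))
  expect_identical(md$fields,
                   list(crop = "Maize", location = "Soroca",
                        scenario = "RCP26"))
  md1 <- extract_metadata("Run1")
  expect_identical(md1$fields, list(token1 = "Run1"))
  expect_error(extract_metadata("A_B", c("x", "y", "z")), "2.*3|3.*2")
})

test_that("project files round-trip the generator's parameters", {
  dir <- withr::local_tempdir()
  seasons <- tiny_seasons(n_years = 2)
  rs <- write_plugin_fileset(seasons, dir, "Proj_X")
  pr <- read_project(rs$files[["prm"]])
  crop <- seasons[[1]]$crop
  expect_identical(pr$run_id, "Proj_X")
  expect_identical(pr$mode, "plugin")
  expect_equal(pr$n_seasons, 2)
  expect_equal(pr$period_start,
               list(year = seasons[[1]]$season_year, doy = crop$sowing_doy))
  expect_equal(pr$period_end$year, seasons[[2]]$season_year)
  expect_equal(pr$soil_horizons, 3)
  expect_equal(pr$settings$Kc, crop$kc)
  expect_equal(pr$settings$HI, crop$hi)
  expect_equal(pr$settings$WPstar, crop$wp_star)
  expect_equal(pr$settings$GDDmaturity, crop$gdd_maturity)
  expect_match(pr$input_files$crop, "Maize")

  # single-season plug-in project: .PRO, one season
  rs1 <- write_plugin_fileset(seasons[[1]], dir, "Solo")
  pr1 <- read_project(rs1$files[["pro"]])
  expect_equal(pr1$n_seasons, 1)
})

test_that("more than five soil horizons are rejected", {
  dir <- withr::local_tempdir()
  rs <- tiny_plugin_run(dir)
  lines <- readLines(rs$files[["prm"]])
  lines <- sub("^SoilHorizons   : .*", "SoilHorizons   : 6", lines)
  bad <- file.path(dir, "bad.PRM")
  writeLines(lines, bad)
  expect_error(read_project(bad), "1 to 5")
})

test_that("missing mandatory period dates raise a parse error", {
  dir <- withr::local_tempdir()
  rs <- tiny_plugin_run(dir)
  lines <- grep("^PeriodEnd", readLines(rs$files[["prm"]]), value = TRUE,
                invert = TRUE)
  bad <- file.path(dir, "noend.PRM")
  writeLines(lines, bad)
  expect_error(read_project(bad), "PeriodEnd")
})

test_that("daily parsing is header-driven and rejects malformed cells", {
  dir <- withr::local_tempdir()
  rs <- write_gui_fileset(tiny_seasons(), dir, "Hdr")
  clim <- read_daily(rs$files[["clim"]], "clim")
  expect_true(all(c("Rain", "ETo", "Tmin", "Tmax", "Tavg") %in% names(clim)))
  expect_identical(attr(clim, "dataset_class"), "daily")
  expect_identical(unname(attr(clim, "units")[["Rain"]]), "mm")

  lines <- readLines(rs$files[["clim"]])
  lines[6] <- sub("\\d+\\.\\d+", "oops", lines[6])
  bad <- file.path(dir, "BadClim.OUT")
  writeLines(lines, bad)
  expect_error(read_daily(bad, "clim"), "oops")

  expect_error(read_daily(rs$files[["clim"]], "nope"), "registered daily kind")
})

test_that("an empty data section yields a zero-row fragment with a valid header", {
  dir <- withr::local_tempdir()
  rs <- tiny_plugin_run(dir)
  lines <- readLines(rs$files[["season"]])
  empty <- file.path(dir, "Emptyseason.OUT")
  writeLines(lines[1:4], empty)  # title, blank, names, units
  frag <- read_seasonal(empty)
  expect_equal(nrow(frag), 0)
  expect_equal(ncol(frag) - 2, 41)
})

test_that("duplicate season keys in a seasonal file are an error", {
  dir <- withr::local_tempdir()
  rs <- tiny_plugin_run(dir)
  lines <- readLines(rs$files[["season"]])
  dup <- c(lines, lines[5])
  bad <- file.path(dir, "Dupseason.OUT")
  writeLines(dup, bad)
  expect_error(read_seasonal(bad), "duplicate")
})
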