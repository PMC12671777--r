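test_that("GUI mode writes exactly 10 nonempty files named prefix + suffix", {
  dir <- withr::local_tempdir()
  rs <- write_gui_fileset(tiny_seasons(), dir, "Maize_Soroca")
  expect_length(rs$files, 10)
  expect_setequal(basename(rs$files),
                  paste0("Maize_Soroca",
                         c(".PRM", "Clim.OUT", "CompEC.OUT", "CompWC.OUT",
                           "Crop.OUT", "Inet.OUT", "Prof.OUT", "Salt.OUT",
                           "Wabal.OUT", "Run.OUT")))
  expect_true(all(file.exists(rs$files)))
  expect_true(all(file.size(rs$files) > 0))
})

test_that("plug-in mode writes 3 files, with .PRO for a single-season project", {
  dir <- withr::local_tempdir()
  seasons <- tiny_seasons(n_years = 2)
  rs <- write_plugin_fileset(seasons, dir, "Maize_Cahul")
  expect_setequal(basename(rs$files),
                  c("Maize_Cahul.PRM", "Maize_Cahulday.OUT",
                    "Maize_Cahulseason.OUT"))
  # two seasons -> two Run blocks in day.OUT and two seasonal rows
  day <- read_daily(rs$files[["day"]], "day")
  expect_setequal(unique(day$season_index), c(1, 2))
  expect_equal(nrow(read_seasonal(rs$files[["season"]])), 2)

  rs1 <- write_plugin_fileset(seasons[[1]], dir, "Single")
  expect_setequal(basename(rs1$files),
                  c("Single.PRO", "Singleday.OUT", "Singleseason.OUT"))
})

test_that("an empty prefix is rejected", {
  dir <- withr::local_tempdir()
  expect_error(write_gui_fileset(tiny_seasons(), dir, ""), "prefix")
  expect_error(write_plugin_fileset(tiny_seasons(), dir, ""), "prefix")
})

test_that("written seasonal files parse back to the source values at printed precision", {
  dir <- withr::local_tempdir()
  seasons <- tiny_seasons(n_years = 3, seed = 11)
  rs <- write_plugin_fileset(seasons, dir, "RT")
  got <- read_seasonal(rs$files[["season"]])
  expect_equal(nrow(got), 3)
  expect_equal(ncol(got) - 2, 41)  # season_index + year keys
  for (i in seq_along(seasons)) {
    s <- seasons[[i]]
    row <- got[got$season_index == i, ]
    expect_equal(row$year, s$season_year)
    expect_equal(row$Cycle, s$cycle_length)
    expect_equal(row$Tr, round(s$sum_tr, 2))
    expect_equal(row$ET, round(s$sum_et, 2))
    expect_equal(row$Biomass, round(s$biomass, 2))
    expect_equal(row$Yield, round(s$yield, 2))
    expect_equal(row$StressSto, round(s$stress_pct, 2))
    expect_equal(row$GDDtot, round(s$gdd_total, 2))
  }
})

test_that("written daily files parse back to the source trace at printed precision", {
  dir <- withr::local_tempdir()
  seasons <- tiny_seasons(n_years = 2, seed = 5)
  rs <- write_gui_fileset(seasons, dir, "RTD")
  clim <- read_daily(rs$files[["clim"]], "clim")
  src <- dplyr::bind_rows(lapply(seasons, `[[`, "daily"))
  expect_equal(nrow(clim), nrow(src))
  expect_equal(clim$Rain, round(src$rain, 2))
  expect_equal(clim$ETo, round(src$eto, 2))
  expect_equal(clim$Tmin, round(src$tmin, 2))
  expect_equal(clim$year, as.numeric(src$year))
  expect_equal(clim$dap, as.numeric(src$dap))

  wabal <- read_daily(rs$files[["wabal"]], "wabal")
  expect_equal(wabal$Wr, round(src$storage, 2))
  expect_equal(wabal$ET, round(src$evap + src$tr, 2))
})

test_that("GUI Run.OUT and plug-in season.OUT agree for the same simulation", {
  dir <- withr::local_tempdir()
  seasons <- tiny_seasons(n_years = 2, seed = 3)
  gui <- write_gui_fileset(seasons, dir, "Gui")
  plg <- write_plugin_fileset(seasons, dir, "Plg")
  a <- read_seasonal(gui$files[["run"]])
  b <- read_seasonal(plg$files[["season"]])
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("identical parameters and seed give byte-identical output files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- tiny_plugin_run(d1, seed = 21)
  r2 <- tiny_plugin_run(d2, seed = 21)
  for (k in names(r1$files)) {
    expect_identical(readLines(r1$files[[k]]), readLines(r2$files[[k]]))
  }
})

test_that("sentinel columns surface as missing, never as -9", {
  dir <- withr::local_tempdir()
  rs <- write_plugin_fileset(tiny_seasons(), dir, "Sent")
  day <- read_daily(rs$files[["day"]], "day")
  expect_true(all(is.na(day$SaltZ)))
  expect_true(all(is.na(day$EC1)))
  expect_false(any(day$SaltZ %in% -9, na.rm = TRUE))
  seas <- read_seasonal(rs$files[["season"]])
  expect_true(all(is.na(seas$ECmean)))
})

test_that("a factorial study enumerates the factor product with underscore-joined prefixes", {
  dir <- withr::local_tempdir()
  runs <- tiny_study(dir)
  expect_length(runs, 4)
  expect_setequal(purrr::map_chr(runs, "prefix"),
                  c("Maize_Soroca_RCP26", "Maize_Soroca_RCP85",
                    "Maize_Cahul_RCP26", "Maize_Cahul_RCP85"))
  # deterministic ordering by prefix
  expect_identical(purrr::map_chr(runs, "prefix"),
                   sort(purrr::map_chr(runs, "prefix")))

  single <- generate_study(study_design("Pea", list(site = "A")),
                           weather_params(n_years = 2),
                           tiny_crop(), dir)
  expect_length(single, 1)
  expect_identical(single[[1]]$prefix, "Pea_A")
})

test_that("level labels containing underscores are rejected", {
  expect_error(study_design("Maize", list(loc = c("So_roca"))), "_")
  expect_error(study_design("Mai_ze", list(loc = "Soroca")), "_")
})

test_that("increasing the warming trend never lengthens the mean crop cycle", {
  cycles <- sapply(c(0, 0.5, 1), function(trend) {
    w <- generate_weather(weather_params(n_years = 10, noise_sd = 0,
                                         warming_trend = trend, seed = 4))
    mean(purrr::map_int(simulate_years(w, tiny_crop()), "cycle_length"))
  })
  expect_true(all(diff(cycles) <= 0))
})
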