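test_that("a factorial study combines into metadata-keyed tidy tables", {
  dir <- withr::local_tempdir()
  runs <- tiny_study(dir)  # 2x2 runs, 2 seasons each
  cd <- combine_runs(runs, c("crop", "location", "scenario"))
  meta <- c("run_id", "crop", "location", "scenario")
  expect_identical(names(cd$seasonal)[1:4], meta)
  expect_equal(nrow(cd$seasonal), 4 * 2)
  expect_equal(ncol(cd$seasonal), 4 + 2 + 41)  # meta + keys + variables
  expect_equal(nrow(cd$project), 4)
  expect_true(all(meta %in% names(cd$daily)))
  expect_true(all(!is.na(cd$seasonal$run_id)))
  # row conservation: daily rows = sum of per-run cycle lengths
  expect_equal(nrow(cd$daily), sum(cd$seasonal$Cycle))
  # all files contributed
  expect_length(cd$provenance, 4 * 3)
})

test_that("a single run combines to its own fragments plus metadata", {
  dir <- withr::local_tempdir()
  rs <- tiny_plugin_run(dir, "Solo")
  cd <- combine_runs(list(rs))
  expect_identical(names(cd$seasonal)[1:2], c("run_id", "token1"))
  expect_equal(unique(cd$seasonal$token1), "Solo")
  frag <- read_seasonal(rs$files[["season"]])
  expect_equal(cd$seasonal$Yield, frag$Yield)
  expect_equal(nrow(cd$daily),
               nrow(read_daily(rs$files[["day"]], "day")))
})

test_that("runs with disjoint optional daily files union their columns", {
  dir <- withr::local_tempdir()
  s1 <- tiny_seasons(seed = 1)
  s2 <- tiny_seasons(seed = 2)
  r1 <- write_gui_fileset(s1, dir, "A")
  r2 <- write_gui_fileset(s2, dir, "B")
  # drop different daily files from each run
  r1$files <- r1$files[setdiff(names(r1$files), "inet")]
  r2$files <- r2$files[setdiff(names(r2$files), "clim")]
  cd <- combine_runs(list(r1, r2))
  expect_true(all(c("Inet", "Tmin") %in% names(cd$daily)))
  expect_true(all(is.na(cd$daily$Inet[cd$daily$run_id == "A"])))
  expect_true(all(!is.na(cd$daily$Tmin[cd$daily$run_id == "A"])))
  expect_true(all(is.na(cd$daily$Tmin[cd$daily$run_id == "B"])))
})

test_that("inconsistent token counts across prefixes are rejected with the offenders listed", {
  dir <- withr::local_tempdir()
  r1 <- tiny_plugin_run(dir, "Maize_Soroca")
  r2 <- tiny_plugin_run(dir, "Chisinau")
  expect_error(combine_runs(list(r1, r2)), "Chisinau")
  expect_error(combine_runs(list(r1), c("a", "b", "c")), "token")
})

test_that("filtering keeps the conjunction of simple predicates", {
  dir <- withr::local_tempdir()
  cd <- combine_runs(tiny_study(dir), c("crop", "location", "scenario"))
  half <- filter_rows(cd$seasonal,
                      list(var = "scenario", op = "==", value = "RCP85"))
  expect_equal(nrow(half), nrow(cd$seasonal) / 2)  # balanced design

  all_rows <- filter_rows(cd$seasonal,
                          list(var = "Cycle", op = ">", value = -Inf))
  expect_equal(as.data.frame(all_rows), as.data.frame(cd$seasonal))

  none <- filter_rows(cd$seasonal,
                      list(var = "year", op = "in", value = numeric(0)))
  expect_equal(nrow(none), 0)

  # filter o filter == single conjunction
  a <- filter_rows(filter_rows(cd$seasonal,
                               list(var = "scenario", op = "==",
                                    value = "RCP85")),
                   list(var = "location", op = "==", value = "Cahul"))
  b <- filter_rows(cd$seasonal,
                   list(list(var = "scenario", op = "==", value = "RCP85"),
                        list(var = "location", op = "==", value = "Cahul")))
  expect_equal(as.data.frame(a), as.data.frame(b))

  expect_error(filter_rows(cd$seasonal,
                           list(var = "nope", op = "==", value = 1)),
               "nope")
  expect_error(filter_rows(cd$seasonal,
                           list(var = "year", op = "~", value = 1)),
               "comparator")
})

test_that("renaming changes only the header and is an involution", {
  tb <- tibble::tibble(Yield = c(1, 2), Year = c(2010, 2011))
  out <- rename_variable(tb, "Yield", "yield_t_ha")
  expect_identical(names(out), c("yield_t_ha", "Year"))
  expect_identical(out$yield_t_ha, tb$Yield)
  back <- rename_variable(out, "yield_t_ha", "Yield")
  expect_identical(back, tb)
  expect_error(rename_variable(tb, "Yield", "Year"), "already exists")
  expect_error(rename_variable(tb, "nope", "x"), "nope")
})

test_that("CSV export round-trips, quotes commas, and writes missing as empty", {
  dir <- withr::local_tempdir()
  tb <- tibble::tibble(label = c("plain", "with, comma"),
                       value = c(1.5, NA))
  path <- file.path(dir, "out.csv")
  export_table(tb, path)
  raw <- readLines(path)
  expect_match(raw[3], "\"with, comma\"")
  expect_match(raw[3], ",$")
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tb))

  empty <- tb[0, ]
  export_table(empty, path)
  expect_identical(readLines(path), "label,value")
})
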