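test_that("long tables read into validated hourly series", {
  path <- write_long_csv(long_table(48))
  coll <- read_hourly_table(path)
  expect_equal(nrow(coll), 1L)
  s <- coll$series[[1]]
  expect_s3_class(s, "soil_hourly")
  expect_equal(nrow(s), 48L)
  expect_equal(attr(s, "variable"), "temperature")
  expect_equal(attr(s, "depth"), 10L)
  expect_equal(attr(s, "label"), "ST10")

  # two variables, two depths -> four series
  df <- dplyr::bind_rows(
    long_table(30, variable = "temperature", depth = 10),
    long_table(30, variable = "moisture", depth = 10),
    long_table(30, variable = "temperature", depth = 30),
    long_table(30, variable = "moisture", depth = 30))
  coll4 <- read_hourly_table(write_long_csv(df))
  expect_equal(nrow(coll4), 4L)
  expect_setequal(coll4$label, c("ST10", "MC10", "ST30", "MC30"))
})

test_that("grid violations raise classed errors naming the offending row", {
  df <- long_table(48, start = "2018-01-01 00:00")
  gap <- df[-8, ] # removes 07:00
  expect_error(read_hourly_table(write_long_csv(gap)),
               class = "soilcoupling_error_gap", regexp = "07:00")

  dup <- dplyr::bind_rows(df, df[5, ])
  expect_error(read_hourly_table(write_long_csv(dup)),
               class = "soilcoupling_error_duplicate")

  bad <- df
  bad$value <- as.character(bad$value)
  bad$value[7] <- "oops"
  expect_error(read_hourly_table(write_long_csv(bad)),
               class = "soilcoupling_error_format", regexp = "row 7")

  out_of_range <- long_table(30, variable = "moisture", values = rep(150, 30))
  expect_error(read_hourly_table(write_long_csv(out_of_range)),
               class = "soilcoupling_error_format", regexp = "instrument range")
})

test_that("short interior gaps can be interpolated, long ones cannot", {
  df <- long_table(48, values = seq(10, 10 + 47 * 0.1, by = 0.1))
  two_gap <- df[-c(10, 11), ]
  expect_message(
    coll <- read_hourly_table(write_long_csv(two_gap), interpolate_gaps = TRUE),
    "interpolated 2")
  expect_equal(nrow(coll$series[[1]]), 48L)
  # linear data -> linear interpolation is exact
  expect_equal(coll$series[[1]]$value, df$value, tolerance = 1e-12)

  three_gap <- df[-c(10, 11, 12), ]
  expect_error(read_hourly_table(write_long_csv(three_gap), interpolate_gaps = TRUE),
               class = "soilcoupling_error_gap")
})

test_that("a December-May study period yields the calendar hour count", {
  # Dec 19 2017 00:00 through May 30 2018 23:00 is 163 days of hourly data
  n_hours <- 163L * 24L
  path <- write_long_csv(long_table(n_hours, start = "2017-12-19 00:00",
                                    values = rep(12, n_hours)))
  coll <- read_hourly_table(path)
  expect_equal(coll$n, 3912L)
  d <- seasonal_difference(coll$series[[1]])
  expect_equal(nrow(d), 3888L)
  expect_equal(d$timestamp[1], as.POSIXct("2017-12-20 00:00", tz = "UTC"))
})

test_that("wide tables parse labels, including deseasonalized ones", {
  ts <- format(seq(as.POSIXct("2018-01-01", tz = "UTC"), by = "hour",
                   length.out = 60), "%Y-%m-%d %H:%M")
  wide <- tibble::tibble(timestamp = ts,
                         ST10 = round(rnorm(60, 10), 3),
                         MCSD30 = round(rnorm(60, 0, 0.1), 3))
  coll <- read_hourly_table(write_long_csv(wide))
  expect_equal(nrow(coll), 2L)
  st <- coll$series[[which(coll$label == "ST10")]]
  mc <- coll$series[[which(coll$label == "MCSD30")]]
  expect_s3_class(st, "soil_hourly")
  expect_s3_class(mc, "soil_deseason")
  expect_equal(attr(mc, "variable"), "moisture")
  expect_equal(attr(mc, "depth"), 30L)

  odd <- tibble::tibble(timestamp = ts, weird = rnorm(60))
  expect_error(read_hourly_table(write_long_csv(odd), format = "wide"),
               class = "soilcoupling_error_format")
})

test_that("seasonal differencing annihilates 24-periodic structure", {
  const <- hourly_series(rep(15, 100), "2018-01-01", "temperature", 10)
  expect_true(all(seasonal_difference(const)$value == 0))

  wave <- rep(5 + 3 * sin(2 * pi * (0:23) / 24) + rnorm(24), 5)
  periodic <- hourly_series(wave, "2018-01-01", "temperature", 10)
  expect_equal(seasonal_difference(periodic)$value, rep(0, 96), tolerance = 1e-12)

  expect_error(seasonal_difference(hourly_series(rep(1, 24), "2018-01-01",
                                                 "temperature", 10)),
               class = "soilcoupling_error_too-short")
})

test_that("seasonal differencing is linear and exactly invertible", {
  set.seed(11)
  x <- cumsum(rnorm(200)) / 10 + 15
  z <- cumsum(rnorm(200)) / 10 + 10
  dx <- seasonal_difference(x)$value
  dz <- seasonal_difference(z)$value
  combo <- seasonal_difference(2.5 * x - 1.3 * z)$value
  expect_equal(combo, 2.5 * dx - 1.3 * dz, tolerance = 1e-12)

  s <- hourly_series(x, "2017-12-19 03:00", "temperature", 30, "ST30")
  d <- seasonal_difference(s)
  expect_equal(attr(d, "label"), "STSD30")
  expect_equal(nrow(d), 200L - 24L)
  expect_equal(as.numeric(d$timestamp[1] - s$timestamp[1], units = "hours"), 24)
  back <- reconstruct_series(d)
  expect_equal(back$value, s$value, tolerance = 1e-12)
  expect_equal(back$timestamp, s$timestamp)
})

test_that("pairs align on the common timestamp window", {
  a <- seasonal_difference(hourly_series(rnorm(124, 10), "2018-01-01 00:00",
                                         "moisture", 10))
  b <- seasonal_difference(hourly_series(rnorm(124, 10), "2018-01-01 10:00",
                                         "temperature", 10))
  p <- align_pair(a, b)
  expect_equal(nrow(p), 90L) # 100-value series offset by 10 h
  expect_equal(attr(p, "labels"), c("MCSD10", "STSD10"))
  same <- align_pair(a, a)
  expect_equal(nrow(same), 100L)

  far <- seasonal_difference(hourly_series(rnorm(50, 10), "2019-06-01",
                                           "temperature", 10))
  expect_error(align_pair(a, far), class = "soilcoupling_error_disjoint")
})

test_that("deseasonalized series round-trip through the CSV writer", {
  d <- seasonal_difference(hourly_series(rnorm(80, 20), "2018-02-01",
                                         "temperature", 30))
  path <- tempfile(fileext = ".csv")
  write_deseasonalized(d, path)
  expect_match(readLines(path, n = 1), "period: 24")
  back <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  expect_equal(back$value, d$value, tolerance = 1e-6)
})
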