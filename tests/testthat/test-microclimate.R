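test_that("trace construction enforces its invariants", {
  ts <- as.POSIXct("2003-01-16", tz = "UTC") + c(0, 60, 120)
  expect_s3_class(temperature_trace(ts, c(1, 2, 3)), "temperature_trace")
  expect_error(temperature_trace(ts[c(1, 3, 2)], c(1, 2, 3)), "increasing")
  expect_error(temperature_trace(ts[1], 1), "at least 2")
  expect_error(temperature_trace(ts, c(1, NA, 3)), "finite")
})

test_that("logger CSV reading sorts, drops bad rows, and round-trips", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,temperature_c",
               "2003-01-16T02:00:00,5.5",
               "2003-01-16T01:00:00,4.0",
               "2003-01-16T03:00:00,bad",
               "2003-01-16T04:00:00,7.25"), p)
  expect_warning(tr <- read_logger_csv(p, species = "sp"), "dropped 1")
  expect_equal(nrow(tr), 3)
  expect_equal(tr$temperature_c, c(4.0, 5.5, 7.25))
  expect_identical(attr(tr, "species"), "sp")

  # missing column and empty-input errors
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp,temp\n2003-01-16,1", p2)
  expect_error(read_logger_csv(p2), "required column")
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,temperature_c", "junk,bad"), p3)
  expect_error(suppressWarnings(read_logger_csv(p3)), "no valid records")

  # write/read round trip of a simulated multi-day trace
  sim <- simulate_temperature_trace(days = 13, seed = 11)
  p4 <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(sim, p4)
  back <- read_logger_csv(p4)
  expect_equal(back$temperature_c, sim$temperature_c, tolerance = 1e-12)
  expect_equal(as.numeric(back$timestamp), as.numeric(sim$timestamp))
})

test_that("temperature binning counts half-open bins and sums to 100", {
  tr <- make_trace(c(-1, 1, 5, 5))
  h <- bin_temperature_frequency(tr, bin_width = 2, range = c(-2, 6))
  expect_equal(h$bin_low, c(-2, 0, 2, 4))
  expect_equal(h$frequency_pct, c(25, 25, 0, 50))
  expect_equal(sum(h$frequency_pct), 100, tolerance = 1e-9)

  # a record on a bin edge goes into the upper (left-closed) bin
  h2 <- bin_temperature_frequency(make_trace(c(2, 2, 3, 5)), bin_width = 2)
  expect_equal(h2$frequency_pct[h2$bin_low == 2], 75)

  # all records in one bin
  h3 <- bin_temperature_frequency(make_trace(rep(5.5, 10)), bin_width = 2)
  expect_equal(h3$frequency_pct[h3$bin_low == 4], 100)
  expect_equal(sum(h3$frequency_pct), 100)

  # out-of-range records extend the histogram instead of being dropped
  h4 <- bin_temperature_frequency(make_trace(c(-6, 0, 34.2, 1)),
                                  bin_width = 2, range = c(-4, 28))
  expect_equal(sum(h4$count), 4)
  expect_true(min(h4$bin_low) <= -6 && max(h4$bin_high) >= 34.2)

  # the conventional 2-degree grid -4, -2, ..., 28 is reproduced
  h5 <- bin_temperature_frequency(make_trace(c(-3.5, 10, 27)), bin_width = 2,
                                  range = c(-4, 28))
  expect_true(all(seq(-4, 26, 2) %in% h5$bin_low))
})

test_that("binning matches a brute-force counter on random traces", {
  set.seed(42)
  for (i in 1:25) {
    x <- runif(1000, -10, 35)
    h <- bin_temperature_frequency(make_trace(x), bin_width = 2)
    edges <- c(h$bin_low, h$bin_high[nrow(h)])
    expect_identical(h$frequency_pct, brute_force_bin_freq(x, edges))
    expect_equal(sum(h$frequency_pct), 100, tolerance = 1e-9)
  }
})

test_that("binning is invariant to record order and record duplication", {
  set.seed(7)
  x <- runif(300, -5, 20)
  h1 <- bin_temperature_frequency(make_trace(x), 2)
  h2 <- bin_temperature_frequency(make_trace(sample(x)), 2)
  expect_equal(h1$frequency_pct, h2$frequency_pct)
  h3 <- bin_temperature_frequency(make_trace(rep(x, 2)), 2)
  expect_equal(h1$frequency_pct, h3$frequency_pct)
  expect_equal(attr(h3, "n_records"), 600)
})

test_that("fraction_time_outside uses strict inequalities", {
  expect_equal(unname(fraction_time_outside(make_trace(c(2, 3, 5, 15)))),
               c(50, 25))
  # records exactly at a threshold count as neither below nor above
  expect_equal(unname(fraction_time_outside(make_trace(rep(4, 5)))), c(0, 0))
  expect_error(fraction_time_outside(make_trace(1:5), low = 10, high = 10),
               "low must be")

  set.seed(9)
  x <- runif(500, -5, 20)
  expect_equal(unname(fraction_time_outside(make_trace(x), 4, 14)),
               brute_force_outside(x, 4, 14))
  out <- fraction_time_outside(make_trace(x), 2, 3)
  expect_lte(sum(out), 100)
})

test_that("diurnal summary keys by hour and flags absent hours", {
  ts <- as.POSIXct(c("2003-01-16 12:10", "2003-01-16 12:40"), tz = "UTC")
  d <- diurnal_summary(temperature_trace(ts, c(10, 14)))
  expect_equal(nrow(d), 24)
  r12 <- d[d$hour == 12, ]
  expect_equal(c(r12$n, r12$mean, r12$max, r12$min), c(2, 12, 14, 10))
  expect_true(all(is.na(d$mean[d$hour != 12])))
  expect_true(all(d$n[d$hour != 12] == 0))

  # constant trace: every present hour reports the constant
  tr <- make_trace(rep(5, 48))
  dc <- diurnal_summary(tr)
  expect_true(all(dc$mean[dc$n > 0] == 5 & dc$max[dc$n > 0] == 5))

  # hour of maximum mean equals the generator's peak hour
  sim <- simulate_temperature_trace(days = 20, noise_sd = 0, spike_prob = 0,
                                    peak_hour = 12.5, seed = 3)
  ds <- diurnal_summary(sim)
  expect_true(ds$hour[which.max(ds$mean)] %in% c(12, 13))
})

test_that("histograms write and read back through CSV and JSON", {
  h <- bin_temperature_frequency(make_trace(c(-1, 1, 5, 5)), 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_histogram(h, p)
  h2 <- read_histogram_csv(p)
  expect_equal(h2$frequency_pct, h$frequency_pct)
  expect_equal(attr(h2, "n_records"), attr(h, "n_records"))
  pj <- withr::local_tempfile(fileext = ".json")
  write_histogram(h, pj, format = "json")
  j <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(j$n_records, 4)
  expect_equal(j$bins$frequency_pct, h$frequency_pct)
})
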