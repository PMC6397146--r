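mk_sensor <- function(days = 60, start = "2011-01-01", vals = NULL) {
  ts <- seq(as.POSIXct(start, tz = "UTC"),
            by = 15 * 60, length.out = days * 96)
  if (is.null(vals)) vals <- data.frame(x = rep(1.5, length(ts)))
  sensor_series(ts, vals)
}

test_that("antecedent mean of a constant is the constant at full coverage", {
  sen <- mk_sensor()
  r <- antecedent_mean(sen, as.Date("2011-02-15"))
  expect_equal(unname(r$mean["x"]), 1.5)
  expect_equal(unname(r$coverage["x"]), 1, tolerance = 1e-6)
})

test_that("a linear ramp over a covered window averages to its midpoint", {
  days <- 60
  ts <- seq(as.POSIXct("2011-01-01", tz = "UTC"), by = 15 * 60,
            length.out = days * 96)
  ramp <- as.numeric(ts) / 86400   # linear in time
  sen <- sensor_series(ts, data.frame(r = ramp))
  d <- as.Date("2011-02-10")
  res <- antecedent_mean(sen, d, window_days = 21)
  # brute-force sum over the generated readings in the half-open window
  t1 <- as.POSIXct(format(d), tz = "UTC")
  sel <- ts >= t1 - 21 * 86400 & ts < t1
  expect_equal(unname(res$mean["r"]), mean(ramp[sel]), tolerance = 1e-12)
  # midpoint value of the ramp across the window (within half a reading step)
  midpoint <- (as.numeric(t1) - 21 * 86400 / 2) / 86400
  expect_lt(abs(unname(res$mean["r"]) - midpoint), 0.01)
})

test_that("the window is half-open and strictly antecedent", {
  ts <- as.POSIXct("2011-03-01", tz = "UTC") + c(-3600, -60, 0, 60)
  sen <- sensor_series(ts, data.frame(x = c(10, 20, 1000, 2000)))
  r <- suppressWarnings(antecedent_mean(sen, as.Date("2011-03-01"),
                                        window_days = 1, min_coverage = 0))
  expect_equal(unname(r$mean["x"]), 15)  # sampling instant and later excluded
})

test_that("coverage below threshold suppresses the mean with a warning", {
  sen <- mk_sensor(days = 10)   # only ~10 of 21 window days exist
  expect_warning(r <- antecedent_mean(sen, as.Date("2011-01-11"),
                                      window_days = 21, min_coverage = 0.5),
                 "coverage")
  expect_true(is.na(r$mean["x"]))
  expect_lt(r$coverage["x"], 0.5)
  expect_error(antecedent_mean(mk_sensor(), as.Date("2010-12-01")), "no data")
})

test_that("log transform is log(a*x + b) with domain checking", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(exp(1) - 1), 1)
  x <- c(0.2, 3, 17)
  expect_equal(log_transform(x, a = 2, b = 0.5),
               vapply(x, function(xi) log(2 * xi + 0.5), numeric(1)))
  expect_error(log_transform(-2), "domain error")
})

test_that("environmental matrices align to sample dates with logged variables", {
  g <- gen_sensor("2011-01-01", "2012-02-01", seed = 2)
  dates <- gen_sample_dates(1, seed = 2, start = as.Date("2011-02-01"))
  env <- build_env_matrix(g$sensor, dates)
  expect_equal(nrow(env), 12)
  expect_equal(ncol(env), 10)
  expect_true(all(c("discharge", "turbidity", "rainfall") %in% names(env)))
  cov <- attr(env, "coverage")
  expect_true(all(cov >= 0 & cov <= 1))
  # winter antecedent discharge exceeds summer antecedent discharge
  mo <- as.integer(format(as.Date(rownames(env)), "%m"))
  expect_gt(mean(env$discharge[mo %in% c(12, 1, 2)]),
            mean(env$discharge[mo %in% 6:8]))
  suppressWarnings(
    expect_error(build_env_matrix(g$sensor, as.Date("2010-06-01")),
                 "empty output|no data"))
})

test_that("window means merge and shift consistently", {
  g <- gen_sensor("2011-01-01", "2011-04-01", seed = 7)
  sen <- g$sensor
  d <- as.Date("2011-03-20")
  # mean over a 20-day window = count-weighted mean of two 10-day sub-windows
  full <- antecedent_mean(sen, d, window_days = 20)
  first <- antecedent_mean(sen, d - 10, window_days = 10)
  second <- antecedent_mean(sen, d, window_days = 10)
  n1 <- 10 * 96
  expect_equal(unname(full$mean["temperature"]),
               unname((first$mean["temperature"] * n1 +
                         second$mean["temperature"] * n1) / (2 * n1)),
               tolerance = 1e-12)
  # shifting all timestamps and the sample date leaves the mean unchanged
  shift <- 86400 * 100
  sen2 <- sensor_series(sen$timestamp + shift,
                        as.data.frame(sen)[setdiff(names(sen), "timestamp")])
  r1 <- antecedent_mean(sen, d)
  r2 <- antecedent_mean(sen2, as.POSIXct(format(d), tz = "UTC") + shift)
  expect_equal(r2$mean, r1$mean, tolerance = 1e-12)
})

test_that("random sensor dropouts barely move covered means", {
  g <- gen_sensor("2011-01-01", "2011-03-15", seed = 11)
  sen <- g$sensor
  d <- as.Date("2011-03-01")
  base <- antecedent_mean(sen, d)
  set.seed(99)
  keep <- sort(sample(nrow(sen), round(0.9 * nrow(sen))))
  sen_thin <- sensor_series(sen$timestamp[keep],
                            as.data.frame(sen)[keep, setdiff(names(sen), "timestamp")])
  thin <- antecedent_mean(sen_thin, d)
  for (v in c("temperature", "conductivity", "oxygen", "ph")) {
    expect_lt(abs(thin$mean[[v]] - base$mean[[v]]) / abs(base$mean[[v]]), 0.01)
  }
})

test_that("sensor CSV round-trips with units sidecar", {
  g <- gen_sensor("2011-01-01", "2011-01-05", seed = 1)
  tmp <- tempfile(fileext = ".csv")
  tmpu <- tempfile(fileext = ".json")
  on.exit(unlink(c(tmp, tmpu)))
  write_sensor_csv(g$sensor, tmp, units_path = tmpu)
  s2 <- read_sensor_csv(tmp, units_path = tmpu)
  expect_equal(as.data.frame(s2)$discharge, as.data.frame(g$sensor)$discharge,
               tolerance = 1e-10)
  expect_equal(attr(s2, "units")[["discharge"]], "m3 s-1")
})
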