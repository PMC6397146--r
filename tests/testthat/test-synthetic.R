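test_that("generators are bit-reproducible by seed and carry their truth", {
  a <- gen_eqr_series(seed = 7)
  b <- gen_eqr_series(seed = 7)
  expect_identical(a$series$values, b$series$values)
  expect_identical(a$truth$a, b$truth$a)
  expect_false(identical(a$series$values, gen_eqr_series(seed = 8)$series$values))
  expect_true(all(c("trend", "a", "b", "seasonal", "noise_sd", "seed") %in%
                    names(a$truth)))
  d <- gen_sample_dates(2, seed = 3)
  g1 <- gen_counts(d, seed = 3)
  g2 <- gen_counts(d, seed = 3)
  expect_identical(g1$counts$counts, g2$counts$counts)
  s1 <- gen_sensor("2011-01-01", "2011-02-01", seed = 3)
  s2 <- gen_sensor("2011-01-01", "2011-02-01", seed = 3)
  expect_identical(as.data.frame(s1$sensor), as.data.frame(s2$sensor))
  # CSV output is byte-identical across regenerations
  t1 <- tempfile(fileext = ".csv")
  t2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(t1, t2)))
  write_series_csv(gen_eqr_series(seed = 5)$series, t1)
  write_series_csv(gen_eqr_series(seed = 5)$series, t2)
  expect_identical(unname(tools::md5sum(t1)), unname(tools::md5sum(t2)))
})

test_that("the EQR generator matches its stated sampling design", {
  g <- gen_eqr_series(seed = 1)
  expect_equal(length(g$series), 66)   # 12 per year over 5.5 years
  expect_true(all(diff(g$series$times) > 0))
  # mid-monthly with <= 5-day jitter: every gap between 21 and 41 days
  gaps <- diff(g$series$times) * 365.2425
  expect_true(all(gaps > 18 & gaps < 43))
  expect_true(all(g$series$values >= 0 & g$series$values <= 1.25))
  expect_error(gen_eqr_series(noise_frac = 0), "noise_frac")
  expect_error(gen_eqr_series(noise_frac = 1), "noise_frac")
  # no drift and vanishing noise gives an exact fixed sinusoid plus trend
  g0 <- gen_eqr_series(seed = 2, amp_drift_sd = 0, noise_frac = 1e-12,
                       trend_slope = 0.01)
  tt <- g0$series$times
  a <- g0$truth$a[1]
  b <- g0$truth$b[1]
  expect_equal(g0$series$values,
               0.7 + 0.01 * (tt - tt[1]) + a * cos(2 * pi * tt) +
                 b * sin(2 * pi * tt),
               tolerance = 1e-4)
})

test_that("observation noise is the stated fraction of series variance", {
  ratios <- vapply(1:50, function(seed) {
    g <- gen_eqr_series(seed = seed)
    var(g$truth$noise) / var(g$series$values)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.15), 0.05)
})

test_that("count draws respect the 300-valve convention and the pool means", {
  dates <- gen_sample_dates(1, seed = 1)
  pools <- default_pools()
  # every sample sums to the counting total
  for (seed in 1:5)
    expect_true(all(rowSums(gen_counts(dates, seed = seed)$counts$counts) == 300))
  # forcing w = 1: mean counts across seeds near 300 * summer pool
  acc <- 0
  nseed <- 50
  for (seed in seq_len(nseed)) {
    g <- gen_counts(dates[1], seed = seed, fixed_weight = 1)
    acc <- acc + g$counts$counts[1, names(pools$summer)]
  }
  mu <- 300 * pools$summer
  se <- sqrt(300 * pools$summer * (1 - pools$summer) / nseed)
  expect_true(all(abs(acc / nseed - mu) <= 3 * se))
  expect_error(gen_counts(dates, summer_pool = c(BAD = 1)), "schema")
  expect_error(gen_counts(dates, summer_pool = c(ACHMIN = 0.5)), "schema")
})

test_that("the sensor generator produces event-driven hydrology", {
  g <- gen_sensor("2011-01-01", "2011-03-01", seed = 2)
  sen <- as.data.frame(g$sensor)
  expect_true(all(diff(as.numeric(sen$timestamp)) == 900))
  # zero rainfall forced: discharge equals baseflow exactly (no event response)
  g0 <- gen_sensor("2011-01-01", "2011-03-01", seed = 2, rain_event_prob = 0)
  sen0 <- as.data.frame(g0$sensor)
  expect_true(all(sen0$rainfall == 0))
  lt <- as.POSIXlt(sen0$timestamp)
  tfrac <- (lt$yday + (lt$hour + lt$min / 60) / 24) / 365.2425
  baseflow <- 0.12 * (1 + 0.6 * cos(2 * pi * tfrac))
  expect_equal(sen0$discharge, baseflow, tolerance = 1e-12)
  # the hydrograph lags the hyetograph: cor(Q_{t+k}, rain_t) peaks at k > 0
  cc <- ccf(sen$discharge, sen$rainfall, lag.max = 96, plot = FALSE)
  expect_gt(cc$lag[which.max(cc$acf)], 0)
  # TRP and turbidity respond to rising discharge
  dq <- pmax(c(0, diff(sen$discharge)), 0)
  expect_gt(cor(dq, sen$trp), 0.5)
  expect_gt(cor(dq, sen$turbidity), 0.5)
})

test_that("winter discharge exceeds summer discharge across seeds", {
  wins <- 0L
  for (seed in 1:10) {
    g <- gen_sensor("2011-06-01", "2012-06-01", seed = seed)
    sen <- as.data.frame(g$sensor)
    mo <- as.integer(format(sen$timestamp, "%m"))
    if (mean(sen$discharge[mo %in% c(12, 1, 2)]) >
        mean(sen$discharge[mo %in% 6:8])) wins <- wins + 1L
  }
  expect_equal(wins, 10L)
})

test_that("truth sidecars serialize to JSON", {
  g <- gen_counts(gen_sample_dates(1, seed = 1), seed = 1)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_truth_json(g$truth, tmp)
  tr <- jsonlite::fromJSON(tmp)
  expect_equal(tr$t_peak, 0.54)
  expect_equal(length(tr$mixing_weight), 12)
})
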