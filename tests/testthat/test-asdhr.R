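test_that("a noiseless sinusoid plus constant is fit almost exactly", {
  tt <- make_times(48, 7)
  y <- 0.7 + 0.25 * cos(2 * pi * tt + 0.4)
  fit <- asdhr(y, times = tt, harmonics = 1, trend = "rw",
               nvr = c(trend = 0, seasonal = 0), sigma2 = 1e-10)
  expect_gte(fit$r.squared, 0.999)
})

test_that("components add exactly to the fitted values", {
  g <- gen_eqr_series(seed = 4)
  fit <- asdhr(g$series, nvr = c(trend = 0.01, seasonal = 0.5))
  expect_equal(fit$fitted, fit$trend$estimate + fit$seasonal$estimate,
               tolerance = 1e-12)
  expect_equal(fit$residuals, g$series$values - fit$fitted, tolerance = 1e-12)
  expect_true(fit$r.squared >= 0 && fit$r.squared <= 1)
})

test_that("zero NVRs reproduce the OLS harmonic regression", {
  for (seed in 1:4) {
    n <- 40
    tt <- make_times(n, seed + 20)
    set.seed(seed + 100)
    y <- 0.6 + 0.05 * (tt - tt[1]) + 0.2 * cos(2 * pi * tt) -
      0.1 * sin(4 * pi * tt) + rnorm(n, 0, 0.07)
    for (tr in c("irw", "rw")) {
      fit <- asdhr(y, times = tt, harmonics = 2, trend = tr,
                   nvr = c(trend = 0, seasonal = 0))
      ols <- ols_harmonic(tt, y, n_harm = 2, trend = tr)
      expect_lt(rel_err(fit$fitted, ols$fitted), 1e-6)
      expect_lt(rel_err(fit$r.squared, ols$r_squared), 1e-6)
      expect_lt(rel_err(fit$edf, ols$p), 1e-6)
      expect_lt(rel_err(fit$fstatistic[["value"]], ols$f_statistic), 1e-6)
    }
  }
})

test_that("goodness-of-fit statistics behave at the extremes", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8)
  perfect <- structure(list(series = list(values = y),
                            residuals = rep(0, 8), edf = 3, sigma2 = 0,
                            logLik = 0, n = 8), class = "asdhr")
  g <- goodness_of_fit(perfect)
  expect_equal(g$r_squared, 1)
  flat <- structure(list(series = list(values = y),
                         residuals = y - mean(y), edf = 3, sigma2 = 1,
                         logLik = 0, n = 8), class = "asdhr")
  g2 <- goodness_of_fit(flat)
  expect_equal(g2$r_squared, 0)
  expect_equal(g2$f_statistic, 0)
  under <- structure(list(series = list(values = y),
                          residuals = rep(0.1, 8), edf = 9, sigma2 = 1,
                          logLik = 0, n = 8), class = "asdhr")
  expect_error(goodness_of_fit(under), "underdetermined")
})

test_that("confidence bands use the Gaussian quantile and track sigma2", {
  g <- gen_eqr_series(seed = 6)
  fit <- asdhr(g$series, nvr = c(trend = 0.01, seasonal = 0.3), sigma2 = 0.002)
  cb <- confidence_band(fit, level = 0.95)
  z <- (cb$fit_hi - cb$fit) / sqrt(fit$var_fitted)
  expect_equal(unique(round(z, 6)), 1.959964)
  cb80 <- confidence_band(fit, level = 0.80)
  expect_true(all(cb80$fit_hi <= cb$fit_hi + 1e-12))
  # band width shrinks as the observation noise vanishes
  fit_small <- asdhr(g$series, nvr = c(trend = 0.01, seasonal = 0.3),
                     sigma2 = 2e-6)
  expect_lt(mean(fit_small$band$fit_hi - fit_small$band$fit_lo),
            mean(fit$band$fit_hi - fit$band$fit_lo))
  expect_error(confidence_band(fit, level = 1), "strictly between")
})

test_that("seasonal band variance matches the joint-Gaussian oracle", {
  n <- 20
  tt <- make_times(n, 31)
  set.seed(31)
  y <- 0.5 + 0.2 * cos(2 * pi * tt) + rnorm(n, 0, 0.05)
  nv <- c(trend = 0.02, seasonal = 0.1)
  s2 <- 0.0025
  fit <- asdhr(y, times = tt, harmonics = 1, trend = "rw", nvr = nv, sigma2 = s2)
  kf <- kalman_filter(fit$series, fit$spec, nv, s2)
  orc <- oracle_joint(tt, y, n_harm = 1, trend = "rw",
                      nvr_trend = nv["trend"], nvr_seas = nv["seasonal"],
                      sigma2 = s2, P0_abs = kf$P0)
  expect_lt(rel_err(fit$var_fitted, orc$fitvar, floor = 1e-8), 1e-6)
  # seasonal variance = h_S Sigma h_S' with h_S the seasonal sub-row
  seas_var_oracle <- vapply(seq_len(n), function(k) {
    hs <- c(0, cos(2 * pi * tt[k]), sin(2 * pi * tt[k]))
    drop(hs %*% orc$Pcs[[k]] %*% hs)
  }, numeric(1))
  expect_lt(rel_err(fit$seasonal$var, seas_var_oracle, floor = 1e-8), 1e-6)
  expect_lt(rel_err(fit$fitted, orc$fitted), 1e-6)
})

test_that("shifting the time origin leaves the fit invariant", {
  g <- gen_eqr_series(seed = 8)
  nv <- c(trend = 0.02, seasonal = 0.4)
  fit1 <- asdhr(g$series, nvr = nv, sigma2 = 0.002)
  shifted <- irregular_series(g$series$times + 7, g$series$values)
  fit2 <- asdhr(shifted, nvr = nv, sigma2 = 0.002)
  expect_lt(max(abs(fit1$fitted - fit2$fitted)), 1e-8)
  expect_lt(abs(fit1$r.squared - fit2$r.squared), 1e-8)
  expect_lt(abs(fit1$fstatistic[["value"]] - fit2$fstatistic[["value"]]), 1e-6)
})

test_that("prediction interpolates through the transition law", {
  g <- gen_eqr_series(seed = 9)
  fit <- asdhr(g$series, nvr = c(trend = 0.01, seasonal = 0.2))
  pr <- predict(fit, times = g$series$times)
  expect_equal(pr$fit, fit$fitted, tolerance = 1e-9)
  expect_equal(pr$seasonal, fit$seasonal$estimate, tolerance = 1e-9)
  # precision-weighted bridge between two neighbours under an RW trend
  # (negligible observation noise relative to the process: nvr * sigma2 = 1)
  t2 <- c(2011.0, 2012.0)
  y2 <- c(1, 3)
  fit2 <- asdhr(y2, times = t2, harmonics = 0, trend = "rw",
                nvr = c(trend = 1e8), sigma2 = 1e-8)
  mid <- predict(fit2, times = 2011.5)
  expect_equal(mid$fit, mean(y2), tolerance = 1e-3)
  q1 <- predict(fit2, times = 2011.25)$fit
  expect_equal(q1, 0.75 * y2[1] + 0.25 * y2[2], tolerance = 1e-3)
  # interpolation is less uncertain than extrapolation past the end
  vin <- predict(fit2, times = 2011.5)$fit_var
  vout <- predict(fit2, times = 2013.0)$fit_var
  expect_lt(vin, vout)
})

test_that("deleting one observation barely moves distant estimates", {
  g <- gen_eqr_series(seed = 11)
  nv <- c(trend = 0.01, seasonal = 0.3)
  fit <- asdhr(g$series, nvr = nv, sigma2 = 0.002)
  drop_k <- 30
  s2 <- irregular_series(g$series$times[-drop_k], g$series$values[-drop_k])
  fit2 <- asdhr(s2, nvr = nv, sigma2 = 0.002)
  far <- which(abs(g$series$times[-drop_k] - g$series$times[drop_k]) > 1)
  half_width <- (fit2$band$fit_hi - fit2$band$fit_lo)[far] / 2
  expect_true(all(abs(fit$fitted[-drop_k][far] - fit2$fitted[far]) < half_width))
})

test_that("model methods expose the fit consistently", {
  g <- gen_eqr_series(seed = 12)
  fit <- asdhr(g$series, nvr = c(trend = 0.01, seasonal = 0.3))
  expect_identical(fitted(fit), fit$fitted)
  expect_identical(residuals(fit), fit$residuals)
  expect_named(coef(fit), c("nvr_trend", "nvr_seasonal", "sigma2"))
  expect_s3_class(summary(fit), "summary.asdhr")
  expect_output(print(fit), "R-squared")
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$logLik)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(fit$n, 2L))
  expect_true(all(is.finite(as.matrix(sim))))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_fit_csv(fit, tmp)
  out <- read.csv(tmp)
  expect_equal(out$fitted, fit$fitted, tolerance = 1e-10)
  js <- jsonlite::fromJSON(fit_summary_json(fit))
  expect_equal(js$r_squared, fit$r.squared, tolerance = 1e-12)
})
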