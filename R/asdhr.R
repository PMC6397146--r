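#' Arbitrary-sampled dynamic harmonic regression
#'
#' Fits the unobserved-components model
#' \deqn{y_t = T_t + S_t + e_t, \qquad
#'       S_t = \sum_{i=1}^{R_s} a_{i,t}\cos(\omega_i t) + b_{i,t}\sin(\omega_i t)}
#' to an irregularly sampled series, where the trend \eqn{T_t} and the
#' harmonic coefficients \eqn{a_{i,t}, b_{i,t}} are stochastic time-varying
#' parameters estimated by Kalman filtering and fixed-interval smoothing in
#' continuous time. The initial state is treated as fully diffuse and
#' handled exactly by regression augmentation, so the constant-parameter
#' limit (`nvr = 0`) reproduces ordinary harmonic regression exactly. Noise
#' variance ratios (and the observation-noise variance) are estimated by
#' maximum (diffuse/marginal) likelihood unless supplied.
#'
#' The fitted value at each sample instant is exactly
#' \eqn{\hat y_t = \hat T_t + \hat S_t}. Goodness of fit is summarised by
#' \eqn{R^2 = 1 - \sum\hat e^2 / \sum (y - \bar y)^2} and an F statistic
#' whose model degrees of freedom are the trace of the smoother's influence
#' map (which equals the regressor count in the constant-parameter limit).
#'
#' @param x Series input: an [irregular_series()], a two-column data frame
#'   (date/time, value), or a numeric vector with `times`.
#' @param period Fundamental seasonal period in years.
#' @param harmonics Number of harmonics \eqn{R_s} (1-6), or 0 for a
#'   trend-only model.
#' @param trend Trend TVP law: `"irw"` (default), `"rw"`, or `"none"`.
#' @param seasonal Seasonal TVP law for the harmonic coefficients: `"rw"`
#'   (default) or `"irw"`.
#' @param nvr Optional fixed NVRs, named `c(trend = , seasonal = )` (a
#'   scalar is shared). `NULL` (default) estimates them by maximum
#'   likelihood.
#' @param sigma2 Optional fixed observation-noise variance; estimated
#'   otherwise.
#' @param level Confidence level for the stored bands.
#' @param times Observation instants when `x` is a bare numeric vector.
#' @param spec Optional full [uc_spec()] overriding
#'   `period`/`harmonics`/`trend`/`seasonal`.
#' @param method Likelihood flavour for hyperparameter estimation; see
#'   [estimate_hyperparameters()]. The default `"marginal"` keeps the
#'   confidence bands calibrated.
#'
#' @return Object of class `"asdhr"` with components `trend`, `seasonal`
#'   (data frames of smoothed estimates and variances), `tvp` (per-harmonic
#'   coefficient paths), `fitted`, `residuals`, `band`, `nvr`, `sigma2`,
#'   `logLik`, `r.squared`, `fstatistic`, `f.pvalue`, `edf`, and the inputs.
#' @seealso [goodness_of_fit()], [confidence_band()], [predict.asdhr()],
#'   [plot.asdhr()]
#' @export
#' @examples
#' t <- sort(2011 + runif(40, 0, 4))
#' y <- 0.7 + 0.2 * cos(2 * pi * t) + rnorm(40, 0, 0.03)
#' fit <- asdhr(y, times = t, harmonics = 1, nvr = c(trend = 0, seasonal = 0))
#' summary(fit)
asdhr <- function(x, period = 1, harmonics = 2,
                  trend = c("irw", "rw", "none"),
                  seasonal = c("rw", "irw"),
                  nvr = NULL, sigma2 = NULL, level = 0.95,
                  times = NULL, spec = NULL,
                  method = c("marginal", "ml")) {
  cl <- match.call()
  series <- as_irregular_series(x, times = times)
  if (is.null(spec)) {
    trend <- match.arg(trend)
    seasonal <- match.arg(seasonal)
    hs <- if (harmonics >= 1) make_harmonics(period, harmonics) else NULL
    spec <- uc_spec(trend = trend,
                    seasonal = if (is.null(hs)) NULL else tvp_model(seasonal),
                    harmonics = hs, sigma2 = sigma2)
  }
  lay <- state_layout(spec)
  n <- length(series$times)
  if (n <= lay$m)
    stop(sprintf("series has %d observations but the state dimension is %d", n, lay$m))

  hyper <- NULL
  if (is.null(nvr)) {
    hyper <- estimate_hyperparameters(series, spec, sigma2 = sigma2,
                                      method = match.arg(method))
    nvr <- hyper$nvr
    sigma2 <- hyper$sigma2
  } else {
    if (length(nvr) == 1L && is.null(names(nvr))) nvr <- c(trend = nvr, seasonal = nvr)
  }
  ctx <- filter_context(series, spec)
  nvu <- expand_nvrs(spec, nvr)
  if (is.null(sigma2)) {
    lite <- diffuse_fit(ctx, nvu, 1, lite = TRUE)
    sigma2 <- lite$quad / (lite$no - lite$q)
  }

  sm <- diffuse_fit(ctx, nvu, sigma2)
  comp <- extract_components(sm)
  fitted <- comp$trend + comp$seasonal
  resid <- series$values - fitted

  edf <- effective_dof_diffuse(ctx, nvu, sigma2)
  gof <- gof_stats(series$values, resid, edf)

  z <- stats::qnorm((1 + level) / 2)
  band <- data.frame(
    time = series$times,
    fit_lo = fitted - z * sqrt(pmax(comp$var_fit, 0)),
    fit_hi = fitted + z * sqrt(pmax(comp$var_fit, 0)),
    seas_lo = comp$seasonal - z * sqrt(pmax(comp$var_seasonal, 0)),
    seas_hi = comp$seasonal + z * sqrt(pmax(comp$var_seasonal, 0)))

  structure(list(
    series = series, spec = spec, nvr = nvr, sigma2 = sigma2,
    logLik = sm$loglik, n = n,
    trend = data.frame(time = series$times, estimate = comp$trend,
                       var = comp$var_trend),
    seasonal = data.frame(time = series$times, estimate = comp$seasonal,
                          var = comp$var_seasonal),
    tvp = comp$tvp,
    fitted = fitted, var_fitted = comp$var_fit, residuals = resid,
    r.squared = gof$r_squared,
    fstatistic = c(value = gof$f_statistic, numdf = gof$numdf, dendf = gof$dendf),
    f.pvalue = gof$f_pvalue, edf = edf, level = level, band = band,
    hyper = hyper, call = cl), class = "asdhr")
}

# Internal: pull trend/seasonal/TVP paths with variances out of a smoother run.
extract_components <- function(sm) {
  lay <- state_layout(sm$spec)
  n <- length(sm$times)
  m <- lay$m
  trend <- var_trend <- numeric(n)
  seasonal <- var_seasonal <- var_fit <- numeric(n)
  for (k in seq_len(n)) {
    P <- matrix(sm$Ps[, , k], m, m)
    h <- sm$H[k, ]
    hs <- observation_vector(sm$times[k], sm$spec, seasonal_only = TRUE)
    if (!is.na(lay$trend_level)) {
      trend[k] <- sm$xs[k, lay$trend_level]
      var_trend[k] <- P[lay$trend_level, lay$trend_level]
    }
    seasonal[k] <- sum(hs * sm$xs[k, ])
    var_seasonal[k] <- drop(hs %*% P %*% hs)
    var_fit[k] <- drop(h %*% P %*% h)
  }
  tvp <- list()
  if (!is.null(sm$spec$harmonics)) {
    for (i in seq_len(sm$spec$harmonics$n_harmonics)) {
      ua <- Filter(function(u) u$group == "seasonal" && u$harmonic == i &&
                     u$role == "a", lay$units)[[1L]]
      ub <- Filter(function(u) u$group == "seasonal" && u$harmonic == i &&
                     u$role == "b", lay$units)[[1L]]
      tvp[[i]] <- data.frame(
        time = sm$times,
        a = sm$xs[, ua$level], var_a = sm$Ps[ua$level, ua$level, ],
        b = sm$xs[, ub$level], var_b = sm$Ps[ub$level, ub$level, ])
    }
  }
  list(trend = trend, var_trend = var_trend, seasonal = seasonal,
       var_seasonal = var_seasonal, var_fit = var_fit, tvp = tvp)
}

# Internal: R^2, F and its p-value from residuals and effective dof.
gof_stats <- function(y, resid, edf) {
  n <- length(y)
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  if (n <= edf)
    stop(sprintf("underdetermined fit: n = %d observations but effective dof = %.2f",
                 n, edf))
  numdf <- edf - 1
  dendf <- n - edf
  f <- if (sse > 0) ((sst - sse) / numdf) / (sse / dendf) else Inf
  p <- stats::pf(f, numdf, dendf, lower.tail = FALSE)
  list(r_squared = r2, f_statistic = f, f_pvalue = p, numdf = numdf, dendf = dendf)
}

#' Goodness-of-fit statistics for an ASDHR fit
#'
#' Recomputes \eqn{R^2 = 1 - \sum \hat e^2 / \sum (y-\bar y)^2}, the F
#' statistic \eqn{F = [(SST - SSE)/(p^*-1)] / [SSE/(n-p^*)]} with
#' \eqn{p^*} the effective model degrees of freedom (trace of the smoother
#' influence map), and its p-value on \eqn{(p^*-1, n-p^*)} degrees of
#' freedom.
#'
#' @param fit An `"asdhr"` object.
#' @return List with `r_squared`, `f_statistic`, `f_pvalue`,
#'   `effective_dof`, `sigma2`, `loglik` and `n`.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "asdhr"))
  g <- gof_stats(fit$series$values, fit$residuals, fit$edf)
  list(r_squared = g$r_squared, f_statistic = g$f_statistic,
       f_pvalue = g$f_pvalue, effective_dof = fit$edf,
       sigma2 = fit$sigma2, loglik = fit$logLik, n = fit$n)
}

#' Pointwise confidence bands for the fit and the seasonal component
#'
#' Bands are `estimate +/- z * se` with `z` the Gaussian quantile at
#' `(1 + level)/2` and the standard error from the smoothed state
#' covariance propagated through the observation row (seasonal sub-row for
#' the seasonal band).
#'
#' @param fit An `"asdhr"` object.
#' @param level Confidence level in (0, 1).
#' @return Data frame: `time`, `fit`, `fit_lo`, `fit_hi`, `seasonal`,
#'   `seas_lo`, `seas_hi`.
#' @export
confidence_band <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "asdhr"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("`level` must lie strictly between 0 and 1")
  z <- stats::qnorm((1 + level) / 2)
  se_fit <- sqrt(pmax(fit$var_fitted, 0))
  se_s <- sqrt(pmax(fit$seasonal$var, 0))
  data.frame(time = fit$series$times,
             fit = fit$fitted,
             fit_lo = fit$fitted - z * se_fit,
             fit_hi = fit$fitted + z * se_fit,
             seasonal = fit$seasonal$estimate,
             seas_lo = fit$seasonal$estimate - z * se_s,
             seas_hi = fit$seasonal$estimate + z * se_s)
}

#' Predict components at arbitrary instants
#'
#' Propagates and interpolates the smoothed state through the same
#' continuous-time transition law used in fitting, by augmenting the time
#' grid with unobserved instants (no measurement update) and re-running the
#' filter/smoother at the estimated hyperparameters. At observed instants
#' the result equals the fitted components.
#'
#' @param object An `"asdhr"` object.
#' @param times Instants (decimal years) at which to predict; defaults to
#'   the sample instants.
#' @param ... Unused.
#' @return Data frame: `time`, `trend`, `trend_var`, `seasonal`,
#'   `seasonal_var`, `fit`, `fit_var`.
#' @export
predict.asdhr <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$series$times
  if (any(!is.finite(times))) stop("`times` must be finite")
  all_t <- sort(unique(c(object$series$times, as.numeric(times))))
  y_all <- rep(NA_real_, length(all_t))
  y_all[match(object$series$times, all_t)] <- object$series$values
  ctx <- filter_context(
    structure(list(times = all_t, values = y_all, label = ""),
              class = "irregular_series"), object$spec)
  sm <- diffuse_fit(ctx, expand_nvrs(object$spec, object$nvr), object$sigma2)
  comp <- extract_components(sm)
  sel <- match(as.numeric(times), all_t)
  data.frame(time = all_t[sel],
             trend = comp$trend[sel], trend_var = comp$var_trend[sel],
             seasonal = comp$seasonal[sel], seasonal_var = comp$var_seasonal[sel],
             fit = comp$trend[sel] + comp$seasonal[sel],
             fit_var = comp$var_fit[sel])
}

#' @export
print.asdhr <- function(x, ...) {
  cat("Arbitrary-sampled dynamic harmonic regression\n")
  if (!is.null(x$spec$harmonics))
    cat(sprintf("  %d harmonic(s), fundamental period %.4g yr; trend: %s\n",
                x$spec$harmonics$n_harmonics,
                x$spec$harmonics$fundamental_period,
                if (is.null(x$spec$trend)) "none" else x$spec$trend$kind))
  cat(sprintf("  n = %d, R-squared = %.4f, F(%.2f, %.2f) = %.3f, p = %.3g\n",
              x$n, x$r.squared, x$fstatistic["numdf"], x$fstatistic["dendf"],
              x$fstatistic["value"], x$f.pvalue))
  cat("  NVR:", paste(sprintf("%s = %.4g", names(x$nvr), x$nvr), collapse = ", "),
      sprintf("; sigma2_e = %.4g\n", x$sigma2))
  invisible(x)
}

#' @export
summary.asdhr <- function(object, ...) {
  structure(list(
    call = object$call, n = object$n, nvr = object$nvr, sigma2 = object$sigma2,
    loglik = object$logLik, r.squared = object$r.squared,
    fstatistic = object$fstatistic, f.pvalue = object$f.pvalue,
    edf = object$edf, level = object$level,
    resid_summary = summary(object$residuals),
    spec = object$spec), class = "summary.asdhr")
}

#' @export
print.summary.asdhr <- function(x, ...) {
  cat("Call:\n  ")
  print(x$call)
  cat("\nResiduals:\n")
  print(x$resid_summary)
  cat(sprintf("\nR-squared: %.4f   effective dof: %.2f\n", x$r.squared, x$edf))
  cat(sprintf("F(%.2f, %.2f) = %.4f,  p-value = %.4g\n",
              x$fstatistic["numdf"], x$fstatistic["dendf"],
              x$fstatistic["value"], x$f.pvalue))
  cat(sprintf("log-likelihood: %.4f   sigma2_e: %.5g\n", x$loglik, x$sigma2))
  cat("NVR estimates:\n")
  print(x$nvr)
  invisible(x)
}

#' @export
coef.asdhr <- function(object, ...) {
  c(stats::setNames(object$nvr, paste0("nvr_", names(object$nvr))),
    sigma2 = object$sigma2)
}

#' @export
fitted.asdhr <- function(object, ...) object$fitted

#' @export
residuals.asdhr <- function(object, ...) object$residuals

#' @export
logLik.asdhr <- function(object, ...) {
  structure(object$logLik, df = object$edf, nobs = object$n, class = "logLik")
}

#' Simulate series from a fitted ASDHR model
#'
#' Draws new observation vectors at the sample instants by propagating the
#' state forward from the smoothed initial state with the estimated process
#' and observation noise.
#'
#' @param object An `"asdhr"` object.
#' @param nsim Number of simulated series.
#' @param seed Optional seed handled as in [stats::simulate()].
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated values.
#' @export
simulate.asdhr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tt <- object$series$times
  n <- length(tt)
  lay <- state_layout(object$spec)
  m <- lay$m
  ctx <- filter_context(object$series, object$spec)
  sm <- diffuse_fit(ctx, expand_nvrs(object$spec, object$nvr), object$sigma2)
  out <- matrix(NA_real_, n, nsim)
  for (s in seq_len(nsim)) {
    x <- sm$xs[1L, ]
    for (k in seq_len(n)) {
      if (k > 1L) {
        ts <- transition_system(tt[k] - tt[k - 1L], object$spec, object$nvr,
                                object$sigma2)
        ev <- eigen(sym(ts$Q), symmetric = TRUE)
        L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), m)
        x <- drop(ts$A %*% x) + drop(L %*% stats::rnorm(m))
      }
      out[k, s] <- sum(sm$H[k, ] * x) + stats::rnorm(1, 0, sqrt(object$sigma2))
    }
  }
  as.data.frame(out)
}

#' Plot an ASDHR fit
#'
#' Base-graphics plot of the data, the smoothed fit with its confidence
#' band, and optionally the seasonal component with its band.
#'
#' @param x An `"asdhr"` object.
#' @param which `"fit"`, `"seasonal"`, or both.
#' @param ... Passed to [plot.default()].
#' @return `x`, invisibly.
#' @export
plot.asdhr <- function(x, which = c("fit", "seasonal"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tt <- x$series$times
  if ("fit" %in% which) {
    graphics::plot(tt, x$series$values, pch = 16, cex = 0.6,
                   xlab = "time (decimal years)",
                   ylab = if (nzchar(x$series$label)) x$series$label else "y",
                   main = sprintf("ASDHR fit (R² = %.2f, %d%% band)",
                                  x$r.squared, round(100 * x$level)), ...)
    graphics::polygon(c(tt, rev(tt)), c(x$band$fit_lo, rev(x$band$fit_hi)),
                      col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
    graphics::lines(tt, x$fitted, col = "steelblue4", lwd = 2)
  }
  if ("seasonal" %in% which) {
    graphics::plot(tt, x$seasonal$estimate, type = "n",
                   ylim = range(x$band$seas_lo, x$band$seas_hi),
                   xlab = "time (decimal years)", ylab = "seasonal component",
                   main = "Smoothed seasonal component")
    graphics::polygon(c(tt, rev(tt)), c(x$band$seas_lo, rev(x$band$seas_hi)),
                      col = grDevices::adjustcolor("darkorange", 0.3), border = NA)
    graphics::lines(tt, x$seasonal$estimate, col = "darkorange3", lwd = 2)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Write a fitted decomposition to CSV
#'
#' Columns: `date`, `time`, `y`, `trend`, `seasonal`, `fitted`, `resid`,
#' and the band columns `fitted_lo<level>`/`fitted_hi<level>` (e.g.
#' `fitted_lo95` for the default 95% level).
#'
#' @param fit An `"asdhr"` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(fit, path) {
  stopifnot(inherits(fit, "asdhr"))
  df <- data.frame(date = date_from_decimal(fit$series$times),
                   time = fit$series$times,
                   y = fit$series$values,
                   trend = fit$trend$estimate,
                   seasonal = fit$seasonal$estimate,
                   fitted = fit$fitted,
                   resid = fit$residuals,
                   lo = fit$band$fit_lo,
                   hi = fit$band$fit_hi)
  lv <- round(100 * fit$level)
  names(df)[names(df) == "lo"] <- sprintf("fitted_lo%d", lv)
  names(df)[names(df) == "hi"] <- sprintf("fitted_hi%d", lv)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Summarise a fit as a JSON string
#'
#' @param fit An `"asdhr"` object.
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
fit_summary_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "asdhr"))
  s <- list(nvrs = as.list(fit$nvr), sigma2_e = fit$sigma2,
            loglik = fit$logLik, r_squared = fit$r.squared,
            f_statistic = unname(fit$fstatistic["value"]),
            f_pvalue = fit$f.pvalue, effective_dof = fit$edf, n = fit$n)
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
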