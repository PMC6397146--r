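# Named substreams: each variable draws from its own derived seed so adding
# a variable never perturbs existing draws. Derived seeds stay below 2^31.
substream_seed <- function(seed, stream) {
  offsets <- c(jitter = 11L, amplitude = 23L, noise = 37L, counts = 51L,
               rainfall = 63L, temperature = 77L, radiation = 89L,
               oxygen = 101L, ph = 113L, conductivity = 127L,
               nitrate = 139L, trp = 151L, turbidity = 163L, dates = 177L)
  if (!stream %in% names(offsets)) stop("unknown substream: ", stream)
  as.integer((as.numeric(seed) * 1009 + offsets[[stream]]) %% 2147483647)
}

#' Simulate an irregular seasonal EQR-like series with ground truth
#'
#' Emulates several years of mid-monthly ecological-quality observations:
#' sample instants are mid-month plus a uniform jitter of up to 5 days; the
#' signal is `trend + a_t cos(2*pi*t) + b_t sin(2*pi*t)` where `a_t, b_t`
#' drift as random walks around an initial amplitude of 0.2 about a level
#' of 0.7 (an EQR-like range straddling the good/moderate boundary);
#' Gaussian observation noise has variance `noise_frac` times the signal
#' variance. Values are clipped to `[0, 1.25]` with clip events logged in
#' the truth sidecar.
#'
#' @param n_years Series span in years (>= 1; default 5.5, i.e. 66
#'   mid-monthly samples).
#' @param seed Integer seed; every draw is reproducible bit-for-bit.
#' @param amp_drift_sd Random-walk step of the harmonic coefficients, in
#'   EQR units per sqrt(year) (default 0.05).
#' @param noise_frac Observation-noise variance as a fraction of signal
#'   variance, strictly in (0, 1).
#' @param trend_slope Linear trend slope in EQR units per year.
#' @param start_year First calendar year of sampling.
#' @param level Mean level of the series.
#' @param amplitude Initial seasonal amplitude.
#' @param phase_peak Year fraction of the initial seasonal peak
#'   (default 0.54, mid-July).
#' @return List with `series` (an [irregular_series()]) and `truth`
#'   (times, trend, `a`/`b` coefficient paths, seasonal path, `noise_sd`,
#'   indices of clipped values, the seed and all parameters).
#' @export
gen_eqr_series <- function(n_years = 5.5, seed = 1, amp_drift_sd = 0.05,
                           noise_frac = 0.15, trend_slope = 0,
                           start_year = 2011, level = 0.7, amplitude = 0.2,
                           phase_peak = 0.54) {
  if (!is.numeric(n_years) || n_years < 1) stop("`n_years` must be >= 1")
  if (!is.numeric(noise_frac) || noise_frac <= 0 || noise_frac >= 1)
    stop("`noise_frac` must lie strictly in (0, 1)")
  if (amp_drift_sd < 0) stop("`amp_drift_sd` must be >= 0")
  n <- floor(12 * n_years)

  set.seed(substream_seed(seed, "jitter"))
  tt <- start_year + (seq_len(n) - 0.5) / 12 +
    stats::runif(n, -5, 5) / 365.2425
  tt <- sort(tt)

  set.seed(substream_seed(seed, "amplitude"))
  a <- b <- numeric(n)
  a[1] <- amplitude * cos(2 * pi * phase_peak)
  b[1] <- amplitude * sin(2 * pi * phase_peak)
  if (n > 1) for (k in 2:n) {
    dt <- tt[k] - tt[k - 1]
    a[k] <- a[k - 1] + stats::rnorm(1, 0, amp_drift_sd * sqrt(dt))
    b[k] <- b[k - 1] + stats::rnorm(1, 0, amp_drift_sd * sqrt(dt))
  }
  trend <- level + trend_slope * (tt - tt[1])
  seasonal <- a * cos(2 * pi * tt) + b * sin(2 * pi * tt)
  signal <- trend + seasonal

  noise_sd <- sqrt(noise_frac * stats::var(signal))
  set.seed(substream_seed(seed, "noise"))
  noise <- stats::rnorm(n, 0, noise_sd)
  y <- signal + noise
  clipped <- which(y < 0 | y > 1.25)
  if (length(clipped))
    message(sprintf("gen_eqr_series: clipped %d value(s) to [0, 1.25]",
                    length(clipped)))
  y <- pmin(pmax(y, 0), 1.25)

  list(series = irregular_series(tt, y, "synthetic EQR"),
       truth = list(times = tt, trend = trend, a = a, b = b,
                    seasonal = seasonal, noise = noise, noise_sd = noise_sd,
                    clipped = clipped, seed = seed,
                    params = list(n_years = n_years, amp_drift_sd = amp_drift_sd,
                                  noise_frac = noise_frac,
                                  trend_slope = trend_slope, level = level,
                                  amplitude = amplitude,
                                  phase_peak = phase_peak)))
}

#' Default seasonal assemblage pools
#'
#' Composition of the "summer" pool (dominated by the low-sensitivity
#' pioneer ACHMIN) and the "winter" pool (dominated by the
#' nutrient-associated AMPPED with motile-guild taxa), over the taxa of the
#' bundled synthetic trait table.
#'
#' @return List with proportion vectors `summer` and `winter` (each sums
#'   to 1).
#' @export
default_pools <- function() {
  summer <- c(ACHMIN = 0.52, GOMOLI = 0.10, ENCMIN = 0.08, MERCIR = 0.06,
              RHOABB = 0.06, SURCRU = 0.05, AMPPED = 0.05, GOMPAR = 0.03,
              COCEUG = 0.03, NAVCRY = 0.02)
  winter <- c(AMPPED = 0.38, NAVLAN = 0.15, COCEUG = 0.10, NAVCRY = 0.10,
              CALBAC = 0.08, GOMPAR = 0.07, ACHMIN = 0.10, RHOABB = 0.02)
  list(summer = summer / sum(summer), winter = winter / sum(winter))
}

#' Simulate seasonal valve-count assemblages with ground truth
#'
#' For each sample date, a mixing weight
#' `w(t) = (1 + cos(2*pi*(t - t_peak))) / 2` blends a summer and a winter
#' taxon pool (`w = 1` at the summer peak); counts are drawn multinomially
#' with a fixed total per sample (300 valves by default, the standard
#' counting convention).
#'
#' @param dates `Date` vector of sample dates.
#' @param seed Integer seed.
#' @param total_valves Valves counted per sample.
#' @param summer_pool,winter_pool Named proportion vectors over the taxa of
#'   the trait table (defaults from [default_pools()]).
#' @param t_peak Year fraction of the summer-community peak.
#' @param fixed_weight Optional scalar in `[0, 1]` forcing the mixing
#'   weight at every date (e.g. `1` = all-summer), for calibration checks.
#' @return List with `counts` (a [count_matrix()]) and `truth` (per-date
#'   mixing weights, pools, seed).
#' @export
gen_counts <- function(dates, seed = 1, total_valves = 300,
                       summer_pool = NULL, winter_pool = NULL,
                       t_peak = 0.54, fixed_weight = NULL) {
  dates <- as.Date(dates)
  pools <- default_pools()
  if (is.null(summer_pool)) summer_pool <- pools$summer
  if (is.null(winter_pool)) winter_pool <- pools$winter
  traits <- default_trait_table()
  for (p in list(summer_pool, winter_pool)) {
    if (is.null(names(p)) || !all(names(p) %in% traits$taxon))
      stop("pool schema error: pool taxa must be named and covered by the trait table")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("pool schema error: pool proportions must be non-negative and sum to 1")
  }
  taxa <- sort(unique(c(names(summer_pool), names(winter_pool))))
  sp <- stats::setNames(numeric(length(taxa)), taxa)
  wp <- sp
  sp[names(summer_pool)] <- summer_pool
  wp[names(winter_pool)] <- winter_pool

  t <- decimal_year(dates)
  w <- if (is.null(fixed_weight)) (1 + cos(2 * pi * (t - t_peak))) / 2
       else rep(fixed_weight, length(t))
  set.seed(substream_seed(seed, "counts"))
  cm <- matrix(0L, length(dates), length(taxa), dimnames = list(NULL, taxa))
  for (i in seq_along(dates)) {
    probs <- w[i] * sp + (1 - w[i]) * wp
    cm[i, ] <- as.integer(stats::rmultinom(1, total_valves, probs))
  }
  list(counts = count_matrix(dates, cm),
       truth = list(dates = dates, mixing_weight = w, t_peak = t_peak,
                    summer_pool = sp, winter_pool = wp,
                    total_valves = total_valves, seed = seed))
}

#' Simulate 15-minute environmental sensor series with ground truth
#'
#' Event-driven synthetic hydrochemistry: rainfall is a marked
#' winter-weighted point process; discharge is seasonal baseflow plus a
#' linear-reservoir convolution of rainfall; total reactive phosphorus and
#' turbidity respond to positive discharge increments (event-driven
#' transfer); water temperature combines annual and diel sinusoids; net
#' radiation is an annual cycle truncated at zero under a diel envelope;
#' dissolved oxygen, pH and conductivity are seasonal sinusoids with noise.
#'
#' @param start,end `Date` (or POSIXct) limits of the record, `end > start`.
#' @param seed Integer seed.
#' @param step_min Cadence in minutes (default 15).
#' @param rain_event_prob Baseline per-step rain probability (0 disables
#'   rainfall, leaving discharge equal to baseflow).
#' @param rain_mean_depth Mean event depth, mm per step.
#' @param reservoir_hours Linear-reservoir time constant, hours.
#' @return List with `sensor` (a [sensor_series()] of rainfall, discharge,
#'   trp, nitrate_n, temperature, radiation, oxygen, ph, turbidity,
#'   conductivity) and `truth` (event timestamps, baseflow and transfer
#'   parameters, seed).
#' @export
gen_sensor <- function(start, end, seed = 1, step_min = 15,
                       rain_event_prob = 0.015, rain_mean_depth = 0.5,
                       reservoir_hours = 12) {
  t0 <- as.POSIXct(format(as.Date(start)), tz = "UTC")
  t1 <- as.POSIXct(format(as.Date(end)), tz = "UTC")
  if (t1 <= t0) stop("`end` must be after `start`")
  ts <- seq(t0, t1, by = step_min * 60)
  n <- length(ts)
  lt <- as.POSIXlt(ts)
  tfrac <- (lt$yday + (lt$hour + lt$min / 60) / 24) / 365.2425
  hour <- lt$hour + lt$min / 60

  # rainfall: winter-weighted marked point process (peak around Jan 1)
  set.seed(substream_seed(seed, "rainfall"))
  p_event <- pmin(0.9, rain_event_prob * (1 + 0.7 * cos(2 * pi * tfrac)))
  occur <- stats::rbinom(n, 1, p_event)
  depth <- stats::rexp(n, rate = 1 / rain_mean_depth)
  rainfall <- occur * depth

  # discharge: seasonal baseflow + linear reservoir routing of rainfall
  # (one-step routing delay so the hydrograph lags the hyetograph)
  alpha <- exp(-(step_min / 60) / reservoir_hours)
  storage <- as.numeric(stats::filter(c(0, rainfall[-n]), alpha,
                                      method = "recursive"))
  baseflow <- 0.12 * (1 + 0.6 * cos(2 * pi * tfrac))
  discharge <- baseflow + 0.08 * storage

  dq <- pmax(c(0, diff(discharge)), 0)  # positive discharge increments

  set.seed(substream_seed(seed, "trp"))
  trp <- pmax(0.02 + 0.4 * dq + stats::rnorm(n, 0, 0.002), 0.001)
  set.seed(substream_seed(seed, "turbidity"))
  turbidity <- pmax(2 + 600 * dq + abs(stats::rnorm(n, 0, 0.5)), 0.1)
  set.seed(substream_seed(seed, "nitrate"))
  nitrate_n <- pmax(1.5 + 0.6 * cos(2 * pi * tfrac) + stats::rnorm(n, 0, 0.05), 0.01)
  set.seed(substream_seed(seed, "temperature"))
  temperature <- 9 + 5.5 * cos(2 * pi * (tfrac - 0.55)) +
    1.5 * cos(2 * pi * (hour - 15) / 24) + stats::rnorm(n, 0, 0.3)
  set.seed(substream_seed(seed, "radiation"))
  annual <- 140 * cos(2 * pi * (tfrac - 0.54)) + 60
  diel <- pmax(0, cos(2 * pi * (hour - 13) / 24))
  radiation <- pmax(pmax(annual, 0) * diel * 2 +
                      stats::rnorm(n, 0, 5) * (diel > 0), 0)
  set.seed(substream_seed(seed, "oxygen"))
  oxygen <- 100 + 12 * cos(2 * pi * (tfrac - 0.45)) + stats::rnorm(n, 0, 2)
  set.seed(substream_seed(seed, "ph"))
  ph <- 7.8 + 0.25 * cos(2 * pi * (tfrac - 0.5)) + stats::rnorm(n, 0, 0.05)
  set.seed(substream_seed(seed, "conductivity"))
  conductivity <- 240 + 50 * cos(2 * pi * (tfrac - 0.6)) + stats::rnorm(n, 0, 5)

  units <- c(rainfall = "mm", discharge = "m3 s-1", trp = "mg P L-1",
             nitrate_n = "mg N L-1", temperature = "degC",
             radiation = "W m-2", oxygen = "%", ph = "pH units",
             turbidity = "NTU", conductivity = "uS cm-1")
  sensor <- sensor_series(
    ts,
    data.frame(rainfall = rainfall, discharge = discharge, trp = trp,
               nitrate_n = nitrate_n, temperature = temperature,
               radiation = radiation, oxygen = oxygen, ph = ph,
               turbidity = turbidity, conductivity = conductivity),
    units = units, step_min = step_min)
  list(sensor = sensor,
       truth = list(event_times = ts[occur == 1], seed = seed,
                    baseflow = list(level = 0.12, seasonal_gain = 0.6),
                    reservoir_hours = reservoir_hours,
                    rain_event_prob = rain_event_prob,
                    rain_mean_depth = rain_mean_depth,
                    transfer = list(trp = 0.4, turbidity = 600)))
}

#' Mid-monthly sample dates with jitter
#'
#' Calendar dates for a mid-monthly sampling campaign: the 14th of each
#' month plus a uniform jitter of up to 5 days, reproducible by seed.
#'
#' @param n_years Span in years.
#' @param seed Integer seed.
#' @param start First month (`Date`; day is ignored).
#' @return A `Date` vector of `floor(12 * n_years)` dates.
#' @export
gen_sample_dates <- function(n_years = 5.5, seed = 1,
                             start = as.Date("2011-03-01")) {
  n <- floor(12 * n_years)
  first <- seq(as.Date(format(as.Date(start), "%Y-%m-01")), by = "month",
               length.out = n)
  set.seed(substream_seed(seed, "dates"))
  sort(first + 13L + sample(-5:5, n, replace = TRUE))
}

#' Write a synthetic truth sidecar as JSON
#'
#' Every generated dataset is paired with its ground truth; this writes the
#' truth list alongside the data so recovery tests can load it.
#'
#' @param truth Truth list from a generator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  truth <- rapply(truth, function(x) {
    if (inherits(x, "Date") || inherits(x, "POSIXt")) format(x) else x
  }, how = "replace")
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}
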