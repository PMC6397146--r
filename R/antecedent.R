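#' High-frequency environmental sensor series
#'
#' Container for nominally 15-minute sensor records: a strictly increasing
#' timestamp column plus one numeric column per variable. Gaps are allowed;
#' units travel as an attribute.
#'
#' @param timestamps `POSIXct` (or ISO-8601 character) timestamps.
#' @param data Data frame or matrix of variables, one row per timestamp.
#' @param units Optional named character vector of units.
#' @param step_min Nominal cadence in minutes (metadata; default 15).
#' @return Object of class `"sensor_series"`: a data frame with column
#'   `timestamp` plus the variables, attributes `units` and `step_min`.
#' @export
sensor_series <- function(timestamps, data, units = NULL, step_min = 15) {
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  if (anyNA(timestamps)) stop("timestamps must parse")
  if (is.unsorted(as.numeric(timestamps), strictly = TRUE))
    stop("timestamps must be strictly increasing")
  data <- as.data.frame(data)
  if (nrow(data) != length(timestamps))
    stop("`data` must have one row per timestamp")
  out <- cbind(data.frame(timestamp = timestamps), data)
  attr(out, "units") <- units
  attr(out, "step_min") <- step_min
  class(out) <- c("sensor_series", "data.frame")
  out
}

#' Read a sensor series from CSV
#'
#' Expects a `timestamp` column (ISO-8601) plus one column per variable;
#' units may be supplied in a sidecar JSON file mapping variable -> unit.
#'
#' @param path CSV file path.
#' @param units_path Optional path to a JSON units sidecar.
#' @return A [sensor_series()].
#' @export
read_sensor_csv <- function(path, units_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(df)) stop("sensor CSV needs a `timestamp` column")
  units <- if (!is.null(units_path))
    unlist(jsonlite::fromJSON(units_path)) else NULL
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))
  sensor_series(ts, df[, setdiff(names(df), "timestamp"), drop = FALSE],
                units = units)
}

#' Write a sensor series to CSV
#' @param x A [sensor_series()].
#' @param path Output path.
#' @param units_path Optional path for the JSON units sidecar.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(x, path, units_path = NULL) {
  df <- as.data.frame(x)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(units_path) && !is.null(attr(x, "units")))
    writeLines(jsonlite::toJSON(as.list(attr(x, "units")), auto_unbox = TRUE),
               units_path)
  invisible(path)
}

#' Antecedent-window mean for one sample date
#'
#' Arithmetic mean of readings falling in the half-open backward window
#' `[sample_date - window_days, sample_date)` — the sampling instant itself
#' is excluded, since antecedent conditions strictly precede collection.
#' Coverage is observed readings over the expected count for a 15-minute
#' cadence (`window_days * 96`); a variable below `min_coverage` is
#' reported absent with a warning, never imputed.
#'
#' @param sensor A [sensor_series()].
#' @param sample_date `Date` or `POSIXct` of the biological sample.
#' @param window_days Window length in days (default 21).
#' @param min_coverage Minimum coverage fraction for a mean to be reported.
#' @return List: `date`, named `mean` vector (NA where coverage failed) and
#'   named `coverage` vector.
#' @export
antecedent_mean <- function(sensor, sample_date, window_days = 21,
                            min_coverage = 0.5) {
  stopifnot(inherits(sensor, "sensor_series"))
  if (!is.numeric(window_days) || window_days <= 0)
    stop("`window_days` must be positive")
  t1 <- as.POSIXct(sample_date, tz = "UTC")
  if (inherits(sample_date, "Date"))
    t1 <- as.POSIXct(format(sample_date), tz = "UTC")
  if (t1 <= sensor$timestamp[1L])
    stop("no data: sample date ", format(t1), " is not after the first sensor record")
  t0 <- t1 - window_days * 86400
  inwin <- sensor$timestamp >= t0 & sensor$timestamp < t1
  vars <- setdiff(names(sensor), "timestamp")
  expected <- window_days * 96
  mn <- cv <- stats::setNames(rep(NA_real_, length(vars)), vars)
  for (v in vars) {
    x <- sensor[[v]][inwin]
    x <- x[!is.na(x)]
    cv[v] <- length(x) / expected
    if (cv[v] >= min_coverage) {
      mn[v] <- mean(x)
    } else {
      warning(sprintf("coverage %.2f below %.2f for %s in the window before %s; mean omitted",
                      cv[v], min_coverage, v, format(t1)))
    }
  }
  list(date = sample_date, mean = mn, coverage = cv)
}

#' Logarithmic transform log(a*x + b)
#'
#' Natural log of the affine-shifted values, the transform applied to
#' right-skewed variables (turbidity, rainfall, discharge) and to species
#' abundances before ordination. Defaults `a = 1, b = 1` give `log(x + 1)`.
#'
#' @param values Numeric vector/matrix.
#' @param a,b Affine constants; `a*x + b` must be strictly positive.
#' @return Transformed values, same shape.
#' @export
#' @examples
#' log_transform(0)        # 0
#' log_transform(exp(1) - 1)  # 1
log_transform <- function(values, a = 1, b = 1) {
  z <- a * values + b
  if (any(!is.na(z) & z <= 0)) {
    bad <- utils::head(unique(values[!is.na(z) & z <= 0]), 5L)
    stop("log transform domain error: a*x + b <= 0 for values ",
         paste(signif(bad, 6), collapse = ", "))
  }
  log(z)
}

#' Antecedent environmental matrix aligned to sample dates
#'
#' Computes the antecedent-window mean of every sensor variable for each
#' biological sample date, applies [log_transform()] to the configured
#' right-skewed variables, and returns a samples x variables matrix aligned
#' to the diatom sampling dates. Dates whose window precedes the sensor
#' record are dropped with a warning; if nothing remains an error is
#' raised.
#'
#' @param sensor A [sensor_series()].
#' @param sample_dates `Date` vector of biological sample dates.
#' @param window_days,min_coverage As in [antecedent_mean()].
#' @param log_vars Variables to log-transform (default turbidity, rainfall,
#'   discharge).
#' @param log_a,log_b Constants of the log transform.
#' @return Data frame (rownames = ISO dates) of per-variable means, with a
#'   `coverage` matrix attribute.
#' @export
build_env_matrix <- function(sensor, sample_dates, window_days = 21,
                             min_coverage = 0.5,
                             log_vars = c("turbidity", "rainfall", "discharge"),
                             log_a = 1, log_b = 1) {
  stopifnot(inherits(sensor, "sensor_series"))
  sample_dates <- as.Date(sample_dates)
  if (length(sample_dates) < 1L) stop("need at least one sample date")
  vars <- setdiff(names(sensor), "timestamp")
  rows <- vector("list", length(sample_dates))
  keep <- rep(TRUE, length(sample_dates))
  for (i in seq_along(sample_dates)) {
    res <- tryCatch(
      antecedent_mean(sensor, sample_dates[i], window_days, min_coverage),
      error = function(e) NULL)
    if (is.null(res)) keep[i] <- FALSE else rows[[i]] <- res
  }
  if (any(!keep))
    warning(sprintf("dropped %d sample date(s) outside the sensor record: %s",
                    sum(!keep), paste(format(sample_dates[!keep]), collapse = ", ")))
  if (!any(keep)) stop("empty output: no sample date has usable sensor data")
  m <- do.call(rbind, lapply(rows[keep], function(r) r$mean[vars]))
  cov <- do.call(rbind, lapply(rows[keep], function(r) r$coverage[vars]))
  if (all(is.na(m))) stop("empty output: every variable failed the coverage threshold")
  out <- as.data.frame(m)
  names(out) <- vars
  rownames(out) <- rownames(cov) <- format(sample_dates[keep])
  for (v in intersect(log_vars, vars)) out[[v]] <- log_transform(out[[v]], log_a, log_b)
  attr(out, "coverage") <- cov
  attr(out, "log_vars") <- intersect(log_vars, vars)
  out
}
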