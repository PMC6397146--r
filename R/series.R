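#' Irregularly sampled time series
#'
#' Container for a univariate series observed at strictly increasing,
#' non-uniform instants measured in decimal years (e.g. `2011.204`).
#' Gaps are represented by absent instants, never by placeholder values.
#'
#' @param times Numeric vector of observation instants in decimal years,
#'   strictly increasing.
#' @param values Numeric vector of observations, same length as `times`.
#' @param label Optional free-text label (e.g. the metric name).
#'
#' @return An object of class `"irregular_series"`: a list with elements
#'   `times`, `values` and `label`.
#' @seealso [as_irregular_series()], [read_series_csv()], [asdhr()]
#' @export
#' @examples
#' s <- irregular_series(c(2011.2, 2011.3, 2011.45), c(0.7, 0.8, 0.75), "EQR")
#' length(s)
irregular_series <- function(times, values, label = "") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length")
  if (length(times) == 0L)
    stop("an irregular series needs at least one observation")
  if (anyNA(times) || any(!is.finite(times)))
    stop("`times` must be finite and non-missing")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite; represent gaps by dropping the instant, not by NA")
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing (duplicate or out-of-order instants found)")
  structure(list(times = times, values = values,
                 label = as.character(label)[1L]),
            class = "irregular_series")
}

#' Coerce to an irregular series
#'
#' Accepts an existing `irregular_series`, a two-column data frame
#' (time/date first, value second; dates are converted to decimal years),
#' or a numeric vector with a `times` argument.
#'
#' @param x Object to coerce.
#' @param times Optional times when `x` is a bare numeric vector.
#' @param label Optional label.
#' @return An `irregular_series`.
#' @export
as_irregular_series <- function(x, times = NULL, label = "") {
  if (inherits(x, "irregular_series")) return(x)
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("data frame input needs a time column and a value column")
    tcol <- x[[1L]]
    if (inherits(tcol, "Date") || inherits(tcol, "POSIXt") || is.character(tcol))
      tcol <- decimal_year(tcol)
    return(irregular_series(tcol, x[[2L]], label))
  }
  if (is.numeric(x)) {
    if (is.null(times)) stop("numeric input requires `times`")
    return(irregular_series(times, x, label))
  }
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to an irregular_series")
}

#' @export
length.irregular_series <- function(x) length(x$times)

#' @export
print.irregular_series <- function(x, ...) {
  cat(sprintf("Irregular series%s: %d observations, %.3f-%.3f\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.irregular_series <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}

#' Convert calendar dates to decimal years
#'
#' Days are placed at their midpoint within the year using the mean
#' Gregorian year length of 365.2425 days; time-of-day is honoured for
#' `POSIXt` input.
#'
#' @param d A `Date`, `POSIXt` or ISO-8601 character vector (numeric input
#'   is returned unchanged).
#' @return Numeric vector of decimal years.
#' @export
#' @examples
#' decimal_year(as.Date("2011-07-02"))
decimal_year <- function(d) {
  if (is.numeric(d)) return(as.numeric(d))
  if (is.character(d)) {
    d <- if (all(nchar(d) > 10L, na.rm = TRUE)) as.POSIXct(d, tz = "UTC") else as.Date(d)
  }
  lt <- as.POSIXlt(d, tz = "UTC")
  dayfrac <- if (inherits(d, "POSIXt"))
    (lt$hour + lt$min / 60 + lt$sec / 3600) / 24 else 0.5
  lt$year + 1900 + (lt$yday + dayfrac) / 365.2425
}

#' Convert decimal years back to calendar dates
#'
#' Approximate inverse of [decimal_year()]; resolves to whole days.
#'
#' @param t Numeric vector of decimal years.
#' @return A `Date` vector.
#' @export
date_from_decimal <- function(t) {
  yr <- floor(t)
  yd <- floor((t - yr) * 365.2425)
  as.Date(sprintf("%d-01-01", as.integer(yr))) + yd
}

#' Read an irregular series from CSV
#'
#' Expects a header and two columns: an ISO-8601 date (or decimal-year
#' number) and a value. Dates are converted to decimal years internally.
#'
#' @param path CSV file path.
#' @param label Optional label; defaults to the value column name.
#' @return An `irregular_series`.
#' @export
read_series_csv <- function(path, label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("series CSV needs two columns: date,value")
  as_irregular_series(df[, 1:2],
                      label = if (is.null(label)) names(df)[2L] else label)
}

#' Write an irregular series to CSV
#'
#' @param x An `irregular_series`.
#' @param path Output path.
#' @param date_col Write calendar dates (`TRUE`, default) or decimal years.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path, date_col = TRUE) {
  x <- as_irregular_series(x)
  df <- if (date_col)
    data.frame(date = date_from_decimal(x$times), value = x$values)
  else
    data.frame(time = x$times, value = x$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
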