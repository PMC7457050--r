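# Microclimate module: temperature-logger traces and frequency-of-time
# histograms that drive the carbon-balance model.

MOISTURE_CLASSES <- c("wet", "intermediate", "dry", "unknown")

#' Construct a canopy-surface temperature trace
#'
#' A `temperature_trace` holds a timestamped series of moss canopy-surface
#' temperatures from a single logger, with sensor/species/site/moisture
#' metadata. Timestamps must be strictly increasing and temperatures finite.
#'
#' @param timestamp `POSIXct` vector (or something coercible via
#'   [as.POSIXct()]), strictly increasing.
#' @param temperature_c numeric vector of surface temperatures in degrees C.
#' @param sensor_id,species,site character scalars; free-form metadata.
#' @param moisture one of `"wet"`, `"intermediate"`, `"dry"`, `"unknown"`.
#' @return An object of class `temperature_trace`: a data frame with columns
#'   `timestamp` and `temperature_c` plus metadata attributes.
#' @examples
#' tr <- temperature_trace(
#'   as.POSIXct("2003-01-16 00:00", tz = "UTC") + 3600 * 0:5,
#'   c(1.5, 1.0, 2.2, 6.0, 9.1, 7.3)
#' )
#' nrow(tr)
#' @export
temperature_trace <- function(timestamp, temperature_c, sensor_id = "",
                              species = "", site = "",
                              moisture = "unknown") {
  if (!inherits(timestamp, "POSIXct")) timestamp <- as.POSIXct(timestamp, tz = "UTC")
  if (length(timestamp) != length(temperature_c))
    stopf("timestamp and temperature_c must have equal length")
  if (length(timestamp) < 2L)
    stopf("a temperature trace needs at least 2 records")
  if (anyNA(timestamp)) stopf("timestamps must not be NA")
  check_number(temperature_c, "temperature_c")
  if (any(diff(as.numeric(timestamp)) <= 0))
    stopf("timestamps must be strictly increasing")
  moisture <- match.arg(moisture, MOISTURE_CLASSES)
  out <- data.frame(timestamp = timestamp, temperature_c = as.numeric(temperature_c))
  structure(out,
    sensor_id = as.character(sensor_id), species = as.character(species),
    site = as.character(site), moisture = moisture,
    class = c("temperature_trace", "data.frame")
  )
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf(
    "<temperature_trace> %d records, %s to %s\n", nrow(x),
    format(min(x$timestamp)), format(max(x$timestamp))
  ))
  cat(sprintf(
    "  sensor: %s  species: %s  site: %s  moisture: %s\n",
    attr(x, "sensor_id"), attr(x, "species"), attr(x, "site"),
    attr(x, "moisture")
  ))
  cat(sprintf(
    "  temperature: %.1f to %.1f degC (mean %.1f)\n",
    min(x$temperature_c), max(x$temperature_c), mean(x$temperature_c)
  ))
  invisible(x)
}

# lenient ISO-8601 parser: unparseable entries become NA instead of errors
parse_timestamps <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in fmts) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], f, tz = "UTC"))
  }
  out
}

#' Read a temperature-logger CSV
#'
#' Expects columns `timestamp` (ISO 8601) and `temperature_c`; optional
#' metadata columns `sensor_id`, `species`, `site`, `moisture` (explicit
#' arguments override them). Rows with unparseable timestamps or
#' non-numeric temperatures are dropped with a warning giving the count;
#' records are sorted into time order.
#'
#' @param path path to the CSV file.
#' @param sensor_id,species,site,moisture metadata overrides; `NULL` to take
#'   them from the file (first row) or leave blank.
#' @return A [temperature_trace()].
#' @export
read_logger_csv <- function(path, sensor_id = NULL, species = NULL,
                            site = NULL, moisture = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("timestamp", "temperature_c")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stopf("logger CSV %s lacks required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  ts <- parse_timestamps(raw$timestamp)
  temp <- suppressWarnings(as.numeric(raw$temperature_c))
  keep <- !is.na(ts) & is.finite(temp)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning(sprintf("dropped %d unparseable row(s) from %s", n_dropped, path),
            call. = FALSE)
  if (!any(keep)) stopf("no valid records in %s", path)
  ord <- order(ts[keep])
  meta <- function(arg, col) {
    if (!is.null(arg)) return(arg)
    if (col %in% names(raw)) raw[[col]][keep][1L] else ""
  }
  mo <- meta(moisture, "moisture")
  if (identical(mo, "")) mo <- "unknown"
  temperature_trace(ts[keep][ord], temp[keep][ord],
                    sensor_id = meta(sensor_id, "sensor_id"),
                    species = meta(species, "species"),
                    site = meta(site, "site"), moisture = mo)
}

#' Write a temperature trace to CSV
#'
#' Inverse of [read_logger_csv()]: round-tripping preserves records and
#' metadata.
#'
#' @param trace a [temperature_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "temperature_trace"))
  out <- data.frame(
    timestamp = format(trace$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    temperature_c = trace$temperature_c,
    sensor_id = attr(trace, "sensor_id"), species = attr(trace, "species"),
    site = attr(trace, "site"), moisture = attr(trace, "moisture")
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Bin a temperature trace into a frequency-of-time histogram
#'
#' Counts records into uniform half-open bins `[lower, upper)` and expresses
#' each count as percent of time, `Time(%) = 100 * t / T`, where `t` is the
#' number of records in the bin and `T` the total. Bin edges are anchored at
#' integer multiples of `bin_width` so the conventional 2-degree edges
#' (-4, -2, ..., 28) are reproduced; records outside `range` extend the
#' histogram with extra bins rather than being dropped.
#'
#' @param trace a [temperature_trace()].
#' @param bin_width bin width in degrees C (default 2).
#' @param range optional `c(low, high)` in degrees C; auto-expanded to cover
#'   all records. `NULL` (default) derives the range from the data.
#' @return An object of class `temperature_histogram`: a data frame with
#'   columns `bin_low`, `bin_high`, `count`, `frequency_pct`, and attribute
#'   `n_records`. Frequencies sum to 100.
#' @examples
#' tr <- temperature_trace(
#'   as.POSIXct("2003-01-16", tz = "UTC") + 3600 * 0:3,
#'   c(-1, 1, 5, 5)
#' )
#' bin_temperature_frequency(tr, bin_width = 2)
#' @export
bin_temperature_frequency <- function(trace, bin_width = 2, range = NULL) {
  stopifnot(inherits(trace, "temperature_trace"))
  check_number(bin_width, "bin_width", positive = TRUE, len = 1)
  x <- trace$temperature_c
  if (!length(x)) stopf("empty trace")
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- floor(max(x) / bin_width) * bin_width + bin_width
  if (!is.null(range)) {
    check_number(range, "range", len = 2)
    if (range[1] >= range[2]) stopf("range must be increasing")
    # snap the requested range onto the bin grid, then expand to the data
    lo <- min(lo, floor(range[1] / bin_width) * bin_width)
    hi <- max(hi, ceiling(range[2] / bin_width) * bin_width)
  }
  edges <- seq(lo, hi, by = bin_width)
  # half-open [lower, upper): findInterval with left-closed intervals
  idx <- findInterval(x, edges, rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  freq <- 100 * counts / length(x)
  structure(
    data.frame(
      bin_low = edges[-length(edges)], bin_high = edges[-1L],
      count = counts, frequency_pct = freq
    ),
    n_records = length(x), bin_width = bin_width,
    class = c("temperature_histogram", "data.frame")
  )
}

#' @export
print.temperature_histogram <- function(x, ...) {
  cat(sprintf("<temperature_histogram> %d bins of %g degC, %d records\n",
              nrow(x), attr(x, "bin_width"), attr(x, "n_records")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Percent of time spent below / above thresholds
#'
#' Strict inequalities: a record exactly at a threshold counts as neither
#' below nor above (the convention behind "below +4 degC" and
#' "exceeded 14 degC").
#'
#' @param trace a [temperature_trace()].
#' @param low,high thresholds in degrees C, `low < high`. Defaults 4 and 14.
#' @return Named numeric vector `c(percent_below, percent_above)` in percent.
#' @export
fraction_time_outside <- function(trace, low = 4, high = 14) {
  stopifnot(inherits(trace, "temperature_trace"))
  check_number(low, "low", len = 1)
  check_number(high, "high", len = 1)
  if (low >= high) stopf("low must be < high")
  x <- trace$temperature_c
  if (!length(x)) stopf("empty trace")
  c(percent_below = 100 * mean(x < low),
    percent_above = 100 * mean(x > high))
}

#' Per-hour-of-day temperature summary
#'
#' Summarises a trace by local hour of day (taken from the timestamps as
#' given; no timezone arithmetic). Hours with no records have `n = 0` and
#' `NA` statistics rather than zeros.
#'
#' @param trace a [temperature_trace()].
#' @return Data frame with one row per hour 0-23: `hour`, `n`, `mean`,
#'   `max`, `min`.
#' @export
diurnal_summary <- function(trace) {
  stopifnot(inherits(trace, "temperature_trace"))
  hr <- as.integer(format(trace$timestamp, "%H"))
  out <- data.frame(hour = 0:23, n = 0L, mean = NA_real_,
                    max = NA_real_, min = NA_real_)
  for (h in unique(hr)) {
    v <- trace$temperature_c[hr == h]
    i <- h + 1L
    out$n[i] <- length(v)
    out$mean[i] <- mean(v)
    out$max[i] <- max(v)
    out$min[i] <- min(v)
  }
  out
}

#' Write a temperature histogram as CSV or JSON
#'
#' @param hist a `temperature_histogram`.
#' @param path output path; format chosen by `format`.
#' @param format `"csv"` (columns `bin_low,bin_high,frequency_pct,count`) or
#'   `"json"`.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path, format = c("csv", "json")) {
  stopifnot(inherits(hist, "temperature_histogram"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(
      hist[, c("bin_low", "bin_high", "frequency_pct", "count")],
      path, row.names = FALSE
    )
  } else {
    jsonlite::write_json(
      list(n_records = attr(hist, "n_records"),
           bin_width = attr(hist, "bin_width"),
           bins = as.data.frame(hist)),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read a temperature histogram written by [write_histogram()]
#'
#' @param path CSV path with columns `bin_low,bin_high,frequency_pct,count`.
#' @return A `temperature_histogram`.
#' @export
read_histogram_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("bin_low", "bin_high", "frequency_pct", "count")
  if (!all(need %in% names(d)))
    stopf("histogram CSV lacks required columns")
  structure(
    data.frame(bin_low = d$bin_low, bin_high = d$bin_high,
               count = d$count, frequency_pct = d$frequency_pct),
    n_records = sum(d$count), bin_width = d$bin_high[1] - d$bin_low[1],
    class = c("temperature_histogram", "data.frame")
  )
}
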