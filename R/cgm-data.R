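#' Minute-gridded CGM series
#'
#' The package's canonical container for a continuous glucose monitoring
#' trace: glucose readings in mg/dL on a uniform 1-minute grid, with a
#' per-minute missingness mask marking sensor disconnections. All downstream
#' bookkeeping (10-minute input windows, 30-minute horizons, "5 timestamps"
#' update cadences) relies on the 1-minute spacing.
#'
#' @param values Numeric vector of glucose readings (mg/dL), one per minute.
#' @param start_time `POSIXct` timestamp of the first minute (seconds = 0).
#' @param missing Logical vector, `TRUE` where no reading exists. Values at
#'   missing minutes are ignored (stored as `NA`).
#' @param patient_id Opaque patient identifier.
#' @return Object of class `cgm_series`.
#' @export
cgm_series <- function(values, start_time, missing = NULL, patient_id = "patient") {
  if (is.null(missing)) missing <- !is.finite(values)
  stopifnot(is.numeric(values), is.logical(missing),
            length(values) == length(missing))
  if (!inherits(start_time, "POSIXct") || length(start_time) != 1L) {
    stop("cgm_series(): start_time must be a single POSIXct", call. = FALSE)
  }
  if (as.numeric(start_time) %% 60 != 0) {
    stop("cgm_series(): start_time must fall on a whole minute", call. = FALSE)
  }
  ok <- !missing
  if (any(!is.finite(values[ok]) | values[ok] <= 0)) {
    stop("cgm_series(): non-missing glucose values must be finite and > 0",
         call. = FALSE)
  }
  values[missing] <- NA_real_
  structure(list(patient_id = patient_id, start_time = start_time,
                 values = as.numeric(values), missing = missing),
            class = "cgm_series")
}

#' @export
print.cgm_series <- function(x, ...) {
  cat(sprintf("CGM series '%s': %d minutes from %s (%.1f%% missing)\n",
              x$patient_id, length(x$values),
              format(x$start_time, "%Y-%m-%d %H:%M", tz = "UTC"),
              100 * mean(x$missing)))
  invisible(x)
}

#' @export
length.cgm_series <- function(x) length(x$values)

series_times <- function(series) {
  series$start_time + 60 * (seq_along(series$values) - 1L)
}

parse_minute_times <- function(x, tz = "UTC", what = "timestamp") {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  t <- rep(as.POSIXct(NA), length(x))
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                "%Y/%m/%d %H:%M:%OS", "%Y-%m-%d")) {
    todo <- is.na(t)
    if (!any(todo)) break
    t[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = tz))
  }
  bad <- which(is.na(t))
  if (length(bad) > 0L) {
    stop(sprintf("unparseable %s in row %d: '%s'", what, bad[1L], x[bad[1L]]),
         call. = FALSE)
  }
  # floor to the minute grid
  as.POSIXct(floor(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = tz)
}

#' Read a CGM table from CSV
#'
#' Reads a device export with one glucose reading per row, sorts it by time,
#' and collapses duplicate timestamps to their mean reading. Column names are
#' configurable through `dialect`.
#'
#' @param path CSV file path.
#' @param dialect Named list mapping roles to column names; defaults to
#'   `timestamp` (ISO-8601) and `glucose_mg_dl`.
#' @param tz Timezone used to interpret the timestamps (default UTC).
#' @return Data frame with columns `time` (`POSIXct`, minute resolution,
#'   strictly increasing) and `glucose` (mg/dL).
#' @export
read_cgm_table <- function(path,
                           dialect = list(timestamp = "timestamp",
                                          glucose = "glucose_mg_dl"),
                           tz = "UTC") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(dialect$timestamp, dialect$glucose)) {
    if (!col %in% names(raw)) {
      stop(sprintf("read_cgm_table(): column '%s' not found in %s", col, path),
           call. = FALSE)
    }
  }
  t <- parse_minute_times(raw[[dialect$timestamp]], tz = tz)
  g <- suppressWarnings(as.numeric(raw[[dialect$glucose]]))
  bad <- which(is.na(g))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric glucose in row %d: '%s'",
                 bad[1L], raw[[dialect$glucose]][bad[1L]]), call. = FALSE)
  }
  agg <- tapply(g, as.numeric(t), mean)
  key <- as.numeric(names(agg))
  o <- order(key)
  data.frame(time = as.POSIXct(key[o], origin = "1970-01-01", tz = tz),
             glucose = as.numeric(agg)[o])
}

#' Read physical-activity annotations from CSV
#'
#' @param path CSV file path.
#' @param dialect Named list mapping roles to column names; defaults to
#'   `start`, `end`, `type`.
#' @param tz Timezone for the timestamps.
#' @return Data frame with `start`, `end` (`POSIXct`) and `pa_type`
#'   (`"aerobic"` or `"anaerobic"`), sorted by start time.
#' @export
read_activity_table <- function(path,
                                dialect = list(start = "start", end = "end",
                                               type = "type"),
                                tz = "UTC") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(dialect$start, dialect$end, dialect$type)) {
    if (!col %in% names(raw)) {
      stop(sprintf("read_activity_table(): column '%s' not found", col),
           call. = FALSE)
    }
  }
  ev <- activity_events(start = parse_minute_times(raw[[dialect$start]], tz, "start"),
                        end = parse_minute_times(raw[[dialect$end]], tz, "end"),
                        pa_type = raw[[dialect$type]])
  ev[order(ev$start), , drop = FALSE]
}

#' Labelled exercise intervals
#'
#' @param start,end `POSIXct` vectors of interval endpoints (closed intervals,
#'   `start < end`).
#' @param pa_type Character vector, `"aerobic"` or `"anaerobic"`.
#' @return Validated data frame with columns `start`, `end`, `pa_type`.
#' @export
activity_events <- function(start, end, pa_type) {
  pa_type <- as.character(pa_type)
  ok <- pa_type %in% c("aerobic", "anaerobic")
  if (any(!ok)) {
    stop(sprintf("activity_events(): unknown activity type '%s'",
                 pa_type[!ok][1L]), call. = FALSE)
  }
  if (any(!(start < end))) {
    stop("activity_events(): every event must have start < end", call. = FALSE)
  }
  data.frame(start = start, end = end, pa_type = pa_type)
}

#' Resample raw readings onto the 1-minute grid
#'
#' Device exports typically report every 5 minutes. Intervals between
#' consecutive readings at most `max_gap_minutes` apart are filled by linear
#' interpolation; longer intervals are treated as sensor disconnections and
#' their interior minutes marked missing. Original readings are preserved
#' exactly at their own minutes.
#'
#' @param records Data frame from [read_cgm_table()] (columns `time`,
#'   `glucose`, time-sorted).
#' @param max_gap_minutes Largest between-reading gap bridged by
#'   interpolation (default 10: one missed 5-minute reading).
#' @param patient_id Identifier attached to the result.
#' @return A [cgm_series()] spanning the first to the last reading.
#' @export
resample_to_minute_grid <- function(records, max_gap_minutes = 10,
                                    patient_id = "patient") {
  if (nrow(records) < 2L) {
    stop("resample_to_minute_grid(): need at least 2 readings", call. = FALSE)
  }
  mins <- round(as.numeric(records$time) / 60)
  if (is.unsorted(mins, strictly = TRUE)) {
    stop("resample_to_minute_grid(): records must be strictly time-sorted",
         call. = FALSE)
  }
  grid <- mins[1L]:mins[length(mins)]
  vals <- stats::approx(mins, records$glucose, xout = grid, method = "linear")$y
  missing <- rep(FALSE, length(grid))
  gap <- diff(mins)
  for (i in which(gap > max_gap_minutes)) {
    # interior minutes of an unbridgeable gap; endpoints stay valid
    missing[(mins[i] - mins[1L] + 2L):(mins[i + 1L] - mins[1L])] <- TRUE
  }
  vals[missing] <- NA_real_
  cgm_series(vals,
             start_time = as.POSIXct(mins[1L] * 60, origin = "1970-01-01", tz = "UTC"),
             missing = missing, patient_id = patient_id)
}

#' A gap-free run of complete calendar days
#'
#' @param values Glucose values, length an exact multiple of 1440, no `NA`.
#' @param start_time Midnight `POSIXct` of the first day.
#' @param patient_id Patient identifier.
#' @param group_id Integer label of the group within the patient.
#' @return Object of class `cgm_day_group`.
#' @export
cgm_day_group <- function(values, start_time, patient_id = "patient",
                          group_id = 1L) {
  stopifnot(length(values) %% 1440L == 0L, !anyNA(values))
  structure(list(patient_id = patient_id, group_id = as.integer(group_id),
                 start_time = start_time, values = as.numeric(values),
                 n_days = length(values) %/% 1440L),
            class = "cgm_day_group")
}

#' @export
length.cgm_day_group <- function(x) length(x$values)

#' @export
print.cgm_day_group <- function(x, ...) {
  cat(sprintf("Continuous-day group %d of '%s': %d day(s) from %s\n",
              x$group_id, x$patient_id, x$n_days,
              format(x$start_time, "%Y-%m-%d", tz = "UTC")))
  invisible(x)
}

#' Apply the continuous-24-hour-day inclusion rule
#'
#' A calendar day (midnight to midnight, in the series' own clock) is complete
#' iff every one of its 1440 minutes lies inside the series and none is
#' missing. Incomplete days are discarded; maximal runs of consecutive
#' complete days become stand-alone groups, each modelled independently
#' downstream (no window, horizon, or trailing training set ever spans a gap).
#'
#' @param series A [cgm_series()].
#' @return List of [cgm_day_group()] objects (possibly empty), in time order.
#' @export
find_continuous_day_groups <- function(series) {
  n <- length(series$values)
  if (n == 0L) return(list())
  start_min <- as.numeric(series$start_time) / 60
  # first midnight at or after the series start
  first_day0 <- ceiling(start_min / 1440) * 1440
  last_min <- start_min + n - 1
  day_starts <- seq(first_day0, by = 1440,
                    length.out = max(0, floor((last_min + 1 - first_day0) / 1440)))
  if (length(day_starts) == 0L) return(list())
  complete <- vapply(day_starts, function(d0) {
    idx <- (d0 - start_min + 1):(d0 - start_min + 1440)
    all(idx >= 1 & idx <= n) && !any(series$missing[idx])
  }, logical(1))
  groups <- list()
  gid <- 0L
  r <- rle(complete)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    gid <- gid + 1L
    d0 <- day_starts[starts[k]]
    idx <- (d0 - start_min + 1):(d0 - start_min + 1440 * r$lengths[k])
    groups[[gid]] <- cgm_day_group(series$values[idx],
                                   start_time = as.POSIXct(d0 * 60,
                                                           origin = "1970-01-01",
                                                           tz = "UTC"),
                                   patient_id = series$patient_id,
                                   group_id = gid)
  }
  groups
}

#' Per-minute physical-activity mask for a day group
#'
#' Minute `m` of the group is flagged iff its timestamp falls inside the
#' closed interval `[start, end]` of at least one event; overlapping events
#' union without double counting. Events entirely outside the group's span
#' are ignored with a warning.
#'
#' @param group A [cgm_day_group()].
#' @param events Data frame from [activity_events()] (or `NULL` for none).
#' @return Logical vector of length `length(group)`.
#' @export
pa_mask <- function(group, events = NULL) {
  n <- length(group$values)
  mask <- rep(FALSE, n)
  if (is.null(events) || nrow(events) == 0L) return(mask)
  g0 <- as.numeric(group$start_time) / 60
  for (i in seq_len(nrow(events))) {
    s <- floor(as.numeric(events$start[i]) / 60) - g0 + 1
    e <- floor(as.numeric(events$end[i]) / 60) - g0 + 1
    if (e < 1 || s > n) {
      warning(sprintf("pa_mask(): event %d (%s) lies outside group %d; ignored",
                      i, events$pa_type[i], group$group_id), call. = FALSE)
      next
    }
    mask[max(1, s):min(n, e)] <- TRUE
  }
  mask
}

#' Serialize a patient's surviving-day index as JSON
#'
#' @param groups List of [cgm_day_group()] objects for one patient.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_day_group_index <- function(groups, path) {
  idx <- lapply(groups, function(g) {
    list(patient_id = g$patient_id, group_id = g$group_id,
         first_day = format(g$start_time, "%Y-%m-%d", tz = "UTC"),
         n_days = g$n_days, n_minutes = length(g$values))
  })
  jsonlite::write_json(idx, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
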