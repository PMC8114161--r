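#' Raw stream schemas
#'
#' Canonical column layouts for every raw sensor stream the pipeline
#' ingests.  Phone streams (AWARE-style): accelerometer, activity
#' recognition, location, screen, calls, sms, battery, light,
#' conversation.  Wearable streams (Fitbit-style): heart_rate, steps,
#' sleep.  All timestamps are epoch milliseconds (UTC); conversion to the
#' participant's civil time happens only at day assignment.
#'
#' @return Named list; each element has `cols` (column names) and
#'   `time_col` (the column used for sorting and day assignment).
#' @export
stream_schemas <- function() {
  list(
    accelerometer = list(cols = c("timestamp", "x", "y", "z"), time_col = "timestamp"),
    activity      = list(cols = c("timestamp", "activity"), time_col = "timestamp"),
    location      = list(cols = c("timestamp", "latitude", "longitude", "accuracy"), time_col = "timestamp"),
    screen        = list(cols = c("timestamp", "state"), time_col = "timestamp"),
    calls         = list(cols = c("timestamp", "direction", "duration", "contact_hash"), time_col = "timestamp"),
    sms           = list(cols = c("timestamp", "direction", "contact_hash"), time_col = "timestamp"),
    battery       = list(cols = c("timestamp", "level", "status"), time_col = "timestamp"),
    light         = list(cols = c("timestamp", "lux"), time_col = "timestamp"),
    conversation  = list(cols = c("start", "end"), time_col = "start"),
    heart_rate    = list(cols = c("timestamp", "bpm"), time_col = "timestamp"),
    steps         = list(cols = c("timestamp", "steps"), time_col = "timestamp"),
    sleep         = list(cols = c("start", "end", "minutes_asleep", "minutes_awake", "is_main_sleep"), time_col = "end")
  )
}

.activity_levels <- c("still", "walking", "running", "in_vehicle", "on_bicycle", "tilting", "unknown")
.screen_states   <- c("on", "off", "locked", "unlocked")

#' The ten diary symptoms
#'
#' Names of the ten patient-reported symptoms rated 0 (not present) to 10
#' (as bad as you can imagine) each morning.
#' @export
symptom_names <- function() {
  c("pain", "fatigue", "sleep_disturbance", "concentration", "sadness",
    "anxiety", "dyspnea", "numbness", "nausea", "bowel")
}

## row-level validity per stream kind; returns logical vector
.validate_rows <- function(dt, kind) {
  n <- nrow(dt)
  ok <- rep(TRUE, n)
  fin <- function(x) is.finite(as.numeric(x))
  switch(kind,
    accelerometer = fin(dt$timestamp) & fin(dt$x) & fin(dt$y) & fin(dt$z),
    activity      = fin(dt$timestamp) & dt$activity %in% .activity_levels,
    location      = fin(dt$timestamp) & fin(dt$latitude) & fin(dt$longitude) &
                    abs(dt$latitude) <= 90 & abs(dt$longitude) <= 180 & fin(dt$accuracy),
    screen        = fin(dt$timestamp) & dt$state %in% .screen_states,
    calls         = fin(dt$timestamp) & dt$direction %in% c("incoming", "outgoing", "missed") &
                    fin(dt$duration) & dt$duration >= 0,
    sms           = fin(dt$timestamp) & dt$direction %in% c("incoming", "outgoing"),
    battery       = fin(dt$timestamp) & fin(dt$level) & dt$level >= 0 & dt$level <= 100 &
                    dt$status %in% c("charging", "discharging"),
    light         = fin(dt$timestamp) & fin(dt$lux) & dt$lux >= 0,
    conversation  = fin(dt$start) & fin(dt$end) & dt$end >= dt$start,
    heart_rate    = fin(dt$timestamp) & fin(dt$bpm) & dt$bpm >= 25 & dt$bpm <= 250,
    steps         = fin(dt$timestamp) & fin(dt$steps) & dt$steps >= 0,
    sleep         = fin(dt$start) & fin(dt$end) & dt$end >= dt$start &
                    fin(dt$minutes_asleep) & fin(dt$minutes_awake) &
                    dt$minutes_asleep >= 0 & dt$minutes_awake >= 0 &
                    (dt$minutes_asleep + dt$minutes_awake) <= (dt$end - dt$start) / 60000 + 1e-9,
    ok
  )
}

#' Read one raw sensor stream from CSV
#'
#' Validates the header against the declared schema, drops rows that
#' violate the stream's value bounds (counting them in the `n_rejected`
#' attribute), and returns records sorted by time.
#'
#' @param path CSV file path.
#' @param stream_kind One of `names(stream_schemas())`.
#' @return A `data.table` sorted ascending by the stream's time column,
#'   with attribute `n_rejected` giving the number of malformed rows
#'   dropped.  An empty file yields an empty table with a warning.
#' @export
read_stream <- function(path, stream_kind) {
  schema <- stream_schemas()[[stream_kind]]
  if (is.null(schema)) stop("unknown stream kind: ", stream_kind)
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, colClasses = NULL, showProgress = FALSE)
  if (nrow(dt) == 0L && ncol(dt) == 0L) {
    warning("empty stream file: ", path)
    dt <- empty_stream(stream_kind)
    data.table::setattr(dt, "n_rejected", 0L)
    return(dt)
  }
  missing_cols <- setdiff(schema$cols, names(dt))
  if (length(missing_cols) > 0L) {
    stop("schema mismatch for stream '", stream_kind, "': missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- dt[, schema$cols, with = FALSE]
  ok <- .validate_rows(dt, stream_kind)
  ok[is.na(ok)] <- FALSE
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) dt <- dt[ok]
  data.table::setorderv(dt, schema$time_col)
  data.table::setattr(dt, "n_rejected", n_rejected)
  dt[]
}

#' @rdname read_stream
#' @param records A `data.table`/`data.frame` matching the stream schema.
#' @return `write_stream` returns `path` invisibly; a subsequent
#'   `read_stream` round-trips the records exactly.
#' @export
write_stream <- function(records, path, stream_kind) {
  schema <- stream_schemas()[[stream_kind]]
  if (is.null(schema)) stop("unknown stream kind: ", stream_kind)
  dt <- data.table::as.data.table(records)
  missing_cols <- setdiff(schema$cols, names(dt))
  if (length(missing_cols) > 0L) {
    stop("schema mismatch for stream '", stream_kind, "': missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(dt[, schema$cols, with = FALSE], path)
  invisible(path)
}

## typed empty table for a stream kind
empty_stream <- function(stream_kind) {
  schema <- stream_schemas()[[stream_kind]]
  proto <- list(
    timestamp = numeric(), x = numeric(), y = numeric(), z = numeric(),
    activity = character(), latitude = numeric(), longitude = numeric(),
    accuracy = numeric(), state = character(), direction = character(),
    duration = numeric(), contact_hash = character(), level = numeric(),
    status = character(), lux = numeric(), start = numeric(), end = numeric(),
    bpm = numeric(), steps = numeric(), minutes_asleep = numeric(),
    minutes_awake = numeric(), is_main_sleep = logical()
  )
  data.table::as.data.table(proto[schema$cols])
}

## ---- civil-time helpers -----------------------------------------------

## epoch ms for local midnight of `date` in `tz`
day_start_ms <- function(date, tz) {
  as.numeric(as.POSIXct(paste(as.character(date), "00:00:00"), tz = tz)) * 1000
}

## local calendar date of epoch-ms timestamps (arithmetic on the UTC
## offset; much cheaper than as.Date.POSIXlt at stream scale)
local_date <- function(ts_ms, tz) {
  ct <- as.POSIXct(ts_ms / 1000, origin = "1970-01-01", tz = tz)
  off <- as.POSIXlt(ct)$gmtoff
  off[is.na(off)] <- 0
  as.Date(floor((as.numeric(ct) + off) / 86400), origin = "1970-01-01")
}

## local hour-of-day (0-23)
local_hour <- function(ts_ms, tz) {
  as.POSIXlt(as.POSIXct(ts_ms / 1000, origin = "1970-01-01", tz = tz))$hour
}

## local minute-of-day (0-1439)
local_minute <- function(ts_ms, tz) {
  lt <- as.POSIXlt(as.POSIXct(ts_ms / 1000, origin = "1970-01-01", tz = tz))
  lt$hour * 60L + lt$min
}

#' Hours of sensor coverage for one participant-day
#'
#' Counts the distinct local clock-hours (0-23) of `date` in which at
#' least one record from any stream falls.  Interval streams
#' (conversation, sleep) cover every clock-hour their span overlaps.
#' Used for the "at least 20 hours of sensor data" retention rule.
#'
#' @param streams Named list of stream `data.table`s for one participant
#'   (names from `stream_schemas()`).
#' @param date Local calendar date (`Date` or ISO string).
#' @param timezone IANA timezone of the participant.
#' @return Number of covered hours, a float in \[0, 24\].
#' @export
day_coverage <- function(streams, date, timezone) {
  date <- as.Date(date)
  hours <- integer(0)
  for (kind in names(streams)) {
    dt <- streams[[kind]]
    if (is.null(dt) || nrow(dt) == 0L) next
    if (kind %in% c("conversation", "sleep")) {
      ## hour marks covered by the interval, hourly resolution
      for (i in seq_len(nrow(dt))) {
        marks <- seq(dt$start[i], dt$end[i], by = 3600 * 1000)
        if (marks[length(marks)] < dt$end[i]) marks <- c(marks, dt$end[i])
        sel <- local_date(marks, timezone) == date
        if (any(sel)) hours <- c(hours, local_hour(marks[sel], timezone))
      }
    } else {
      ts <- dt[[stream_schemas()[[kind]]$time_col]]
      sel <- local_date(ts, timezone) == date
      if (any(sel)) hours <- c(hours, local_hour(ts[sel], timezone))
    }
  }
  as.numeric(length(unique(hours)))
}

## ---- cohort-level I/O --------------------------------------------------

#' Write / read a cohort directory
#'
#' Layout: `<dir>/cohort.csv` (participant metadata),
#' `<dir>/<participant_id>/diary.csv`, and
#' `<dir>/<participant_id>/<stream_kind>.csv` for each stream present.
#' Readmission intervals are serialized as `start:end` pairs joined by
#' `;` in a single `readmissions` column.
#'
#' @param cohort A cohort list as produced by [simulate_cohort()]:
#'   elements `meta`, `diary`, `streams`.
#' @param dir Target directory.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` the
#'   cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort$meta, file.path(dir, "cohort.csv"))
  for (pid in names(cohort$streams)) {
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    data.table::fwrite(cohort$diary[participant_id == pid], file.path(pdir, "diary.csv"))
    for (kind in names(cohort$streams[[pid]])) {
      write_stream(cohort$streams[[pid]][[kind]], file.path(pdir, paste0(kind, ".csv")), kind)
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- data.table::fread(file.path(dir, "cohort.csv"))
  for (col in c("surgery_date", "discharge_date", "study_start", "study_end")) {
    meta[[col]] <- as.Date(meta[[col]])
  }
  meta[, readmissions := as.character(readmissions)]
  meta[is.na(readmissions), readmissions := ""]
  streams <- list()
  diaries <- list()
  for (pid in meta$participant_id) {
    pdir <- file.path(dir, pid)
    diaries[[pid]] <- data.table::fread(file.path(pdir, "diary.csv"))
    diaries[[pid]][, date := as.Date(date)]
    streams[[pid]] <- list()
    for (kind in names(stream_schemas())) {
      f <- file.path(pdir, paste0(kind, ".csv"))
      if (file.exists(f)) streams[[pid]][[kind]] <- read_stream(f, kind)
    }
  }
  list(meta = meta, diary = data.table::rbindlist(diaries), streams = streams)
}

## parse the serialized readmissions column into a list of date-interval
## tables (one per participant, same order as meta rows)
readmissions_list <- function(meta) {
  lapply(meta$readmissions, function(s) {
    if (is.null(s) || is.na(s) || !nzchar(s)) {
      return(data.table::data.table(start = as.Date(character()), end = as.Date(character())))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.table::data.table(
      start = as.Date(vapply(parts, `[`, character(1), 1L)),
      end   = as.Date(vapply(parts, `[`, character(1), 2L))
    )
  })
}
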