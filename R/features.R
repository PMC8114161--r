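## Day-level behavioral feature extraction.
##
## Each extractor computes features for ONE participant-day from that
## day's records.  Conventions shared by all extractors:
##   * durations are minutes, counts are non-negative integers;
##   * an absent sensor on an otherwise covered day yields NA features
##     ("missing", imputed later), never zeros -- except sleep, where the
##     wearable emits no episode when no sleep was detected, so zeros are
##     meaningful;
##   * day = one local civil day, midnight to midnight.

## run-length encoding of a logical over positions 1..n -> start/end table
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.table::data.table(start = starts, end = ends, value = r$values, len = r$lengths)
}

#' Step-based activity bout features
#'
#' An active bout is a maximal run of at least `min_bout_len` consecutive
#' recorded minutes each with `steps >= active_threshold`; sedentary
#' bouts are the complementary runs over recorded minutes.  Minutes must
#' be consecutive day-minute indices for a run to continue (a recording
#' gap breaks a bout).
#'
#' @param minutes Integer day-minute indices (0-1439) of the recorded
#'   per-minute samples, strictly increasing.
#' @param steps Per-minute step counts aligned with `minutes`.
#' @param active_threshold Steps/min at or above which a minute is
#'   active (default 10).
#' @param min_bout_len Minimum run length in minutes (default 1).
#' @return Named list: `sumsteps`, `n_active_bouts`,
#'   `total_active_minutes`, `max_active_bout_minutes`,
#'   `median_active_bout_minutes`, `n_sedentary_bouts`,
#'   `total_sedentary_minutes`.  All NA when no samples.
#' @export
step_bout_features <- function(minutes, steps, active_threshold = 10, min_bout_len = 1) {
  nm <- c("sumsteps", "n_active_bouts", "total_active_minutes",
          "max_active_bout_minutes", "median_active_bout_minutes",
          "n_sedentary_bouts", "total_sedentary_minutes")
  if (length(minutes) == 0L) return(setNames(as.list(rep(NA_real_, length(nm))), nm))
  ## split recorded minutes into contiguous segments, then run-scan each
  seg <- cumsum(c(1L, diff(minutes) != 1L))
  active_lens <- integer(0); sedentary_lens <- integer(0)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    runs <- .runs(steps[idx] >= active_threshold)
    act <- runs[value == TRUE & len >= min_bout_len]
    sed <- runs[!(value == TRUE & len >= min_bout_len)]
    active_lens <- c(active_lens, act$len)
    sedentary_lens <- c(sedentary_lens, sed$len)
  }
  list(
    sumsteps = sum(steps),
    n_active_bouts = length(active_lens),
    total_active_minutes = sum(active_lens),
    max_active_bout_minutes = if (length(active_lens)) max(active_lens) else 0,
    median_active_bout_minutes = if (length(active_lens)) median(active_lens) else 0,
    n_sedentary_bouts = length(sedentary_lens),
    total_sedentary_minutes = sum(sedentary_lens)
  )
}

#' Accelerometer exertion-episode features
#'
#' The day is cut into non-overlapping windows of `window_s` seconds
#' from local midnight; a window is exertional when the mean absolute
#' deviation of the acceleration magnitude from standard gravity is
#' strictly greater than `exertion_threshold`.  Episodes are maximal
#' runs of same-labeled windows; a gap of more than 5 minutes with no
#' data breaks an episode.
#'
#' @param timestamp Epoch-ms sample times (sorted).
#' @param x,y,z Acceleration components (m/s^2).
#' @param day_start_ms Epoch ms of local midnight for the day.
#' @param window_s Window length in seconds (default 60).
#' @param exertion_threshold Mean deviation (m/s^2) strictly above which
#'   a window is exertional (default 0.3; a window exactly at the
#'   threshold is nonexertional).
#' @return Named list: `n_exertional_episodes`,
#'   `total_exertional_minutes`, `median_nonexertional_episode_minutes`,
#'   `max_nonexertional_episode_minutes`.  All NA with less than one
#'   full window of data.
#' @export
exertion_episode_features <- function(timestamp, x, y, z, day_start_ms,
                                      window_s = 60, exertion_threshold = 0.3) {
  nm <- c("n_exertional_episodes", "total_exertional_minutes",
          "median_nonexertional_episode_minutes", "max_nonexertional_episode_minutes")
  if (length(timestamp) == 0L) return(setNames(as.list(rep(NA_real_, length(nm))), nm))
  dev <- abs(sqrt(x^2 + y^2 + z^2) - .G)
  win <- floor((timestamp - day_start_ms) / (window_s * 1000))
  agg <- data.table::data.table(win = win, dev = dev)[, .(m = mean(dev)), by = win]
  data.table::setorderv(agg, "win")
  ## strict ">": a window exactly at the threshold is nonexertional
  ## (1e-9 guard absorbs magnitude round-off)
  agg[, exertional := m - exertion_threshold > 1e-9]
  ## gaps > 5 min between consecutive observed windows break episodes
  gap_break <- c(TRUE, diff(agg$win) * window_s > 300)
  same <- c(TRUE, agg$exertional[-1] == agg$exertional[-nrow(agg)])
  episode_id <- cumsum(gap_break | !same)
  ep <- agg[, .(exertional = exertional[1], minutes = .N * window_s / 60),
            by = .(id = episode_id)]
  ex <- ep[exertional == TRUE]; nx <- ep[exertional == FALSE]
  list(
    n_exertional_episodes = nrow(ex),
    total_exertional_minutes = sum(ex$minutes),
    median_nonexertional_episode_minutes = if (nrow(nx)) median(nx$minutes) else 0,
    max_nonexertional_episode_minutes = if (nrow(nx)) max(nx$minutes) else 0
  )
}

#' Heart-rate level and zone features
#'
#' Zones are percentages of the age-predicted maximum heart rate
#' (HRmax = 220 - age): below fat burn < 50%, fat burn \[50%, 70%),
#' cardio \[70%, 85%), peak >= 85% (lower bounds inclusive, so 70.0% of
#' HRmax is cardio and 85.0% is peak).  Each per-minute sample
#' contributes one minute to exactly one zone.
#'
#' @param bpm Per-minute heart-rate samples.
#' @param age Participant age in years.
#' @return Named list: `min_hr`, `avg_hr`, `max_hr`,
#'   `minutes_below_fatburn`, `minutes_fatburn`, `minutes_cardio`,
#'   `minutes_peak`.  All NA when no samples.
#' @export
heart_rate_features <- function(bpm, age) {
  nm <- c("min_hr", "avg_hr", "max_hr", "minutes_below_fatburn",
          "minutes_fatburn", "minutes_cardio", "minutes_peak")
  if (length(bpm) == 0L) return(setNames(as.list(rep(NA_real_, length(nm))), nm))
  pct <- bpm / (220 - age)
  list(
    min_hr = min(bpm), avg_hr = mean(bpm), max_hr = max(bpm),
    minutes_below_fatburn = sum(pct < 0.5),
    minutes_fatburn = sum(pct >= 0.5 & pct < 0.7),
    minutes_cardio = sum(pct >= 0.7 & pct < 0.85),
    minutes_peak = sum(pct >= 0.85)
  )
}

#' Sleep-episode features
#'
#' An episode is attributed to the local calendar date containing its
#' END timestamp, so overnight main sleep and daytime naps both count
#' toward the day the sleeper woke up.  Absence of episodes is
#' meaningful (the wearable emits nothing when no sleep was detected),
#' so totals are zero, not missing.
#'
#' @param episodes `data.table` with columns `start`, `end` (epoch ms),
#'   `minutes_asleep`, `minutes_awake`, `is_main_sleep`.
#' @param date Local date to attribute to.
#' @param timezone IANA timezone.
#' @return Named list: `total_minutes_asleep`, `total_minutes_awake`,
#'   `n_sleep_episodes`, `main_sleep_minutes`, `nap_minutes`.
#' @export
sleep_features <- function(episodes, date, timezone) {
  date <- as.Date(date)
  if (is.null(episodes) || nrow(episodes) == 0L) {
    return(list(total_minutes_asleep = 0, total_minutes_awake = 0,
                n_sleep_episodes = 0, main_sleep_minutes = 0, nap_minutes = 0))
  }
  sel <- episodes[local_date(end, timezone) == date]
  list(
    total_minutes_asleep = sum(sel$minutes_asleep),
    total_minutes_awake = sum(sel$minutes_awake),
    n_sleep_episodes = nrow(sel),
    main_sleep_minutes = sum(sel$minutes_asleep[sel$is_main_sleep]),
    nap_minutes = sum(sel$minutes_asleep[!sel$is_main_sleep])
  )
}

## DBSCAN over a precomputed distance matrix (meters); eps-neighborhood
## density clustering, minPts including the point itself.  Expansion is
## frontier-vectorized (whole neighbor sets per round) rather than
## point-by-point.
.dbscan_dist <- function(D, eps, min_pts) {
  n <- nrow(D)
  A <- D <= eps
  core <- rowSums(A) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier) > 0L) {
      reach <- which(colSums(A[frontier, , drop = FALSE]) > 0L & labels == 0L)
      labels[reach] <- cl
      frontier <- reach[core[reach]]
    }
  }
  labels                       # 0 = noise
}

## full pairwise haversine distance matrix (meters); plain vectorized
## trig (geosphere's per-call input validation is too costly at n^2)
.hav_mat <- function(lon, lat) {
  R <- 6378137
  la <- lat * pi / 180; lo <- lon * pi / 180
  dla <- outer(la, la, `-`) / 2
  dlo <- outer(lo, lo, `-`) / 2
  a <- sin(dla)^2 + outer(cos(la), cos(la)) * sin(dlo)^2
  2 * R * asin(pmin(sqrt(a), 1))
}

#' Location features (clusters, dwell, entropy, movement)
#'
#' Fixes with accuracy worse than 100 m are dropped.  A fix is
#' stationary when the interpolated speed of its incoming segment is
#' below 1 km/h (the first fix inherits its outgoing segment).
#' Stationary fixes are clustered by density (DBSCAN over haversine
#' distance, default radius 30 m, minimum 3 fixes).  Dwell time per
#' cluster sums the intervals to the next fix, capped at 10 minutes
#' each; the top cluster is the one with the largest dwell.  Entropy is
#' Shannon entropy of the cluster dwell proportions; `normalized_entropy`
#' divides by `log(n_clusters)` when more than one cluster exists, else
#' 0.  `total_distance_km` sums haversine distance over moving segments
#' only (so stationary GPS jitter does not inflate it).
#'
#' @param timestamp Epoch-ms fix times (sorted).
#' @param latitude,longitude WGS84 degrees.
#' @param accuracy Reported accuracy in meters.
#' @param cluster_radius_m DBSCAN radius (default 30).
#' @param min_cluster_fixes DBSCAN minimum points (default 3).
#' @param speed_threshold_kmh Stationary/moving cutoff (default 1).
#' @param dwell_cap_min Per-interval dwell cap in minutes (default 10).
#' @return Named list: `n_clusters`, `minutes_at_top_cluster`,
#'   `location_entropy`, `normalized_entropy`, `total_distance_km`,
#'   `minutes_moving`.  All NA with fewer than two usable fixes.
#' @export
location_features <- function(timestamp, latitude, longitude, accuracy,
                              cluster_radius_m = 30, min_cluster_fixes = 3,
                              speed_threshold_kmh = 1, dwell_cap_min = 10) {
  nm <- c("n_clusters", "minutes_at_top_cluster", "location_entropy",
          "normalized_entropy", "total_distance_km", "minutes_moving")
  keep <- accuracy <= 100
  timestamp <- timestamp[keep]; latitude <- latitude[keep]; longitude <- longitude[keep]
  n <- length(timestamp)
  if (n < 2L) return(setNames(as.list(rep(NA_real_, length(nm))), nm))
  seg_m <- geosphere::distHaversine(cbind(longitude[-n], latitude[-n]),
                                    cbind(longitude[-1], latitude[-1]))
  seg_h <- diff(timestamp) / 3600000
  speed <- ifelse(seg_h > 0, (seg_m / 1000) / seg_h, Inf)
  stationary <- c(speed[1], speed) < speed_threshold_kmh  # fix i <- segment i-1
  ## interval owned by fix i (to the next fix), capped
  int_min <- pmin(c(diff(timestamp) / 60000, 0), dwell_cap_min)

  labels <- rep(0L, n)
  st <- which(stationary)
  if (length(st) >= min_cluster_fixes) {
    D <- .hav_mat(longitude[st], latitude[st])
    labels[st] <- .dbscan_dist(D, cluster_radius_m, min_cluster_fixes)
  }
  k <- max(labels)
  dwell <- if (k > 0) vapply(seq_len(k), function(c) sum(int_min[labels == c]), numeric(1)) else numeric(0)
  ent <- NA_real_; nent <- NA_real_; top <- NA_real_
  if (k >= 1) {
    p <- dwell / sum(dwell)
    p <- p[p > 0]
    ent <- -sum(p * log(p))
    nent <- if (k > 1) ent / log(k) else 0
    top <- max(dwell)
  }
  list(
    n_clusters = k,
    minutes_at_top_cluster = top,
    location_entropy = ent,
    normalized_entropy = nent,
    total_distance_km = sum(seg_m[!stationary[-1]]) / 1000,
    minutes_moving = sum(int_min[!stationary])
  )
}

#' Screen-session features
#'
#' A session runs from an `unlocked` event to the next `locked`/`off`
#' event; sessions crossing midnight are truncated at the day boundary
#' and an unpaired unlock is closed at day end.  `on` events do not open
#' sessions (screen on is not screen unlocked).
#'
#' @param timestamp Epoch-ms event times (sorted).
#' @param state Event states (`on`, `off`, `locked`, `unlocked`).
#' @param day_start_ms Epoch ms of local midnight.
#' @return Named list: `n_unlocks`, `total_screen_on_minutes`,
#'   `max_session_minutes`, `first_unlock_hour`.  All NA when no events.
#' @export
screen_features <- function(timestamp, state, day_start_ms) {
  nm <- c("n_unlocks", "total_screen_on_minutes", "max_session_minutes",
          "first_unlock_hour")
  if (length(timestamp) == 0L) return(setNames(as.list(rep(NA_real_, length(nm))), nm))
  day_end <- day_start_ms + 1440 * 60000
  sessions <- numeric(0)
  open_at <- NA_real_
  for (i in seq_along(timestamp)) {
    if (state[i] == "unlocked") {
      if (is.na(open_at)) open_at <- timestamp[i]
    } else if (state[i] %in% c("locked", "off")) {
      if (!is.na(open_at)) {
        sessions <- c(sessions, (min(timestamp[i], day_end) - open_at) / 60000)
        open_at <- NA_real_
      }
    }
  }
  if (!is.na(open_at)) sessions <- c(sessions, (day_end - open_at) / 60000)
  unlocks <- timestamp[state == "unlocked"]
  list(
    n_unlocks = length(unlocks),
    total_screen_on_minutes = sum(sessions),
    max_session_minutes = if (length(sessions)) max(sessions) else 0,
    first_unlock_hour = if (length(unlocks)) floor((unlocks[1] - day_start_ms) / 3600000) else NA_real_
  )
}

#' Call and SMS features
#'
#' @param calls `data.table` with `direction`, `duration` (seconds),
#'   `contact_hash` for the day's calls (may be empty).
#' @param sms Same for SMS events.
#' @return Named list: `n_calls_in`, `n_calls_out`, `n_missed`,
#'   `total_call_minutes`, `n_sms_in`, `n_sms_out`, `n_unique_contacts`.
#'   A day with no events yields zeros (communication silence is
#'   observable, not missing), unless both streams are entirely absent
#'   upstream (handled by the caller).
#' @export
communication_features <- function(calls, sms) {
  if (is.null(calls)) calls <- empty_stream("calls")
  if (is.null(sms)) sms <- empty_stream("sms")
  list(
    n_calls_in = sum(calls$direction == "incoming"),
    n_calls_out = sum(calls$direction == "outgoing"),
    n_missed = sum(calls$direction == "missed"),
    total_call_minutes = sum(calls$duration) / 60,
    n_sms_in = sum(sms$direction == "incoming"),
    n_sms_out = sum(sms$direction == "outgoing"),
    n_unique_contacts = length(unique(c(calls$contact_hash, sms$contact_hash)))
  )
}

#' Activity-recognition features
#'
#' Each event's activity is forward-filled until the next event or day
#' end; minutes before the first event are unattributed.  `tilting` and
#' `unknown` are excluded from `n_unique_activities` (they are sensor
#' artifacts, not behaviors) but still accumulate minutes.
#'
#' @param timestamp Epoch-ms event times (sorted).
#' @param activity Activity tokens.
#' @param day_start_ms Epoch ms of local midnight.
#' @return Named list: `n_unique_activities`, `most_common_activity`
#'   (categorical; minute-count ties broken toward the lexicographically
#'   smallest token), and `minutes_<activity>` for still, walking,
#'   running, in_vehicle, on_bicycle.  NA when no events.
#' @export
activity_recognition_features <- function(timestamp, activity, day_start_ms) {
  acts <- c("still", "walking", "running", "in_vehicle", "on_bicycle")
  nm <- c("n_unique_activities", "most_common_activity", paste0("minutes_", acts))
  if (length(timestamp) == 0L) {
    out <- as.list(rep(NA_real_, length(nm))); names(out) <- nm
    out$most_common_activity <- NA_character_
    return(out)
  }
  day_end <- day_start_ms + 1440 * 60000
  dur_min <- (c(timestamp[-1], day_end) - timestamp) / 60000
  tot <- tapply(dur_min, activity, sum)
  behav <- tot[setdiff(names(tot), c("tilting", "unknown"))]
  mc <- names(tot)[order(-tot, names(tot))][1]
  out <- list(
    n_unique_activities = sum(behav > 0),
    most_common_activity = mc
  )
  for (a in acts) out[[paste0("minutes_", a)]] <- if (a %in% names(tot)) unname(tot[a]) else 0
  out
}

#' Ambient-light features
#'
#' @param timestamp Epoch-ms sample times.
#' @param lux Illuminance samples (lux).
#' @param day_start_ms Epoch ms of local midnight.
#' @return Named list: `max_lux`, `avg_lux`, `std_lux` (0 for a single
#'   sample), `avg_lux_night` (00:00-06:00 local; NA if no night
#'   samples).  All NA when no samples.
#' @export
light_features <- function(timestamp, lux, day_start_ms) {
  nm <- c("max_lux", "avg_lux", "std_lux", "avg_lux_night")
  if (length(lux) == 0L) return(setNames(as.list(rep(NA_real_, length(nm))), nm))
  night <- timestamp < day_start_ms + 360 * 60000
  list(
    max_lux = max(lux), avg_lux = mean(lux),
    std_lux = if (length(lux) > 1L) sd(lux) else 0,
    avg_lux_night = if (any(night)) mean(lux[night]) else NA_real_
  )
}

#' Battery features
#'
#' Charge episodes are maximal runs of `charging` status over the day's
#' events; discharge minutes forward-fill each `discharging` event to
#' the next event or day end.
#'
#' @param timestamp Epoch-ms event times (sorted).
#' @param status `charging` / `discharging` tokens.
#' @param day_start_ms Epoch ms of local midnight.
#' @return Named list: `n_charge_episodes`, `total_discharge_minutes`.
#'   NA when no events.
#' @export
battery_features <- function(timestamp, status, day_start_ms) {
  nm <- c("n_charge_episodes", "total_discharge_minutes")
  if (length(timestamp) == 0L) return(setNames(as.list(rep(NA_real_, length(nm))), nm))
  day_end <- day_start_ms + 1440 * 60000
  dur_min <- (c(timestamp[-1], day_end) - timestamp) / 60000
  r <- rle(status)
  list(
    n_charge_episodes = sum(r$values == "charging"),
    total_discharge_minutes = sum(dur_min[status == "discharging"])
  )
}

#' Conversation features
#'
#' Episodes are clipped to the day's bounds before summing.
#'
#' @param episodes `data.table` with `start`, `end` epoch ms for episodes
#'   overlapping the day.
#' @param day_start_ms Epoch ms of local midnight.
#' @return Named list: `total_conversation_minutes`, `n_conversations`.
#'   NA when no episodes.
#' @export
conversation_features <- function(episodes, day_start_ms) {
  nm <- c("total_conversation_minutes", "n_conversations")
  if (is.null(episodes) || nrow(episodes) == 0L) {
    return(setNames(as.list(rep(NA_real_, length(nm))), nm))
  }
  day_end <- day_start_ms + 1440 * 60000
  s <- pmax(episodes$start, day_start_ms)
  e <- pmin(episodes$end, day_end)
  keep <- e > s
  list(
    total_conversation_minutes = sum((e[keep] - s[keep]) / 60000),
    n_conversations = sum(keep)
  )
}

#' All day-level features for one participant-day
#'
#' Concatenates every per-sensor extractor for one local day, plus the
#' day's sensor coverage in hours.  Missing sensors yield missing
#' features (except sleep; see [sleep_features()]).
#'
#' @param streams Named list of the participant's full stream tables.
#' @param meta One-row metadata (needs `age`, `timezone`).
#' @param date Local date.
#' @return Named list of features plus `coverage_hours`.
#' @export
extract_all <- function(streams, meta, date) {
  date <- as.Date(date)
  tz <- meta$timezone
  d0 <- day_start_ms(date, tz)
  d1 <- day_start_ms(date + 1, tz)   # civil next midnight (DST-aware)
  day_of <- function(kind) {
    dt <- streams[[kind]]
    if (is.null(dt) || nrow(dt) == 0L) return(empty_stream(kind))
    tcol <- stream_schemas()[[kind]]$time_col
    dt[dt[[tcol]] >= d0 & dt[[tcol]] < d1]
  }
  st <- day_of("steps"); hr <- day_of("heart_rate"); ac <- day_of("accelerometer")
  lo <- day_of("location"); sc <- day_of("screen"); ca <- day_of("calls")
  sm <- day_of("sms"); av <- day_of("activity"); li <- day_of("light")
  ba <- day_of("battery")
  ## conversation: overlap the day, not just start within it
  cv <- streams$conversation
  cv <- if (is.null(cv) || nrow(cv) == 0L) empty_stream("conversation") else cv[end > d0 & start < d1]

  feats <- c(
    step_bout_features(floor((st$timestamp - d0) / 60000), st$steps),
    exertion_episode_features(ac$timestamp, ac$x, ac$y, ac$z, d0),
    heart_rate_features(hr$bpm, meta$age),
    sleep_features(streams$sleep, date, tz),
    location_features(lo$timestamp, lo$latitude, lo$longitude, lo$accuracy),
    screen_features(sc$timestamp, sc$state, d0),
    if (nrow(ca) + nrow(sm) > 0L) communication_features(ca, sm) else
      setNames(as.list(rep(NA_real_, 7)),
               c("n_calls_in", "n_calls_out", "n_missed", "total_call_minutes",
                 "n_sms_in", "n_sms_out", "n_unique_contacts")),
    activity_recognition_features(av$timestamp, av$activity, d0),
    light_features(li$timestamp, li$lux, d0),
    battery_features(ba$timestamp, ba$status, d0),
    conversation_features(cv, d0)
  )
  feats$coverage_hours <- day_coverage(streams, date, tz)
  feats
}

#' Extract day-level features for a whole cohort
#'
#' One row per participant-day over each participant's study window.
#'
#' @param cohort A `persense_cohort` (or any list with `meta`,
#'   `streams`).
#' @param verbose Print progress per participant.
#' @return `data.table` with `participant_id`, `date`, `coverage_hours`,
#'   and one column per feature (`most_common_activity` is categorical).
#' @export
extract_features <- function(cohort, verbose = FALSE) {
  rows <- list()
  for (pid in cohort$meta$participant_id) {
    m <- cohort$meta[participant_id == pid]
    if (verbose) message("extracting ", pid)
    dates <- seq(m$study_start, m$study_end, by = "day")
    pstreams <- .index_by_date(cohort$streams[[pid]], m$timezone)
    prows <- lapply(dates, function(d) {
      f <- extract_all_indexed(pstreams, m, d)
      c(list(participant_id = pid, date = d), f)
    })
    rows[[pid]] <- data.table::rbindlist(prows)
  }
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, c("participant_id", "date", "coverage_hours"))
  out
}

## pre-split every stream by local date so per-day extraction does not
## rescan full stream tables; also precompute the hour sets for coverage
.index_by_date <- function(streams, tz) {
  idx <- list()
  hours <- list()
  for (kind in names(stream_schemas())) {
    dt <- streams[[kind]]
    if (is.null(dt) || nrow(dt) == 0L) { idx[[kind]] <- list(); next }
    tcol <- stream_schemas()[[kind]]$time_col
    d <- local_date(dt[[tcol]], tz)
    idx[[kind]] <- split(dt, d)
    if (kind %in% c("conversation", "sleep")) {
      ## hour coverage from interval spans (hourly marks)
      marks <- unlist(lapply(seq_len(nrow(dt)), function(i) {
        mk <- seq(dt$start[i], dt$end[i], by = 3600000)
        if (mk[length(mk)] < dt$end[i]) mk <- c(mk, dt$end[i])
        mk
      }))
    } else {
      marks <- dt[[tcol]]
    }
    hours[[kind]] <- unique(data.table::data.table(
      date = local_date(marks, tz), hour = local_hour(marks, tz)))
  }
  cov <- data.table::rbindlist(hours[!vapply(hours, is.null, logical(1))])
  cov <- unique(cov)[, .(coverage = .N), by = date]
  list(by_date = idx, coverage = cov, full_sleep = streams$sleep,
       full_conversation = streams$conversation)
}

## extract_all against a pre-indexed stream set (fast path; equals
## extract_all by construction of the same per-day slices)
extract_all_indexed <- function(pstreams, meta, date) {
  tz <- meta$timezone
  d0 <- day_start_ms(date, tz)
  d1 <- day_start_ms(as.Date(date) + 1, tz)
  key <- as.character(date)
  g <- function(kind) {
    dt <- pstreams$by_date[[kind]][[key]]
    if (is.null(dt)) empty_stream(kind) else dt
  }
  st <- g("steps"); hr <- g("heart_rate"); ac <- g("accelerometer")
  lo <- g("location"); sc <- g("screen"); ca <- g("calls")
  sm <- g("sms"); av <- g("activity"); li <- g("light"); ba <- g("battery")
  cv <- pstreams$full_conversation
  cv <- if (is.null(cv) || nrow(cv) == 0L) empty_stream("conversation") else cv[end > d0 & start < d1]
  ## sleep is pre-split by END date, matching the attribution rule
  sl <- g("sleep")

  feats <- c(
    step_bout_features(floor((st$timestamp - d0) / 60000), st$steps),
    exertion_episode_features(ac$timestamp, ac$x, ac$y, ac$z, d0),
    heart_rate_features(hr$bpm, meta$age),
    list(total_minutes_asleep = sum(sl$minutes_asleep),
         total_minutes_awake = sum(sl$minutes_awake),
         n_sleep_episodes = nrow(sl),
         main_sleep_minutes = sum(sl$minutes_asleep[sl$is_main_sleep]),
         nap_minutes = sum(sl$minutes_asleep[!sl$is_main_sleep])),
    location_features(lo$timestamp, lo$latitude, lo$longitude, lo$accuracy),
    screen_features(sc$timestamp, sc$state, d0),
    if (nrow(ca) + nrow(sm) > 0L) communication_features(ca, sm) else
      setNames(as.list(rep(NA_real_, 7)),
               c("n_calls_in", "n_calls_out", "n_missed", "total_call_minutes",
                 "n_sms_in", "n_sms_out", "n_unique_contacts")),
    activity_recognition_features(av$timestamp, av$activity, d0),
    light_features(li$timestamp, li$lux, d0),
    battery_features(ba$timestamp, ba$status, d0),
    conversation_features(cv, d0)
  )
  .d <- as.Date(date)
  covrow <- pstreams$coverage[date == .d]
  feats$coverage_hours <- if (nrow(covrow)) as.numeric(covrow$coverage) else 0
  feats
}
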