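test_that("step bouts follow the run-length definition", {
  ## spec-style fixture: [0,0,15,20,12,0,9,11] at threshold 10 ->
  ## two active bouts (minutes 2-4 and 7), totalling 4 active minutes
  st <- c(0, 0, 15, 20, 12, 0, 9, 11)
  f <- step_bout_features(0:7, st)
  expect_equal(f$n_active_bouts, 2)
  expect_equal(f$total_active_minutes, 4)
  expect_equal(f$max_active_bout_minutes, 3)
  expect_equal(f$sumsteps, sum(st))

  ## all minutes at/above threshold: one bout over all recorded minutes
  f <- step_bout_features(0:9, rep(12, 10))
  expect_equal(f$n_active_bouts, 1)
  expect_equal(f$total_active_minutes, 10)
  expect_equal(f$n_sedentary_bouts, 0)

  ## all zeros
  f <- step_bout_features(0:9, rep(0, 10))
  expect_equal(f$n_active_bouts, 0)
  expect_equal(f$total_active_minutes, 0)
  expect_equal(f$total_sedentary_minutes, 10)

  ## empty input -> missing, not zero
  f <- step_bout_features(integer(0), integer(0))
  expect_true(is.na(f$n_active_bouts))

  ## a recording gap breaks a bout even when steps stay high
  f <- step_bout_features(c(0, 1, 5, 6), rep(20, 4))
  expect_equal(f$n_active_bouts, 2)

  ## randomized equivalence against the brute-force scan, including a
  ## min_bout_len > 1 configuration
  set.seed(5)
  for (rep in 1:20) {
    mins <- sort(sample(0:200, 80))
    st <- rpois(80, 8)
    for (ml in c(1, 3)) {
      got <- step_bout_features(mins, st, min_bout_len = ml)
      want <- oracle_step_bouts(mins, st, min_len = ml)
      expect_equal(got[names(want)], want)
    }
  }
})

test_that("exertion episodes label 60-s windows by deviation from gravity", {
  d0 <- ms_at("2020-03-10", 0)
  ## constant gravity-only signal: one nonexertional episode, no exertion
  n <- 30
  ts <- d0 + (0:(n - 1)) * 60000
  f <- exertion_episode_features(ts, rep(0, n), rep(0, n), rep(9.80665, n), d0)
  expect_equal(f$n_exertional_episodes, 0)
  expect_equal(f$max_nonexertional_episode_minutes, 30)

  ## alternating high/low windows H,L,H -> 2 exertional episodes of 1 min
  ts3 <- d0 + (0:2) * 60000
  z <- 9.80665 + c(1, 0, 1)
  f <- exertion_episode_features(ts3, rep(0, 3), rep(0, 3), z, d0)
  expect_equal(f$n_exertional_episodes, 2)
  expect_equal(f$total_exertional_minutes, 2)

  ## magnitude exactly at the threshold is nonexertional (strict >)
  f <- exertion_episode_features(ts3, rep(0, 3), rep(0, 3),
                                 rep(9.80665 + 0.3, 3), d0)
  expect_equal(f$n_exertional_episodes, 0)

  ## gaps > 5 minutes break episodes
  ts_gap <- d0 + c(0, 1, 10, 11) * 60000
  f <- exertion_episode_features(ts_gap, rep(0, 4), rep(0, 4),
                                 rep(9.80665, 4), d0)
  expect_equal(f$max_nonexertional_episode_minutes, 2)

  ## empty -> missing
  f <- exertion_episode_features(numeric(0), numeric(0), numeric(0),
                                 numeric(0), d0)
  expect_true(is.na(f$n_exertional_episodes))

  ## randomized equivalence against the run-length oracle on labeled windows
  set.seed(6)
  for (rep in 1:10) {
    wins <- sort(sample(0:120, 50))
    dev <- runif(50, 0, 0.8)
    f <- exertion_episode_features(d0 + wins * 60000 + 1000,
                                   rep(0, 50), rep(0, 50), 9.80665 + dev, d0)
    want <- oracle_episodes(wins, dev > 0.3)
    expect_equal(f$n_exertional_episodes, want$n_exertional)
    expect_equal(f$total_exertional_minutes, want$total_exertional_minutes)
    expect_equal(f$median_nonexertional_episode_minutes, want$median_nonexertional)
    expect_equal(f$max_nonexertional_episode_minutes, want$max_nonexertional)
  }
})

test_that("heart-rate zones use lower-inclusive percent-of-HRmax bounds", {
  ## age 60 -> HRmax 160; 112 = 70.0% (cardio), 136 = 85.0% (peak),
  ## 80 = 50.0% (fat burn)
  f <- heart_rate_features(c(112, 112, 136, 80), 60)
  expect_equal(f$minutes_cardio, 2)
  expect_equal(f$minutes_peak, 1)
  expect_equal(f$minutes_fatburn, 1)
  expect_equal(f$minutes_below_fatburn, 0)
  expect_equal(f$min_hr, 80)

  ## constant series: min = avg = max
  f <- heart_rate_features(rep(72, 5), 50)
  expect_equal(f$min_hr, f$avg_hr)
  expect_equal(f$avg_hr, f$max_hr)

  ## zone minutes always partition the samples; oracle = per-sample if/else
  set.seed(7)
  for (rep in 1:10) {
    bpm <- sample(40:190, 60, replace = TRUE)
    age <- sample(40:80, 1)
    f <- heart_rate_features(bpm, age)
    z <- oracle_hr_zones(bpm, age)
    expect_equal(f$minutes_below_fatburn + f$minutes_fatburn +
                 f$minutes_cardio + f$minutes_peak, length(bpm))
    expect_equal(f$minutes_cardio, unname(z["cardio"]))
    expect_equal(f$minutes_peak, unname(z["peak"]))
  }
  expect_true(is.na(heart_rate_features(numeric(0), 60)$min_hr))
})

test_that("sleep episodes attribute to the day they end", {
  tz <- TEST_TZ
  d <- as.Date("2020-03-10")
  main <- data.table::data.table(
    start = ms_at(d - 1, 1380), end = ms_at(d, 450),  # 23:00 -> 07:30
    minutes_asleep = 420, minutes_awake = 40, is_main_sleep = TRUE)
  f <- sleep_features(main, d, tz)
  expect_equal(f$total_minutes_asleep, 420)
  expect_equal(f$total_minutes_awake, 40)
  ## nothing is attributed to the day the episode started
  f0 <- sleep_features(main, d - 1, tz)
  expect_equal(f0$total_minutes_asleep, 0)
  expect_equal(f0$n_sleep_episodes, 0)

  ## main + nap ending the same day: totals are sums
  nap <- data.table::data.table(
    start = ms_at(d, 810), end = ms_at(d, 850),
    minutes_asleep = 35, minutes_awake = 5, is_main_sleep = FALSE)
  f <- sleep_features(rbind(main, nap), d, tz)
  expect_equal(f$n_sleep_episodes, 2)
  expect_equal(f$total_minutes_asleep, 455)
  expect_equal(f$main_sleep_minutes, 420)
  expect_equal(f$nap_minutes, 35)

  ## no episodes is meaningful -> zeros, not missing
  f <- sleep_features(NULL, d, tz)
  expect_equal(f$total_minutes_asleep, 0)
})

test_that("location features: dwell clusters, entropy, movement", {
  d0 <- ms_at("2020-06-10", 600)
  ## 61 fixes at one coordinate, 1-min spacing -> single cluster,
  ## 60 dwell minutes, zero entropy
  n <- 61
  f <- location_features(d0 + (0:(n - 1)) * 60000, rep(40.44, n),
                         rep(-79.99, n), rep(10, n))
  expect_equal(f$n_clusters, 1)
  expect_equal(f$minutes_at_top_cluster, 60)
  expect_equal(f$location_entropy, 0)
  expect_equal(f$normalized_entropy, 0)

  ## two equal 60-minute dwells 1 km apart: entropy log 2, normalized 1,
  ## travel distance ~1 km (noise-free closed form)
  lat2 <- 40.44 + 1000 / 111320   # ~1 km north
  ts <- d0 + c(0:60, 61:121) * 60000
  f <- location_features(ts, c(rep(40.44, 61), rep(lat2, 61)),
                         rep(-79.99, 122), rep(10, 122))
  expect_equal(f$n_clusters, 2)
  expect_equal(f$location_entropy, log(2), tolerance = 0.02)
  expect_equal(f$normalized_entropy, 1, tolerance = 0.02)
  expect_equal(f$total_distance_km, 1.0, tolerance = 0.05)

  ## continuous transit at 20 km/h: no clusters, dwell missing, all
  ## recorded span moving
  km_per_min <- 20 / 60
  lats <- 40.44 + (0:30) * km_per_min * 1000 / 111320
  f <- location_features(d0 + (0:30) * 60000, lats, rep(-79.99, 31),
                         rep(10, 31))
  expect_equal(f$n_clusters, 0)
  expect_true(is.na(f$minutes_at_top_cluster))
  expect_equal(f$minutes_moving, 30)

  ## inaccurate fixes are dropped before anything else
  f <- location_features(d0 + (0:2) * 60000, rep(40.44, 3), rep(-79.99, 3),
                         c(10, 150, 10))
  expect_equal(f$n_clusters, 0)  # 2 usable fixes < min_cluster_fixes

  expect_true(is.na(location_features(d0, 40.44, -79.99, 10)$n_clusters))
})

test_that("screen sessions replay unlock/lock with midnight truncation", {
  d0 <- ms_at("2020-03-10", 0)
  ## paired unlock/lock 10 minutes apart
  f <- screen_features(d0 + c(600, 610) * 60000, c("unlocked", "locked"), d0)
  expect_equal(f$n_unlocks, 1)
  expect_equal(f$total_screen_on_minutes, 10)
  expect_equal(f$first_unlock_hour, 10)

  ## unlock at 23:55 with the lock falling on the next day: 5 minutes today
  f <- screen_features(d0 + 1435 * 60000, "unlocked", d0)
  expect_equal(f$total_screen_on_minutes, 5)

  ## "on" events do not open sessions
  f <- screen_features(d0 + c(10, 20) * 60000, c("on", "off"), d0)
  expect_equal(f$n_unlocks, 0)
  expect_equal(f$total_screen_on_minutes, 0)

  ## noisy interleavings equal the brute-force state machine replay
  set.seed(8)
  for (rep in 1:10) {
    mins <- sort(sample(0:1439, 30))
    states <- sample(c("unlocked", "locked", "off", "on"), 30, replace = TRUE)
    f <- screen_features(d0 + mins * 60000, states, d0)
    want <- oracle_screen(mins, states)
    expect_equal(f$total_screen_on_minutes, sum(want))
    expect_equal(f$max_session_minutes, if (length(want)) max(want) else 0)
  }
})

test_that("communication counts calls, texts, and unique contacts", {
  calls <- data.table::data.table(
    timestamp = 1:3, direction = c("outgoing", "outgoing", "missed"),
    duration = c(120, 60, 0), contact_hash = c("a", "a", "a"))
  sms <- data.table::data.table(
    timestamp = 4, direction = "incoming", contact_hash = "b")
  f <- communication_features(calls, sms)
  expect_equal(f$n_calls_out, 2)
  expect_equal(f$n_missed, 1)
  expect_equal(f$total_call_minutes, 3)
  expect_equal(f$n_sms_in, 1)
  expect_equal(f$n_unique_contacts, 2)

  f <- communication_features(NULL, NULL)
  expect_equal(f$n_calls_in, 0)
  expect_equal(f$n_unique_contacts, 0)
})

test_that("activity recognition forward-fills events to day end", {
  d0 <- ms_at("2020-03-10", 0)
  ## single "still" event at midnight covers the whole day
  f <- activity_recognition_features(d0, "still", d0)
  expect_equal(f$most_common_activity, "still")
  expect_equal(f$minutes_still, 1440)

  ## still -> walking -> still: two unique behaviors
  f <- activity_recognition_features(d0 + c(0, 600, 660) * 60000,
                                     c("still", "walking", "still"), d0)
  expect_equal(f$n_unique_activities, 2)
  expect_equal(f$minutes_walking, 60)
  expect_equal(f$minutes_still, 1380)

  ## tilting/unknown accumulate minutes but are not unique behaviors
  f <- activity_recognition_features(d0 + c(0, 100) * 60000,
                                     c("unknown", "tilting"), d0)
  expect_equal(f$n_unique_activities, 0)

  ## random event trains match the interval-fill oracle
  set.seed(9)
  for (rep in 1:10) {
    mins <- sort(sample(0:1439, 15))
    acts <- sample(c("still", "walking", "in_vehicle"), 15, replace = TRUE)
    f <- activity_recognition_features(d0 + mins * 60000, acts, d0)
    want <- oracle_forward_fill(mins, acts)
    for (a in names(want)) {
      expect_equal(f[[paste0("minutes_", a)]], unname(want[a]))
    }
  }
})

test_that("light features summarize day and night samples", {
  d0 <- ms_at("2020-03-10", 0)
  f <- light_features(d0 + c(100, 200) * 60000, c(50, 50), d0)
  expect_equal(f$max_lux, f$avg_lux)
  expect_equal(f$std_lux, 0)
  ## night = 00:00-06:00: oracle subset mean
  set.seed(10)
  mins <- sort(sample(0:1439, 100))
  lux <- rexp(100, 1 / 100)
  f <- light_features(d0 + mins * 60000, lux, d0)
  expect_equal(f$avg_lux_night, mean(lux[mins < 360]))
  expect_true(is.na(light_features(numeric(0), numeric(0), d0)$max_lux))
})

test_that("battery features count charge episodes and discharge time", {
  d0 <- ms_at("2020-03-10", 0)
  ## monotone discharge -> 0 charge episodes
  f <- battery_features(d0 + (0:5) * 3600000, rep("discharging", 6), d0)
  expect_equal(f$n_charge_episodes, 0)
  ## charge / discharge / charge -> 2 episodes
  f <- battery_features(d0 + (0:3) * 3600000,
                        c("charging", "discharging", "charging", "charging"), d0)
  expect_equal(f$n_charge_episodes, 2)
  ## forward-fill oracle equality
  set.seed(11)
  mins <- sort(sample(0:1439, 20))
  st <- sample(c("charging", "discharging"), 20, replace = TRUE)
  f <- battery_features(d0 + mins * 60000, st, d0)
  want <- oracle_forward_fill(mins, st)
  expect_equal(f$total_discharge_minutes,
               unname(want["discharging"]))
})

test_that("conversation minutes clip episodes to the day", {
  d0 <- ms_at("2020-03-10", 0)
  eps <- data.table::data.table(
    start = c(d0 - 10 * 60000, d0 + 600 * 60000),
    end = c(d0 + 5 * 60000, d0 + 615 * 60000))
  f <- conversation_features(eps, d0)
  expect_equal(f$n_conversations, 2)
  expect_equal(f$total_conversation_minutes, 20)  # 5 clipped + 15
  expect_true(is.na(conversation_features(NULL, d0)$n_conversations))
})

test_that("extract_all concatenates sensors with missing-vs-zero semantics", {
  coh <- test_cohort()
  pid <- coh$meta$participant_id[1]
  m <- coh$meta[participant_id == pid]
  d <- m$surgery_date + 10
  row <- extract_all(coh$streams[[pid]], m, d)
  expect_true(row$coverage_hours > 0)
  expect_false(is.na(row$sumsteps))

  ## remove the wearable: step/hr features go missing, sleep goes to zero
  st2 <- coh$streams[[pid]]
  st2$steps <- NULL; st2$heart_rate <- NULL; st2$sleep <- NULL
  row2 <- extract_all(st2, m, d)
  expect_true(is.na(row2$sumsteps))
  expect_true(is.na(row2$min_hr))
  expect_equal(row2$total_minutes_asleep, 0)
})

test_that("features are invariant to a +24 h shift of all timestamps", {
  coh <- test_cohort()
  pid <- coh$meta$participant_id[1]
  m <- coh$meta[participant_id == pid]
  d <- m$surgery_date + 12
  st <- coh$streams[[pid]]
  shift <- function(dt, kind) {
    out <- data.table::copy(dt)
    for (cc in intersect(c("timestamp", "start", "end"), names(out))) {
      out[[cc]] <- out[[cc]] + 86400000
    }
    out
  }
  st24 <- Map(shift, st, names(st))
  a <- extract_all(st, m, d)
  b <- extract_all(st24, m, as.Date(d) + 1)
  expect_equal(b, a)
})

test_that("indexed cohort extraction equals the direct per-day extractor", {
  coh <- test_cohort()
  feats <- test_features()
  pid <- coh$meta$participant_id[3]
  m <- coh$meta[participant_id == pid]
  for (d in as.list(m$study_start + c(2, 15, 25))) {
    direct <- extract_all(coh$streams[[pid]], m, d)
    row <- feats[participant_id == pid & date == as.Date(d)]
    for (nm in names(direct)) {
      expect_equal(row[[nm]], direct[[nm]], info = paste(d, nm))
    }
  }
})
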