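#' Simulation configuration for a synthetic perioperative cohort
#'
#' Parameters mirror the structure of a perioperative mobile-sensing
#' study: a preoperative baseline window, an inpatient stay, up to 60
#' days of post-discharge follow-up, a surgery-related bump in daily
#' symptom burden that decays exponentially, day-to-day burden
#' autocorrelation, and a configurable coupling between symptom state and
#' behavior (fewer/shorter active bouts, more fragmented sleep, higher
#' minimum heart rate, more time at the home location, lower peak ambient
#' light, more screen time on high-burden days).
#'
#' @param n_participants Number of participants (default 44).
#' @param preop_days Days observed before surgery (default 14).
#' @param inpatient_mean,inpatient_min,inpatient_max Inpatient stay length
#'   distribution: `inpatient_min + Poisson(inpatient_mean - inpatient_min)`
#'   truncated at `inpatient_max` (defaults 7, 2, 22 days).
#' @param postdischarge_days Follow-up days after discharge (default 60).
#' @param readmission_prob Probability a participant has one readmission
#'   interval during follow-up (default 0.30).
#' @param baseline_mean,baseline_sd Per-participant mean composite burden
#'   (0-100 scale) drawn Normal(15, 5).
#' @param rho AR(1) coefficient of the daily burden noise (default 0.5).
#' @param innovation_sd Innovation SD of the Gaussian AR(1) noise
#'   (default 4 composite points).
#' @param flare_prob Daily probability of a right-tail symptom flare
#'   (default 0.25).  Flares add a Gamma(`flare_shape`, `flare_scale`)
#'   spike to that day's burden; this right skew is what makes
#'   above-own-mean days a minority (roughly a third) after
#'   person-mean centering, as observed in perioperative
#'   symptom-diary cohorts.
#' @param flare_shape,flare_scale Gamma parameters of the flare spike
#'   (defaults 2 and 6: mean 12 points).
#' @param bump_height Burden increase at surgery (default +30 points).
#' @param bump_half_life Half-life of the post-surgery exponential decay
#'   (default 10 days).
#' @param beta Standardized shift of each coupled behavioral channel on
#'   high-burden days (default 0.8; 0 gives the uncoupled null scenario).
#' @param missing_fraction Mean fraction of participant-day sensor cells
#'   removed by [inject_missingness()] (default 0.07; observed range in
#'   comparable cohorts roughly 0 to 0.19).
#' @param timezone IANA timezone shared by the cohort.
#' @param anchor_date First possible surgery date.
#' @param seed RNG seed; the whole cohort is deterministic given it.
#' @return A validated config list of class `persense_sim_config`.
#' @export
sim_config <- function(n_participants = 44, preop_days = 14,
                       inpatient_mean = 7, inpatient_min = 2, inpatient_max = 22,
                       postdischarge_days = 60, readmission_prob = 0.30,
                       baseline_mean = 15, baseline_sd = 5,
                       rho = 0.5, innovation_sd = 4,
                       flare_prob = 0.25, flare_shape = 2, flare_scale = 6,
                       bump_height = 30, bump_half_life = 10,
                       beta = 0.8, missing_fraction = 0.07,
                       timezone = "America/New_York",
                       anchor_date = as.Date("2017-03-01"), seed = 1) {
  stopifnot(
    n_participants >= 1, preop_days >= 1, postdischarge_days >= 1,
    readmission_prob >= 0, readmission_prob <= 1,
    rho > -1, rho < 1, bump_half_life > 0,
    flare_prob >= 0, flare_prob <= 1, flare_shape > 0, flare_scale >= 0,
    missing_fraction >= 0, missing_fraction <= 0.5,
    inpatient_min >= 1, inpatient_max >= inpatient_min
  )
  cfg <- as.list(environment())
  cfg$anchor_date <- as.Date(anchor_date)
  class(cfg) <- "persense_sim_config"
  cfg
}

#' Null-scenario configuration
#'
#' Convenience wrapper for the no-signal scenario: behavior-symptom
#' coupling off (`beta = 0`), no day-to-day autocorrelation
#' (`rho = 0`), no surgery bump (`bump_height = 0`), and no symptom
#' flares (`flare_prob = 0`), so daily burden is iid Gaussian noise and
#' high/low labels are an unpredictable fair coin.  Every latent
#' component is removed, not just the behavioral coupling: the bump
#' would make days-since-surgery a real predictor, and the skewed
#' flares would move label prevalence away from one half, so a "null"
#' keeping either would not be a no-signal benchmark.  Used to check
#' that the modeling stack does not manufacture signal.
#'
#' @param ... Overrides passed to [sim_config()].
#' @export
null_config <- function(...) {
  sim_config(beta = 0, rho = 0, bump_height = 0, flare_prob = 0, ...)
}

## split `points` rating points across the 10 symptoms: multinomial with
## fixed weights (pain .2, fatigue .2, bowel .15, rest spread), each
## symptom capped at 10; overflow redistributed.  Sum is preserved
## exactly whenever points <= 100.
.symptom_weights <- c(pain = 0.20, fatigue = 0.20, bowel = 0.15,
                      sleep_disturbance = 0.45 / 7, concentration = 0.45 / 7,
                      sadness = 0.45 / 7, anxiety = 0.45 / 7,
                      dyspnea = 0.45 / 7, numbness = 0.45 / 7, nausea = 0.45 / 7)

.decompose_points <- function(points) {
  w <- .symptom_weights[symptom_names()]
  v <- as.vector(rmultinom(1, points, w))
  excess <- sum(pmax(v - 10L, 0L))
  v <- pmin(v, 10L)
  while (excess > 0L) {
    room <- which(v < 10L)
    if (length(room) == 0L) break
    idx <- if (length(room) == 1L) room else sample(room, 1L, prob = w[room])
    v[idx] <- v[idx] + 1L
    excess <- excess - 1L
  }
  v
}

#' Generate a synthetic perioperative cohort
#'
#' Produces raw minute-level sensor streams, daily 10-symptom diaries,
#' and participant metadata with the statistical structure the analysis
#' pipeline assumes.  The latent daily burden is
#' `b_t = mu_i + B * exp(-lambda * (t - t_surgery)) + e_t` (bump only
#' from surgery onward), with `e_t` an AR(1) process, clipped to
#' \[0, 100\]; diary ratings are a weighted multinomial decomposition of
#' `round(b_t)`.  Behavioral channels are generated minute-by-minute
#' with day-level targets shifted by `beta` standard deviations on
#' high-burden days (high = above that participant's own latent mean).
#'
#' @param config A [sim_config()] object.
#' @return A list of class `persense_cohort`: `meta` (participant
#'   metadata with serialized readmission intervals), `diary` (one row
#'   per participant-day), `streams` (per participant, per stream kind),
#'   `truth` (latent per-day burden, high/low indicator, hospital flag,
#'   and the day-level behavioral targets -- for validation only), and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "persense_sim_config"))
  set.seed(config$seed)
  tz <- config$timezone
  metas <- list(); diaries <- list(); truths <- list(); streams <- list()

  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    age <- sample(40:82, 1)
    surgery <- config$anchor_date + sample(0:180, 1)
    stay <- min(config$inpatient_max,
                config$inpatient_min + rpois(1, config$inpatient_mean - config$inpatient_min))
    study_start <- surgery - config$preop_days
    discharge <- surgery + stay
    study_end <- discharge + config$postdischarge_days
    readm <- ""
    if (runif(1) < config$readmission_prob) {
      rs <- discharge + sample(5:40, 1)
      re <- rs + sample(2:6, 1)
      if (re <= study_end - 1) readm <- paste(rs, re, sep = ":")
    }
    dates <- seq(study_start, study_end, by = "day")
    nd <- length(dates)
    hosp <- dates >= surgery & dates <= discharge
    if (nzchar(readm)) {
      iv <- as.Date(strsplit(readm, ":", fixed = TRUE)[[1]])
      hosp <- hosp | (dates >= iv[1] & dates <= iv[2])
    }

    ## latent burden
    mu <- min(40, max(2, rnorm(1, config$baseline_mean, config$baseline_sd)))
    e <- numeric(nd)
    e[1] <- rnorm(1, 0, config$innovation_sd / sqrt(1 - config$rho^2))
    if (nd > 1) for (t in 2:nd) e[t] <- config$rho * e[t - 1] + rnorm(1, 0, config$innovation_sd)
    lambda <- log(2) / config$bump_half_life
    dd <- as.numeric(dates - surgery)
    bump <- ifelse(dd >= 0, config$bump_height * exp(-lambda * dd), 0)
    ## right-tail flares: bad symptom days are spikes above a lower
    ## typical level, so above-own-mean days are a minority
    flare <- rbinom(nd, 1, config$flare_prob) *
      rgamma(nd, shape = config$flare_shape, scale = config$flare_scale)
    b <- pmin(100, pmax(0, mu + bump + e + flare))
    h <- as.integer(b > mean(b))

    ## day-level behavioral targets (coupling: effect size beta between
    ## high and low latent-burden days, signs per the coupling model)
    beta <- config$beta
    A <- pmax(0, 150 - beta * 35 * h + rnorm(nd, 0, 35))      # active minutes (down)
    A[hosp] <- A[hosp] * 0.3
    W <- pmax(5, round(30 + beta * 15 * h + rnorm(nd, 0, 12))) # awake-in-sleep minutes (up)
    mhr <- 55 + beta * 4 * h + rnorm(nd, 0, 3)                 # minimum heart rate (up)
    homefrac <- pmin(0.98, pmax(0.30, 0.70 + beta * 0.12 * h + rnorm(nd, 0, 0.10)))
    luxlog <- 6.0 - beta * 0.5 * h + rnorm(nd, 0, 0.4)         # daytime log-lux (down)
    Stot <- pmax(20, 170 + beta * 45 * h + rnorm(nd, 0, 45))   # screen minutes (up)

    ## diary (one row per day; completed each morning)
    ratings <- t(vapply(round(b), .decompose_points, integer(10)))
    colnames(ratings) <- symptom_names()
    diaries[[pid]] <- data.table::data.table(
      participant_id = pid, date = dates, ratings
    )

    ## anchors for the location model (home vs away; hospital when admitted)
    home <- c(lat = 40.44 + runif(1, -0.05, 0.05), lon = -79.99 + runif(1, -0.05, 0.05))
    away <- home + c(runif(1, 0.01, 0.03), runif(1, 0.01, 0.03))
    hosp_anchor <- c(lat = 40.4406, lon = -79.9610)

    acc <- .stream_accumulator()
    for (t in seq_len(nd)) {
      d0 <- day_start_ms(dates[t], tz)
      .simulate_day(acc, d0, active_target = A[t], awake_target = W[t],
                    min_hr = mhr[t], homefrac = homefrac[t], luxlog = luxlog[t],
                    screen_target = Stot[t],
                    home = if (hosp[t]) hosp_anchor else home, away = away,
                    in_hospital = hosp[t])
    }
    streams[[pid]] <- .collect_streams(acc)

    metas[[pid]] <- data.table::data.table(
      participant_id = pid, age = age, timezone = tz,
      surgery_date = surgery, discharge_date = discharge,
      study_start = study_start, study_end = study_end,
      readmissions = readm
    )
    truths[[pid]] <- data.table::data.table(
      participant_id = pid, date = dates, burden = b, high = h,
      hospital = hosp, active_target = A, awake_target = W,
      minhr_target = mhr, homefrac_target = homefrac,
      luxlog_target = luxlog, screen_target = Stot
    )
  }

  out <- list(meta = data.table::rbindlist(metas),
              diary = data.table::rbindlist(diaries),
              streams = streams,
              truth = data.table::rbindlist(truths),
              config = config)
  class(out) <- "persense_cohort"
  out
}

## mutable accumulator of per-stream column vectors (environment so the
## per-day generator can append in place)
.stream_accumulator <- function() {
  acc <- new.env(parent = emptyenv())
  acc$bufs <- list()
  acc
}

.acc_add <- function(acc, kind, cols) {
  acc$bufs[[kind]] <- c(acc$bufs[[kind]], list(cols))
}

.collect_streams <- function(acc) {
  out <- list()
  for (kind in names(stream_schemas())) {
    bufs <- acc$bufs[[kind]]
    if (is.null(bufs)) { out[[kind]] <- empty_stream(kind); next }
    cols <- lapply(names(bufs[[1]]), function(nm) unlist(lapply(bufs, `[[`, nm), use.names = FALSE))
    names(cols) <- names(bufs[[1]])
    dt <- data.table::as.data.table(cols)
    data.table::setorderv(dt, stream_schemas()[[kind]]$time_col)
    out[[kind]] <- dt
  }
  out
}

## generate all streams for one participant-day (civil minutes 0..1439;
## sleep window 23:00 prev -> 07:00, waking window 07:00 -> 23:00)
.simulate_day <- function(acc, d0, active_target, awake_target, min_hr,
                          homefrac, luxlog, screen_target, home, away,
                          in_hospital) {
  MIN <- 60000
  waking <- 420:1379
  asleep_min <- c(0:419, 1380:1439)

  ## --- active-minute placement (bout blocks in 30-min slots) ----------
  n_active <- min(900, round(active_target))
  active_idx <- integer(0)
  if (n_active > 0) {
    k <- max(1L, min(30L, ceiling(n_active / 20)))
    slots <- sort(sample(seq(420L, 1350L, by = 30L), k))
    lens <- as.vector(rmultinom(1, n_active, rep(1, k)))
    lens <- pmin(lens, 29L)
    active_idx <- unlist(lapply(seq_len(k), function(i) {
      if (lens[i] == 0L) integer(0) else slots[i]:(slots[i] + lens[i] - 1L)
    }))
  }
  active_ind <- integer(1440); active_ind[active_idx + 1L] <- 1L

  ## --- wearable: steps, heart rate ------------------------------------
  steps <- integer(1440)
  steps[waking + 1L] <- pmin(8L, rpois(length(waking), 0.8))
  steps[active_idx + 1L] <- 10L + rpois(length(active_idx), 30)
  ts_min <- d0 + (0:1439) * MIN
  .acc_add(acc, "steps", list(timestamp = ts_min, steps = steps))

  hr <- min_hr + rgamma(1440, shape = 2, scale = 5)
  hr[asleep_min + 1L] <- min_hr + rgamma(length(asleep_min), shape = 2, scale = 2)
  hr <- hr + 25 * active_ind
  hr <- pmin(200L, pmax(40L, as.integer(round(hr))))
  .acc_add(acc, "heart_rate", list(timestamp = ts_min, bpm = hr))

  ## --- sleep episodes (main sleep ends 07:00 this day) -----------------
  span <- 480
  awake <- min(awake_target, 200)
  .acc_add(acc, "sleep", list(
    start = d0 - 60 * MIN, end = d0 + 420 * MIN,
    minutes_asleep = span - awake, minutes_awake = awake, is_main_sleep = TRUE
  ))
  if (runif(1) < 0.25) {
    .acc_add(acc, "sleep", list(
      start = d0 + 810 * MIN, end = d0 + 850 * MIN,
      minutes_asleep = 35, minutes_awake = 5, is_main_sleep = FALSE
    ))
  }

  ## --- phone accelerometer (1 sample / minute) -------------------------
  dev <- 0.05 + 0.75 * active_ind + abs(rnorm(1440, 0, 0.03))
  .acc_add(acc, "accelerometer", list(
    timestamp = ts_min, x = rnorm(1440, 0, 0.01), y = rnorm(1440, 0, 0.01),
    z = .G + dev
  ))

  ## --- location (fix every 2 min while awake) --------------------------
  fix_min <- seq(420L, 1378L, by = 2L)
  away_len <- round((1 - homefrac) * 960)
  at_away <- rep(FALSE, length(fix_min))
  if (away_len >= 4 && !in_hospital) {
    a0 <- sample(480:900, 1)
    at_away <- fix_min >= a0 & fix_min < (a0 + away_len)
  }
  lat <- ifelse(at_away, away["lat"], home["lat"]) + rnorm(length(fix_min), 0, 15) / 111320
  lon <- ifelse(at_away, away["lon"], home["lon"]) +
    rnorm(length(fix_min), 0, 15) / (111320 * cos(home["lat"] * pi / 180))
  accuracy <- runif(length(fix_min), 5, 30)
  bad <- runif(length(fix_min)) < 0.03
  accuracy[bad] <- runif(sum(bad), 110, 200)
  .acc_add(acc, "location", list(
    timestamp = d0 + fix_min * MIN, latitude = lat, longitude = lon, accuracy = accuracy
  ))

  ## --- ambient light (sample every 10 min) -----------------------------
  lmin <- seq(0L, 1439L, by = 10L)
  is_day <- lmin >= 420 & lmin <= 1320
  lux <- numeric(length(lmin))
  lux[is_day] <- exp(rnorm(sum(is_day), luxlog, 0.5))
  lux[!is_day] <- exp(rnorm(sum(!is_day), 1, 0.5))
  .acc_add(acc, "light", list(timestamp = d0 + lmin * MIN, lux = lux))

  ## --- screen sessions --------------------------------------------------
  ns <- max(1L, rpois(1, 18))
  starts <- sort(sample(420:1380, ns))
  durs <- rexp(ns, rate = ns / screen_target)
  gap_cap <- c(diff(starts) - 1, 1439 - starts[ns])
  durs <- pmax(1, pmin(durs, pmin(gap_cap, 90)))
  .acc_add(acc, "screen", list(
    timestamp = c(d0 + starts * MIN, d0 + (starts + durs) * MIN),
    state = c(rep("unlocked", ns), rep("locked", ns))
  ))

  ## --- communication ----------------------------------------------------
  nc <- rpois(1, 1.5)
  if (nc > 0) {
    dirs <- sample(c("incoming", "outgoing", "missed"), nc, replace = TRUE,
                   prob = c(0.4, 0.4, 0.2))
    .acc_add(acc, "calls", list(
      timestamp = d0 + sample(waking, nc) * MIN, direction = dirs,
      duration = ifelse(dirs == "missed", 0, round(rexp(nc, 1 / 180))),
      contact_hash = sample(paste0("c", 1:8), nc, replace = TRUE)
    ))
  }
  nm <- rpois(1, 3)
  if (nm > 0) {
    .acc_add(acc, "sms", list(
      timestamp = d0 + sample(waking, nm) * MIN,
      direction = sample(c("incoming", "outgoing"), nm, replace = TRUE),
      contact_hash = sample(paste0("c", 1:8), nm, replace = TRUE)
    ))
  }

  ## --- battery (hourly) -------------------------------------------------
  charging <- rep(FALSE, 24); charging[1:2] <- TRUE
  if (runif(1) < 0.4) charging[14] <- TRUE
  level <- numeric(24); lv <- 70
  for (hh in 1:24) {
    lv <- min(100, max(5, lv + if (charging[hh]) 15 else -3))
    level[hh] <- lv
  }
  .acc_add(acc, "battery", list(
    timestamp = d0 + (0:23) * 60 * MIN, level = level,
    status = ifelse(charging, "charging", "discharging")
  ))

  ## --- conversation episodes -------------------------------------------
  nv <- rpois(1, 4)
  if (nv > 0) {
    cs <- sample(waking, nv) * MIN
    .acc_add(acc, "conversation", list(
      start = d0 + cs, end = d0 + cs + round(runif(nv, 2, 20)) * MIN
    ))
  }

  ## --- activity recognition (events on state change) --------------------
  act <- rep("still", 1440)
  act[active_idx + 1L] <- "walking"
  if (any(at_away)) {
    tr <- range(fix_min[at_away])
    act[(tr[1] + 1L):min(1440L, tr[1] + 10L)] <- "in_vehicle"
    act[(tr[2] + 1L):min(1440L, tr[2] + 10L)] <- "in_vehicle"
  }
  r <- rle(act)
  ev_min <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  .acc_add(acc, "activity", list(
    timestamp = d0 + ev_min * MIN, activity = r$values
  ))
  invisible(NULL)
}

#' Remove sensor data to emulate real-world missingness
#'
#' Removal operates on whole sensor-days: a unit is one (participant,
#' date, stream kind) cell, and removing it deletes every record of that
#' stream on that local date.  Half of each participant's removed cells
#' come in multi-day blocks (3-7 consecutive days of one stream, as when
#' a device goes unworn or uncharged), half as scattered single days.
#' Per-participant removal fractions are drawn around `fraction` (Beta
#' distributed, capped at 0.195) so the cohort shows realistic spread.
#' Diary rows are never touched.
#'
#' @param cohort A `persense_cohort`.
#' @param fraction Mean fraction of sensor-day cells to remove, in
#'   \[0, 0.5\].
#' @param seed RNG seed.
#' @return The cohort with records removed; attribute
#'   `missingness_report` is a table of per-participant target and
#'   realized fractions.
#' @export
inject_missingness <- function(cohort, fraction = 0.07, seed = 1) {
  force(cohort)   # evaluate before touching the RNG
  stopifnot(fraction >= 0, fraction <= 0.5)
  if (fraction == 0) {
    data.table::setattr(cohort, "missingness_report",
      data.table::data.table(participant_id = names(cohort$streams),
                             target_fraction = 0, realized_fraction = 0))
    return(cohort)
  }
  set.seed(seed)
  kinds <- names(stream_schemas())
  tz_by <- setNames(cohort$meta$timezone, cohort$meta$participant_id)
  rep_list <- list()
  for (pid in names(cohort$streams)) {
    m <- cohort$meta[participant_id == pid]
    dates <- seq(m$study_start, m$study_end, by = "day")
    ncells <- length(dates) * length(kinds)
    fp <- min(0.195, rbeta(1, 2, 2 * (1 - fraction) / fraction))
    n_remove <- round(fp * ncells)
    removed <- data.table::data.table(kind = character(), date = as.Date(character()))
    ## block removals (~half the budget)
    while (nrow(removed) < n_remove / 2) {
      k <- sample(kinds, 1)
      len <- sample(3:7, 1)
      s <- sample(seq_along(dates), 1)
      blk <- dates[s:min(length(dates), s + len - 1L)]
      removed <- unique(rbind(removed, data.table::data.table(kind = k, date = blk)))
    }
    ## scattered single days
    while (nrow(removed) < n_remove) {
      cand <- data.table::data.table(kind = sample(kinds, 1), date = sample(dates, 1))
      removed <- unique(rbind(removed, cand))
    }
    for (k in unique(removed$kind)) {
      dt <- cohort$streams[[pid]][[k]]
      if (is.null(dt) || nrow(dt) == 0L) next
      tcol <- stream_schemas()[[k]]$time_col
      ld <- local_date(dt[[tcol]], tz_by[[pid]])
      cohort$streams[[pid]][[k]] <- dt[!(ld %in% removed[kind == k]$date)]
    }
    rep_list[[pid]] <- data.table::data.table(
      participant_id = pid, target_fraction = fp,
      realized_fraction = nrow(removed) / ncells
    )
  }
  data.table::setattr(cohort, "missingness_report", data.table::rbindlist(rep_list))
  cohort
}
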