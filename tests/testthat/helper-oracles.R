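## Independent brute-force oracles.  Each reimplements a feature
## definition by direct per-minute / per-event enumeration, sharing no
## code with the package implementations.

## active/sedentary bouts by walking the recorded minutes one by one
oracle_step_bouts <- function(minutes, steps, thr = 10, min_len = 1) {
  active_lens <- integer(0); sed_lens <- integer(0)
  cur_len <- 0L; cur_active <- NA
  flush <- function() {
    if (cur_len == 0L) return()
    if (isTRUE(cur_active) && cur_len >= min_len) {
      active_lens <<- c(active_lens, cur_len)
    } else {
      sed_lens <<- c(sed_lens, cur_len)
    }
  }
  prev_min <- NA
  for (i in seq_along(minutes)) {
    a <- steps[i] >= thr
    new_run <- is.na(prev_min) || minutes[i] != prev_min + 1L || !identical(a, cur_active)
    if (new_run) { flush(); cur_len <- 0L; cur_active <- a }
    cur_len <- cur_len + 1L
    prev_min <- minutes[i]
  }
  flush()
  ## a too-short "active" run counts as sedentary, matching the spec
  ## that sedentary bouts are the complement over recorded minutes
  list(n_active_bouts = length(active_lens),
       total_active_minutes = sum(active_lens),
       max_active_bout_minutes = if (length(active_lens)) max(active_lens) else 0,
       n_sedentary_bouts = length(sed_lens),
       total_sedentary_minutes = sum(sed_lens))
}

## episodes from labeled windows by explicit enumeration
oracle_episodes <- function(win_idx, exertional, window_s = 60, max_gap_s = 300) {
  eps <- list()
  cur <- NULL
  for (i in seq_along(win_idx)) {
    brk <- is.null(cur) ||
      (win_idx[i] - cur$last) * window_s > max_gap_s ||
      exertional[i] != cur$label
    if (brk) {
      if (!is.null(cur)) eps[[length(eps) + 1L]] <- cur
      cur <- list(label = exertional[i], n = 0L, last = win_idx[i])
    }
    cur$n <- cur$n + 1L
    cur$last <- win_idx[i]
  }
  if (!is.null(cur)) eps[[length(eps) + 1L]] <- cur
  lab <- vapply(eps, `[[`, logical(1), "label")
  mins <- vapply(eps, `[[`, integer(1), "n") * window_s / 60
  list(n_exertional = sum(lab),
       total_exertional_minutes = sum(mins[lab]),
       median_nonexertional = if (any(!lab)) median(mins[!lab]) else 0,
       max_nonexertional = if (any(!lab)) max(mins[!lab]) else 0)
}

## per-sample heart-rate zone assignment with explicit if/else
oracle_hr_zones <- function(bpm, age) {
  hrmax <- 220 - age
  z <- c(below = 0, fatburn = 0, cardio = 0, peak = 0)
  for (b in bpm) {
    f <- b / hrmax
    if (f < 0.5) z["below"] <- z["below"] + 1
    else if (f < 0.7) z["fatburn"] <- z["fatburn"] + 1
    else if (f < 0.85) z["cardio"] <- z["cardio"] + 1
    else z["peak"] <- z["peak"] + 1
  }
  z
}

## screen sessions by an explicit state machine over events
oracle_screen <- function(minute, state, day_minutes = 1440) {
  sessions <- numeric(0); open <- NA_real_
  for (i in seq_along(minute)) {
    if (state[i] == "unlocked" && is.na(open)) open <- minute[i]
    if (state[i] %in% c("locked", "off") && !is.na(open)) {
      sessions <- c(sessions, min(minute[i], day_minutes) - open)
      open <- NA_real_
    }
  }
  if (!is.na(open)) sessions <- c(sessions, day_minutes - open)
  sessions
}

## forward-fill durations for event streams (activity, battery)
oracle_forward_fill <- function(minute, token, day_minutes = 1440) {
  out <- setNames(numeric(0), character(0))
  for (i in seq_along(minute)) {
    dur <- (if (i < length(minute)) minute[i + 1] else day_minutes) - minute[i]
    out[token[i]] <- (if (token[i] %in% names(out)) out[[token[i]]] else 0) + dur
  }
  out
}

## Mann-Whitney AUC via pROC (independent of the package's rank formula)
oracle_auc <- function(y, prob) {
  as.numeric(suppressMessages(pROC::auc(pROC::roc(y, prob, quiet = TRUE,
                                                  direction = "<"))))
}

## confusion-matrix metrics by direct counting
oracle_confusion <- function(y, pred) {
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  pr1 <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc1 <- if (tp + fn > 0) tp / (tp + fn) else 0
  pr0 <- if (tn + fn > 0) tn / (tn + fn) else 0
  rc0 <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0
  list(accuracy = (tp + tn) / length(y),
       precision_0 = pr0, recall_0 = rc0, f1_0 = f1(pr0, rc0),
       precision_1 = pr1, recall_1 = rc1, f1_1 = f1(pr1, rc1))
}

## independent local-date via strftime (vs the package's gmtoff arithmetic)
oracle_local_date <- function(ts_ms, tz) {
  as.Date(format(as.POSIXct(ts_ms / 1000, origin = "1970-01-01", tz = tz),
                 "%Y-%m-%d", tz = tz))
}

## union-find transitive closure DBSCAN oracle over haversine distances
oracle_location_clusters <- function(lat, lon, eps_m = 30, min_pts = 3) {
  n <- length(lat)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D[i, ] <- geosphere::distHaversine(cbind(lon[i], lat[i]), cbind(lon, lat))
  }
  A <- D <= eps_m
  core <- rowSums(A) >= min_pts
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in which(core)) for (j in which(core & A[i, ])) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  labels <- rep(0L, n)
  roots <- unique(vapply(which(core), find, integer(1)))
  for (k in seq_along(roots)) {
    labels[core][vapply(which(core), find, integer(1)) == roots[k]] <- k
  }
  ## border points join a reachable core cluster
  for (i in which(!core)) {
    nb <- which(A[i, ] & core)
    if (length(nb)) labels[i] <- labels[nb[1]]
  }
  labels
}
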