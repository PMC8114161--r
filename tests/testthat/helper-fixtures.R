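## Shared fixtures, built in code and cached for the duration of the
## test run (simulation and extraction are the expensive steps).

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

TEST_TZ <- "America/New_York"

## epoch ms helper for fixture construction
ms_at <- function(date, minute, tz = TEST_TZ) {
  as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = tz)) * 1000 + minute * 60000
}

## small coupled cohort shared across label/prepare/model tests
test_cohort <- function() {
  .memo("cohort", function() {
    simulate_cohort(sim_config(n_participants = 5, preop_days = 7,
                               postdischarge_days = 24, seed = 11))
  })
}

test_features <- function() {
  .memo("features", function() extract_features(test_cohort()))
}

## labeled modeling table for the small cohort
test_prepared <- function() {
  .memo("prepared", function() {
    prepare_experiment(test_cohort(), target = "burden",
                       features = test_features())
  })
}

## small labeled table with known structure for modeling unit tests:
## 2 informative features + noise, autocorrelation-free
toy_labeled <- function(n_participants = 4, n_days = 12, seed = 3,
                        separable = FALSE) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_participants)) {
    y <- rbinom(n_days, 1, 0.4)
    f1 <- y * 2 + rnorm(n_days, 0, if (separable) 0.01 else 1)
    f2 <- -y + rnorm(n_days, 0, if (separable) 0.01 else 1)
    rows[[p]] <- data.table::data.table(
      participant_id = sprintf("P%02d", p),
      date = as.Date("2020-01-01") + seq_len(n_days) - 1,
      f1 = f1, f2 = f2, noise = rnorm(n_days),
      days_since_surgery = seq_len(n_days) - 5,
      most_recent_score = rnorm(n_days, 15, 4),
      running_mean_score = rnorm(n_days, 15, 2),
      y = y)
  }
  data.table::rbindlist(rows)
}
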