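mk_meta <- function(pid = "P01", surgery = "2020-02-01", discharge = "2020-02-08",
                    readm = "") {
  data.table::data.table(participant_id = pid,
                         surgery_date = as.Date(surgery),
                         discharge_date = as.Date(discharge),
                         readmissions = readm)
}

test_that("hospital-day exclusion drops closed intervals", {
  meta <- mk_meta(readm = "2020-02-20:2020-02-22")
  rows <- data.table::data.table(
    participant_id = "P01",
    date = as.Date("2020-01-25") + 0:35)
  kept <- drop_hospital_days(rows, meta)
  ## surgery through discharge inclusive is gone
  expect_false(as.Date("2020-02-01") %in% kept$date)
  expect_false(as.Date("2020-02-08") %in% kept$date)   # discharge dropped
  expect_true(as.Date("2020-02-09") %in% kept$date)    # discharge + 1 kept
  ## readmission interval closed on both ends
  expect_false(any(as.Date(c("2020-02-20", "2020-02-22")) %in% kept$date))
  expect_true(as.Date("2020-02-23") %in% kept$date)

  ## random calendars equal direct interval arithmetic
  set.seed(15)
  for (rep in 1:10) {
    d <- as.Date("2020-01-01") + sort(sample(0:60, 30))
    rows <- data.table::data.table(participant_id = "P01", date = d)
    kept <- drop_hospital_days(rows, meta)
    in_hosp <- (d >= meta$surgery_date & d <= meta$discharge_date) |
      (d >= as.Date("2020-02-20") & d <= as.Date("2020-02-22"))
    expect_equal(kept$date, d[!in_hosp])
  }
})

## a hand-built 3-participant matrix exercising every cleaning rule
cleaning_fixture <- function() {
  mk <- function(pid, n, cov, f1, f2, f3) {
    data.table::data.table(participant_id = pid,
                           date = as.Date("2020-01-01") + seq_len(n) - 1,
                           coverage_hours = cov, f1 = f1, f2 = f2, f3 = f3)
  }
  rbind(
    ## P01: 10 days, one below the coverage cutoff, one exactly at it
    mk("P01", 10, c(19.9, 20, rep(24, 8)),
       f1 = c(NA, NA, NA, 4:10), f2 = rnorm(10), f3 = 1),
    ## P02: only 4 high-coverage days -> dropped as a participant
    mk("P02", 4, 24, f1 = 1:4, f2 = rnorm(4), f3 = 1),
    ## P03: 8 days; one day missing everything except f3
    mk("P03", 8, 24, f1 = c(NA, 2:8), f2 = c(NA, rnorm(7)), f3 = 1)
  )
}

test_that("cleaning applies the quoted steps in order with strict thresholds", {
  set.seed(16)
  fx <- cleaning_fixture()
  res <- clean(fx, min_coverage = 20, min_days = 5, max_missing = 0.3)
  rep <- res$report

  ## 19.9 h dropped at step 1; the 20.0 h day survives step 1 (it is
  ## later dropped by the day-missingness rule, not the coverage rule)
  expect_equal(rep$days_dropped_low_coverage, 1)
  expect_false(as.Date("2020-01-01") %in% res$data[participant_id == "P01"]$date)

  ## P02 had 4 days < 5
  expect_equal(rep$participants_dropped_few_days, 1)
  expect_false("P02" %in% res$data$participant_id)

  ## f3 is constant -> dropped; f1 after day drops: P01 has NA on days
  ## 2,3 (day 1 dropped), P03 day 1 -> 3/17 missing = 17.6% -> kept
  expect_equal(rep$features_dropped_missing_or_constant, 1)
  expect_false("f3" %in% names(res$data))

  ## days missing > 30% of the 2 remaining features: P01 days 2-3
  ## (f1 NA = 50%) and P03 day 1 -> 3 days dropped
  expect_equal(rep$days_dropped_missing_features, 3)
  expect_equal(rep$final_n_days, nrow(res$data))
  expect_equal(rep$final_n_participants, 2)
  expect_equal(rep$final_n_features, 2)
})

test_that("a feature missing exactly 30% of days is kept", {
  set.seed(17)
  dt <- data.table::data.table(
    participant_id = "P01", date = as.Date("2020-01-01") + 0:9,
    coverage_hours = 24,
    f1 = c(rep(NA_real_, 3), rnorm(7)),   # exactly 30% missing
    f2 = rnorm(10))
  res <- clean(dt)
  expect_true("f1" %in% names(res$data))
  dt$f1[4] <- NA                          # now 40% -> dropped
  expect_false("f1" %in% names(clean(dt)$data))
})

test_that("cleaning is idempotent and errors when nothing survives", {
  set.seed(18)
  fx <- cleaning_fixture()
  once <- clean(fx)$data
  twice <- clean(once)$data
  expect_equal(twice, once)
  low <- data.table::copy(fx)[, coverage_hours := 10]
  expect_error(clean(low), "low-coverage")
})

test_that("cleaning merges labels and refilters participants", {
  set.seed(19)
  fx <- cleaning_fixture()
  ## labels on alternating days for P03 -> few consecutive pairs
  labels <- data.table::data.table(
    participant_id = rep(c("P01", "P03"), each = 10),
    date = rep(as.Date("2020-01-01") + 0:9, 2),
    label = rbinom(20, 1, 0.4))
  res <- clean(fx, labels = labels)
  expect_true("y" %in% names(res$data))
  expect_equal(res$report$final_n_days, nrow(res$data))
  ## every retained participant has at least 5 labeled rows
  expect_true(all(res$data[, .N, by = participant_id]$N >= 5))
})

test_that("imputation follows the three continuous rules", {
  tr <- data.table::data.table(
    participant_id = "A", date = as.Date("2020-01-01") + 0:2,
    f = c(4, NA, 8))
  ## rule 1: average of the 2 closest days
  got <- impute(tr, feature_cols = "f")
  expect_equal(got$train$f, c(4, 6, 8))

  ## rule 1 tie-break toward earlier days: neighbors at distance 1 both
  ## sides plus a far earlier day; the two closest are used
  tr2 <- data.table::data.table(
    participant_id = "A", date = as.Date("2020-01-01") + c(0, 3, 4, 5),
    f = c(100, 2, NA, 10))
  expect_equal(impute(tr2, feature_cols = "f")$train$f[3], 6)

  ## single valid day is used alone
  tr3 <- data.table::data.table(
    participant_id = "A", date = as.Date("2020-01-01") + 0:1, f = c(NA, 7))
  expect_equal(impute(tr3, feature_cols = "f")$train$f[1], 7)

  ## rule 2: test rows take the last valid training value
  te <- data.table::data.table(
    participant_id = "A", date = as.Date("2020-01-10"), f = NA_real_)
  got <- impute(tr, te, feature_cols = "f")
  expect_equal(got$test$f, 8)

  ## rule 3: participant with no valid training value borrows the
  ## cross-participant mean
  tr4 <- rbind(tr,
               data.table::data.table(participant_id = "B",
                                      date = as.Date("2020-01-01") + 0:1,
                                      f = c(NA_real_, NA_real_)))
  got <- impute(tr4, feature_cols = "f")
  expect_equal(got$train[participant_id == "B"]$f, c(6, 6))  # mean(4, 8)

  ## observed values are never altered
  expect_equal(got$train[participant_id == "A"]$f, c(4, 6, 8))
})

test_that("categorical imputation uses participant then cohort mode", {
  tr <- data.table::data.table(
    participant_id = c("A", "A", "A", "B", "B"),
    date = as.Date("2020-01-01") + c(0:2, 0:1),
    g = c("x", "y", NA, NA, NA))
  got <- impute(tr, feature_cols = "g")$train
  ## A's modes tie between x and y -> lexicographically smallest
  expect_equal(got[participant_id == "A"]$g[3], "x")
  ## B has no training value -> mode of the others (tie x/y -> x)
  expect_equal(got[participant_id == "B"]$g, c("x", "x"))
})

test_that("imputation errors when a feature has no donor anywhere", {
  tr <- data.table::data.table(participant_id = "A",
                               date = as.Date("2020-01-01") + 0:1,
                               f = c(NA_real_, NA_real_))
  expect_error(impute(tr, feature_cols = "f"), "no valid training value")
})

test_that("encoding and scaling fit on training rows only", {
  tr <- data.table::data.table(participant_id = "A",
                               date = as.Date("2020-01-01") + 0:3,
                               num = c(0, 10, 5, 5),
                               cat = c("a", "b", "a", "a"))
  te <- data.table::data.table(participant_id = "A",
                               date = as.Date("2020-01-05"),
                               num = 5, cat = "c")   # unseen category

  ## tree family passes numerics through unchanged
  enc <- encode_and_scale(tr, te, model_family = "boosted_trees")
  expect_equal(enc$train[, "num"], tr$num)
  ## unseen category -> all-zero indicators
  expect_equal(unname(enc$test[, c("cat=a", "cat=b")]), c(0, 0))

  ## min-max on train range [0, 10] maps a test 5 to 0.5
  enc <- encode_and_scale(tr, te, model_family = "logistic", scaler = "minmax")
  expect_equal(unname(enc$test[, "num"]), 0.5)
  expect_equal(range(enc$train[, "num"]), c(0, 1))

  ## robust scaling equals the (x - median)/IQR oracle
  set.seed(20)
  tr2 <- data.table::data.table(participant_id = "A",
                                date = as.Date("2020-01-01") + 0:19,
                                num = rnorm(20, 3, 2))
  enc <- encode_and_scale(tr2, model_family = "svm", scaler = "robust")
  expect_equal(unname(enc$train[, "num"]),
               (tr2$num - median(tr2$num)) / IQR(tr2$num))
})

test_that("mutual information ranks informative features first", {
  set.seed(21)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  ## a label-identical feature always ranks first
  X <- cbind(noise1 = rnorm(n), dup = as.numeric(y), noise2 = rnorm(n))
  expect_equal(select_features(X, y, k = 1), "dup")

  ## 5 informative + 100 noise features: at least 4 of 5 recovered
  informative <- sapply(1:5, function(i) y * runif(1, 1, 2) + rnorm(n))
  colnames(informative) <- paste0("inf", 1:5)
  noise <- matrix(rnorm(n * 100), n, 100,
                  dimnames = list(NULL, paste0("n", 1:100)))
  X <- cbind(informative, noise)
  sel <- select_features(X, y, k = 5)
  expect_gte(sum(grepl("^inf", sel)), 4)

  ## k >= p is the identity
  expect_equal(select_features(X, y, k = 500), colnames(X))
  ## constant features carry zero information
  expect_equal(mutual_information(rep(1, n), y), 0)
})

test_that("SVM-SMOTE balances classes with convex minority combinations", {
  set.seed(22)
  n0 <- 80; n1 <- 20
  X <- rbind(cbind(rnorm(n0, 0), rnorm(n0, 0)),
             cbind(rnorm(n1, 3), rnorm(n1, 3)))
  colnames(X) <- c("u", "v")
  y <- c(rep(0, n0), rep(1, n1))

  res <- resample_minority(X, y, seed = 0)
  expect_equal(sum(res$y == 1), sum(res$y == 0))   # parity contract
  ## synthetic rows lie within the minority bounding box coordinate-wise
  synth <- res$X[(n0 + n1 + 1):nrow(res$X), , drop = FALSE]
  expect_true(all(synth[, "u"] >= min(X[y == 1, "u"]) - 1e-12))
  expect_true(all(synth[, "u"] <= max(X[y == 1, "u"]) + 1e-12))
  expect_true(all(synth[, "v"] >= min(X[y == 1, "v"]) - 1e-12))
  expect_true(all(synth[, "v"] <= max(X[y == 1, "v"]) + 1e-12))

  ## balanced input is the identity
  Xb <- X[c(1:20, 81:100), ]; yb <- y[c(1:20, 81:100)]
  resb <- resample_minority(Xb, yb, seed = 0)
  expect_equal(resb$X, Xb)

  ## determinism given seed
  r1 <- resample_minority(X, y, seed = 7)
  r2 <- resample_minority(X, y, seed = 7)
  expect_identical(r1, r2)

  ## tiny minority falls back to duplication with a warning
  Xs <- X[c(1:40, 81:83), ]; ys <- y[c(1:40, 81:83)]
  expect_warning(ress <- resample_minority(Xs, ys, seed = 1), "duplication")
  expect_equal(sum(ress$y == 1), sum(ress$y == 0))
  expect_true(all(apply(ress$X[ress$y == 1, ], 1, function(r) {
    any(apply(Xs[ys == 1, , drop = FALSE], 1, function(o) all(o == r)))
  })))
})

test_that("the fold-loop imputation cache equals direct imputation", {
  prep <- test_prepared()
  data <- data.table::copy(prep$data)
  data.table::setorderv(data, c("participant_id", "date"))
  ## add an all-missing-for-one-participant feature to force rule 3
  ## through both paths
  set.seed(40)
  data[, synthetic_gap := rnorm(.N)]
  data[participant_id == data$participant_id[1], synthetic_gap := NA_real_]
  fcols <- feature_columns(data)
  folds <- make_folds(data)
  cache <- persense:::.impute_cache(data, fcols)
  for (i in unique(c(2, length(folds) %/% 3, length(folds) - 1))) {
    direct <- impute(data[folds[[i]]$train], data[folds[[i]]$test],
                     feature_cols = fcols)
    fast <- persense:::.impute_fold(cache, data, folds[[i]]$train,
                                    folds[[i]]$test)
    expect_equal(fast$train, direct$train, ignore_attr = "sorted",
                 info = paste("fold", i))
    expect_equal(fast$test, direct$test, ignore_attr = "sorted",
                 info = paste("fold", i))
  }
})

test_that("imputation and scaling never read test values", {
  prep <- test_prepared()
  data <- prep$data
  folds <- make_folds(data)
  i <- length(folds) %/% 2
  train <- data[folds[[i]]$train]
  test <- data[folds[[i]]$test]
  fcols <- feature_columns(data)

  a <- impute(train, test, feature_cols = fcols)
  ## poison every test-side feature value: training output unchanged
  poisoned <- data.table::copy(test)
  for (f in fcols) {
    poisoned[[f]] <- if (is.character(poisoned[[f]])) "still" else 1e6
  }
  b <- impute(train, poisoned, feature_cols = fcols)
  expect_identical(a$train, b$train)

  ea <- encode_and_scale(a$train, a$test, model_family = "logistic")
  eb <- encode_and_scale(a$train, NULL, model_family = "logistic")
  expect_identical(ea$train, eb$train)
})
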