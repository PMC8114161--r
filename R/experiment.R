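## End-to-end experiment orchestration: cohort -> features -> labels ->
## cleaning -> per-fold prepare (impute / encode / select / SMOTE, on
## training rows only) -> tune & fit -> pooled metrics -> SHAP ranking.

#' Build the labeled modeling table from a cohort
#'
#' Runs feature extraction, hospital-day exclusion (features and diary
#' alike), composite or single-symptom person-centered labeling
#' (person means computed over post-exclusion days), the three
#' non-sensor features, and the order-faithful cleaning/label merge.
#'
#' @param cohort A `persense_cohort` (simulated or read from disk).
#' @param target `"burden"` for the 10-symptom composite, or one of
#'   `"pain"`, `"fatigue"`, `"bowel"`.
#' @param features Optional pre-extracted day-feature table (skips
#'   extraction).
#' @param min_coverage,min_days,max_missing Cleaning thresholds, see
#'   [clean()].
#' @return List: `data` (labeled modeling table with `y`), `report`
#'   (cleaning report), `labels` (the per-day label table).
#' @export
prepare_experiment <- function(cohort, target = c("burden", "pain", "fatigue", "bowel"),
                               features = NULL, min_coverage = 20, min_days = 5,
                               max_missing = 0.3) {
  target <- match.arg(target)
  if (is.null(features)) features <- extract_features(cohort)
  features <- drop_hospital_days(features, cohort$meta)
  diary <- drop_hospital_days(cohort$diary, cohort$meta)
  labels <- if (target == "burden") {
    center_labels(composite_burden(diary))
  } else {
    single_symptom_labels(diary, target)
  }
  ## the composite always drives the three non-sensor score features
  composite <- composite_burden(diary)
  features <- nonsensor_features(composite, cohort$meta,
                                 days = features)
  cleaned <- clean(features, labels = labels, min_coverage = min_coverage,
                   min_days = min_days, max_missing = max_missing)
  list(data = cleaned$data, report = cleaned$report, labels = labels)
}

## Imputation cache for the fold loop.  For a fold testing participant
## p, the training set contains every OTHER participant's full row set,
## so their rule-1 (two-closest-days) imputations are identical across
## all folds not testing them and can be computed once.  Only p's past
## rows, the rule-3 cross-participant donor means (which must exclude
## p's post-test rows), and the test row are fold-specific.
.impute_cache <- function(data, fcols) {
  data <- data.table::as.data.table(data)
  num_cols <- fcols[!vapply(fcols, function(f) is.character(data[[f]]) ||
                              is.factor(data[[f]]), logical(1))]
  cat_cols <- setdiff(fcols, num_cols)
  pids <- unique(data$participant_id)
  ## per-participant full-series rule-1 imputation
  full <- lapply(pids, function(q) {
    impute(data[participant_id == q], feature_cols = fcols,
           .allow_all_missing = TRUE)$train
  })
  names(full) <- pids
  ## raw per-(participant, feature) valid sums/counts for donor means
  sums <- lapply(pids, function(q) {
    d <- data[participant_id == q]
    list(sum = vapply(num_cols, function(f) sum(d[[f]], na.rm = TRUE), numeric(1)),
         n = vapply(num_cols, function(f) sum(!is.na(d[[f]])), numeric(1)),
         dates = d$date,
         vals = as.matrix(d[, num_cols, with = FALSE]))
  })
  names(sums) <- pids
  list(full = full, sums = sums, num_cols = num_cols, cat_cols = cat_cols,
       pids = pids)
}

## fold-exact imputation using the cache; equals
## impute(train, test)$train / $test bit-for-bit (verified in tests)
.impute_fold <- function(cache, data, train_idx, test_idx) {
  p <- data$participant_id[test_idx]
  d <- data$date[test_idx]
  ## donor totals over THIS fold's training rows, per numeric feature
  fut <- cache$sums[[p]]$dates >= d
  tot_sum <- Reduce(`+`, lapply(cache$pids, function(q) cache$sums[[q]]$sum))
  tot_n <- Reduce(`+`, lapply(cache$pids, function(q) cache$sums[[q]]$n))
  p_fut_vals <- cache$sums[[p]]$vals[fut, , drop = FALSE]
  fut_sum <- colSums(p_fut_vals, na.rm = TRUE)
  fut_n <- colSums(!is.na(p_fut_vals))
  train_sum <- tot_sum - fut_sum
  train_n <- tot_n - fut_n

  parts <- list()
  for (q in setdiff(cache$pids, p)) {
    tq <- cache$full[[q]]
    ## features q never observed: donor mean over this fold's train rows
    for (f in cache$num_cols) {
      if (cache$sums[[q]]$n[[f]] == 0L) {
        donor_n <- train_n[[f]] - 0
        if (donor_n <= 0) stop("feature '", f, "' has no valid training value")
        tq <- data.table::copy(tq)
        data.table::set(tq, j = f, value = rep(train_sum[[f]] / donor_n, nrow(tq)))
      }
    }
    parts[[q]] <- tq
  }
  ## the test participant: impute past rows from past rows only
  own_past <- data[train_idx][participant_id == p]
  test_row <- data[test_idx]
  imp_p <- impute(own_past, test_row, feature_cols = c(cache$num_cols, cache$cat_cols),
                  .allow_all_missing = TRUE)
  tp <- imp_p$train; te <- imp_p$test
  for (f in cache$num_cols) {
    n_past <- sum(!is.na(own_past[[f]]))
    if (n_past == 0L) {
      ## no valid past value of f for the test participant: rule-3
      ## donor mean, filling MISSING cells only
      donor <- train_sum[[f]] / train_n[[f]]
      if (nrow(tp) && anyNA(tp[[f]])) {
        v <- tp[[f]]; v[is.na(v)] <- donor
        data.table::set(tp, j = f, value = v)
      }
      if (anyNA(te[[f]])) {
        v <- te[[f]]; v[is.na(v)] <- donor
        data.table::set(te, j = f, value = v)
      }
    }
  }
  ## categorical rule 3 for any remaining NA (participant never observed
  ## the token): cohort training mode
  for (f in cache$cat_cols) {
    fill_needed <- any(is.na(te[[f]])) || (nrow(tp) && any(is.na(tp[[f]])))
    if (fill_needed) {
      pool <- data[train_idx][[f]]
      fill <- .mode_token(table(pool[!is.na(pool)]))
      if (nrow(tp)) { v <- tp[[f]]; v[is.na(v)] <- fill; data.table::set(tp, j = f, value = v) }
      v <- te[[f]]; v[is.na(v)] <- fill; data.table::set(te, j = f, value = v)
    }
  }
  parts[[p]] <- tp
  train <- data.table::rbindlist(parts, use.names = TRUE)
  ## categorical features some OTHER participant never observed: fill
  ## with the mode over this fold's training values
  for (f in cache$cat_cols) {
    if (anyNA(train[[f]])) {
      pool <- data[train_idx][[f]]
      fill <- .mode_token(table(pool[!is.na(pool)]))
      v <- train[[f]]; v[is.na(v)] <- fill
      data.table::set(train, j = f, value = v)
    }
  }
  data.table::setorderv(train, c("participant_id", "date"))
  list(train = train, test = te)
}

## per-fold training-side preparation; never reads test$y
.prep_fold <- function(train, test, family, scaler, k_select, smote_seed,
                       imp = NULL) {
  fcols <- feature_columns(train)
  if (is.null(imp)) imp <- impute(train, test, feature_cols = fcols)
  enc <- encode_and_scale(imp$train, imp$test, model_family = family,
                          scaler = scaler, feature_cols = fcols)
  sel <- select_features(enc$train, train$y, k = k_select)
  res <- resample_minority(enc$train[, sel, drop = FALSE], train$y,
                           seed = smote_seed)
  list(imp = imp, X = res$X, y = res$y, X_test = enc$test[, sel, drop = FALSE],
       selected = sel)
}

#' Run a full temporal nested cross-validation experiment
#'
#' For every labeled participant-day (outer fold): impute, encode,
#' select, and resample using that fold's training rows only; tune
#' hyperparameters by inner 3-fold stratified CV (re-tuned every
#' `tune_every` folds -- the winning point is carried forward, which
#' only ever reuses information from earlier data); fit and predict the
#' held-out day.  The three baselines (majority, random-weighted,
#' non-sensor decision tree) are evaluated on the identical folds.
#' Finally the model is refitted on all labeled rows to produce the
#' SHAP feature ranking.
#'
#' @param data Labeled modeling table from [prepare_experiment()].
#' @param family Model family (default `"boosted_trees"`).
#' @param hyper Hyperparameter specification, see [default_hyper_grid()].
#' @param seed Experiment seed (controls SMOTE draws, the
#'   random-weighted baseline, and inner splits).
#' @param tune_every Re-tune the grid every this many folds (default
#'   50; `1` re-tunes inside every fold).
#' @param k_select Number of features kept by mutual information
#'   (default 75).
#' @param scaler Scaling for non-tree families (default `"robust"`).
#' @param verbose Print fold progress.
#' @return List of class `persense_experiment`: `metrics` (pooled panel
#'   for the model), `baseline_metrics` (panels for the three
#'   baselines), `folds` (per-fold table: participant, date, y_true,
#'   p_hat and baseline outputs), `shap_ranking`, `params_log`, and
#'   `config`.
#' @export
run_experiment <- function(data, family = "boosted_trees",
                           hyper = default_hyper_grid(), seed = 1,
                           tune_every = 50, k_select = 75,
                           scaler = "robust", verbose = FALSE) {
  data <- data.table::as.data.table(data)
  data.table::setorderv(data, c("participant_id", "date"))
  folds <- make_folds(data)
  n <- length(folds)
  cache <- .impute_cache(data, feature_columns(data))
  set.seed(seed)

  prob <- numeric(n); y_true <- integer(n)
  maj_class <- integer(n); maj_prob <- numeric(n)
  rw_class <- integer(n); rw_prob <- numeric(n)
  tree_prob <- numeric(n)
  params <- NULL
  params_log <- list()

  for (i in seq_len(n)) {
    fold <- folds[[i]]
    train <- data[fold$train]
    test <- data[fold$test]
    y_true[i] <- test$y
    prep <- .prep_fold(train, test, family, scaler, k_select,
                       smote_seed = seed + i,
                       imp = .impute_fold(cache, data, fold$train, fold$test))

    if (is.null(params) || (i - 1L) %% tune_every == 0L) {
      tf <- tune_and_fit(prep$X, prep$y, hyper, family, seed = seed + i)
      params <- tf$params
      params_log[[length(params_log) + 1L]] <- c(list(fold = i), params)
      model <- tf$model
    } else {
      model <- fit_model(family, prep$X, prep$y, params, seed = hyper$seed)
    }
    prob[i] <- predict(model, prep$X_test)

    ## baselines on the identical fold
    bm <- predict_majority(baseline_majority(train$y), 1L)
    maj_class[i] <- bm$class; maj_prob[i] <- bm$prob
    brw <- predict_random_weighted(baseline_random_weighted(train$y), 1L)
    rw_class[i] <- brw$class; rw_prob[i] <- brw$prob
    tr_ns <- prep$imp$train; te_ns <- prep$imp$test
    bt <- baseline_tree_nonsensor(tr_ns)
    tree_prob[i] <- predict_tree_nonsensor(bt, te_ns)$prob
    if (verbose && i %% 100 == 0) message("fold ", i, "/", n)
  }

  metrics <- pooled_metrics(y_true, prob)
  baseline_metrics <- list(
    majority = pooled_metrics(y_true, maj_prob, class = maj_class),
    random_weighted = pooled_metrics(y_true, rw_prob, class = rw_class),
    tree_nonsensor = pooled_metrics(y_true, tree_prob)
  )

  ## SHAP ranking from a refit on all labeled rows (attribution only;
  ## predictions above never use it)
  shap_ranking <- NULL
  if (family %in% c("boosted_trees", "xgb_depthwise")) {
    full <- impute(data, feature_cols = feature_columns(data))$train
    encf <- encode_and_scale(full, model_family = family,
                             feature_cols = feature_columns(data))
    self <- select_features(encf$train, data$y, k = k_select)
    resf <- resample_minority(encf$train[, self, drop = FALSE], data$y, seed = seed)
    mf <- fit_model(family, resf$X, resf$y, params %||% list(), seed = hyper$seed)
    shap_ranking <- shap_summary(mf, encf$train[, self, drop = FALSE])$ranking
  }

  structure(list(
    metrics = metrics,
    baseline_metrics = baseline_metrics,
    folds = data.table::data.table(
      participant_id = data$participant_id, date = data$date,
      y_true = y_true, p_hat = prob, majority_class = maj_class,
      random_weighted_class = rw_class, tree_p_hat = tree_prob),
    shap_ranking = shap_ranking,
    params_log = params_log,
    config = list(family = family, seed = seed, tune_every = tune_every,
                  k_select = k_select, scaler = scaler,
                  n_folds = n, hyper = hyper)
  ), class = "persense_experiment")
}

#' Training-side artifacts of one fold (leakage audit)
#'
#' Recomputes every training-side artifact of one outer fold -- the
#' imputed training table, the encoded/selected/resampled matrices, and
#' the serialized fitted model -- with the test-fold label optionally
#' overwritten.  Because no preparation or fitting step may read the
#' test label, the artifacts must be bit-identical whatever value the
#' test label takes.
#'
#' @param data Labeled modeling table.
#' @param fold_index Outer fold to audit.
#' @param flip_test_label Overwrite the test row's `y` with its
#'   complement before running the fold.
#' @param family,hyper,seed,k_select,scaler As in [run_experiment()].
#' @return List of artifacts suitable for `identical()` comparison.
#' @export
fold_artifacts <- function(data, fold_index, flip_test_label = FALSE,
                           family = "boosted_trees",
                           hyper = default_hyper_grid(), seed = 1,
                           k_select = 75, scaler = "robust") {
  data <- data.table::copy(data.table::as.data.table(data))
  data.table::setorderv(data, c("participant_id", "date"))
  folds <- make_folds(data)
  fold <- folds[[fold_index]]
  if (flip_test_label) data[fold$test, y := 1L - y]
  train <- data[fold$train]
  test <- data[fold$test]
  prep <- .prep_fold(train, test, family, scaler, k_select,
                     smote_seed = seed + fold_index)
  tf <- tune_and_fit(prep$X, prep$y, hyper, family, seed = seed + fold_index)
  raw <- if (family %in% c("boosted_trees", "xgb_depthwise")) {
    xgboost::xgb.save.raw(tf$model$fit)
  } else serialize(tf$model$fit, NULL)
  list(imputed_train = prep$imp$train, X = prep$X, y = prep$y,
       selected = prep$selected, params = tf$params, model_raw = raw)
}
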