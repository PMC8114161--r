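## Temporal leave-one-day-out nested cross-validation, the model
## roster, label-only and non-sensor baselines, and SHAP attribution.

#' Temporal leave-one-day-out outer folds
#'
#' One fold per labeled participant-day.  The training set for the fold
#' testing participant p's day d is: every row of the OTHER
#' participants, plus p's rows with date strictly earlier than d (so no
#' data collected after the test day, from that participant, is ever
#' trained on).  A fold whose test participant has no personal history
#' is still valid -- it trains on the other participants only.
#'
#' @param rows Labeled table with `participant_id`, `date`.
#' @return List of folds, each `list(test = i, train = integer vector)`
#'   of row indices into `rows` (sorted by participant then date).
#' @export
make_folds <- function(rows) {
  rows <- data.table::as.data.table(rows)
  stopifnot(!is.unsorted(order(rows$participant_id, rows$date)))
  n <- nrow(rows)
  pid <- as.character(rows$participant_id)
  lapply(seq_len(n), function(i) {
    train <- which(pid != pid[i] | rows$date < rows$date[i])
    list(test = i, train = train)
  })
}

#' Default leaf-wise gradient-boosting hyperparameter grid
#'
#' Fixed: random seed 0, 200 boosted trees, at most 128 leaves per
#' tree.  Searched: learning rate in \{0.008, 0.01, 0.012\} and the
#' column subsample ratio per tree in \{0.68, 0.70, 0.72\}.
#'
#' @return List with `seed`, `n_trees`, `max_leaves`, and a `grid`
#'   table of the searched combinations (learning rate varying
#'   fastest).
#' @export
default_hyper_grid <- function() {
  list(seed = 0, n_trees = 200, max_leaves = 128,
       grid = data.table::as.data.table(expand.grid(
         learning_rate = c(0.008, 0.01, 0.012),
         colsample = c(0.68, 0.70, 0.72))))
}

#' Fit one classifier family
#'
#' One interface over the classifier roster.  `boosted_trees` (the
#' primary model) is leaf-wise histogram gradient boosting (xgboost with
#' `grow_policy = "lossguide"` and a `max_leaves` cap); `xgb_depthwise`
#' is conventional depth-wise boosting; the remaining families
#' (`logistic`, `knn`, `svm`, `random_forest`, `decision_tree`) are
#' available behind the same interface with small default settings.
#'
#' @param family Family name.
#' @param X Numeric training matrix.
#' @param y Binary labels (0/1).
#' @param params Hyperparameters: for boosting families
#'   `learning_rate`, `colsample`, `n_trees`, `max_leaves`; `k` for knn;
#'   `maxdepth` for decision_tree.
#' @param seed RNG seed for stochastic learners.
#' @return Fitted model object of class `persense_model`.
#' @export
fit_model <- function(family, X, y, params = list(), seed = 0) {
  y <- as.integer(y)
  fit <- switch(family,
    boosted_trees = ,
    xgb_depthwise = {
      p <- list(objective = "binary:logistic",
                eta = params$learning_rate %||% 0.01,
                colsample_bytree = params$colsample %||% 0.7,
                tree_method = "hist", nthread = 1, seed = seed,
                max_bin = params$max_bin %||% 32, verbosity = 0)
      if (family == "boosted_trees") {
        p$grow_policy <- "lossguide"
        p$max_leaves <- params$max_leaves %||% 128
        p$max_depth <- params$max_depth %||% 0   # leaf-wise, unbounded depth
        ## LightGBM-convention leaf-size floor (min_data_in_leaf = 20;
        ## logistic hessian <= 1/4 per row)
        p$min_child_weight <- params$min_child_weight %||% 5
      } else {
        p$max_depth <- params$max_depth %||% 6
      }
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(params = p, data = dtrain,
                         nrounds = params$n_trees %||% 200, verbose = 0)
    },
    logistic = {
      df <- data.frame(X)
      suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y),
                                  family = stats::binomial()))
    },
    knn = list(X = X, y = y, k = params$k %||% 5),
    svm = {
      set.seed(seed)
      e1071::svm(x = X, y = factor(y, levels = c(0, 1)), probability = TRUE)
    },
    random_forest = {
      if (!requireNamespace("ranger", quietly = TRUE)) stop("ranger not installed")
      ranger::ranger(x = data.frame(X), y = factor(y, levels = c(0, 1)),
                     probability = TRUE, seed = seed,
                     num.trees = params$n_trees %||% 200, num.threads = 1)
    },
    decision_tree = {
      df <- cbind(data.frame(X), .y = factor(y, levels = c(0, 1)))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = params$maxdepth %||% 5, cp = 0.01))
    },
    stop("unknown model family: ", family)
  )
  structure(list(family = family, fit = fit, params = params,
                 feature_names = colnames(X)),
            class = "persense_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class-1 probabilities
#'
#' @param object A `persense_model`.
#' @param X Numeric matrix with the training column layout.
#' @param ... Unused.
#' @return Numeric vector of probabilities of class 1.
#' @export
predict.persense_model <- function(object, X, ...) {
  X <- X[, object$feature_names, drop = FALSE]
  switch(object$family,
    boosted_trees = ,
    xgb_depthwise = as.numeric(predict(object$fit, xgboost::xgb.DMatrix(X))),
    logistic = as.numeric(predict(object$fit, newdata = data.frame(X),
                                  type = "response")),
    knn = {
      if (!requireNamespace("class", quietly = TRUE)) stop("class not installed")
      pr <- class::knn(object$fit$X, X, factor(object$fit$y, levels = c(0, 1)),
                       k = object$fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    svm = {
      pr <- attr(predict(object$fit, X, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    random_forest = as.numeric(predict(object$fit, data.frame(X))$predictions[, "1"]),
    decision_tree = as.numeric(predict(object$fit, newdata = data.frame(X),
                                       type = "prob")[, "1"])
  )
}

## stratified k-fold assignment (returns fold id per row)
stratified_folds <- function(y, k, seed = 0) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  fold <- integer(length(y))
  for (c in unique(y)) {
    idx <- which(y == c)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Inner-loop hyperparameter tuning and refit
#'
#' Three-fold stratified cross-validation on the (already resampled)
#' training rows scores every grid point by pooled inner macro F1 (the
#' criterion is configurable); the first best point wins ties, and the
#' winner is refitted on the full training set.  A grid point that
#' fails on a degenerate inner fold scores as chance rather than
#' crashing.
#'
#' @param X,y Training matrix and labels.
#' @param hyper A [default_hyper_grid()]-shaped list.
#' @param family Model family (see [fit_model()]).
#' @param seed RNG seed for the inner splits.
#' @param criterion `"macro_f1"` (default), `"accuracy"`, or `"auc"`.
#' @return List: `model` (refit on all rows), `params` (winning
#'   hyperparameters), `scores` (per grid point).
#' @export
tune_and_fit <- function(X, y, hyper = default_hyper_grid(),
                         family = "boosted_trees", seed = 0,
                         criterion = c("macro_f1", "accuracy", "auc")) {
  criterion <- match.arg(criterion)
  grid <- hyper$grid
  n_pts <- nrow(grid)
  scores <- numeric(n_pts)
  if (n_pts > 1L) {
    fold <- stratified_folds(y, 3L, seed = seed)
    for (g in seq_len(n_pts)) {
      pars <- c(as.list(grid[g]), list(n_trees = hyper$n_trees,
                                       max_leaves = hyper$max_leaves))
      prob <- rep(NA_real_, length(y))
      ok <- TRUE
      for (f in 1:3) {
        tr <- fold != f
        res <- tryCatch({
          m <- fit_model(family, X[tr, , drop = FALSE], y[tr], pars, seed = hyper$seed)
          predict(m, X[!tr, , drop = FALSE])
        }, error = function(e) NULL)
        if (is.null(res)) { ok <- FALSE; break }
        prob[!tr] <- res
      }
      scores[g] <- if (!ok || anyNA(prob)) 50 else {
        mm <- pooled_metrics(y, prob)
        mm[[criterion]]
      }
    }
    best <- which.max(scores)  # first max wins
  } else {
    best <- 1L
  }
  params <- c(as.list(grid[best]), list(n_trees = hyper$n_trees,
                                        max_leaves = hyper$max_leaves))
  list(model = fit_model(family, X, y, params, seed = hyper$seed),
       params = params, scores = scores)
}

## ---- baselines ---------------------------------------------------------

#' Label-only and non-sensor baselines
#'
#' `baseline_majority` always predicts the training-majority class
#' (exact 50/50 ties go to class 0) with a constant probability equal
#' to the training prevalence of class 1.  `baseline_random_weighted`
#' predicts class c with probability equal to c's training prevalence,
#' independent of features; its probability output is the constant
#' class-1 prevalence (so its AUC is chance).
#' `baseline_tree_nonsensor` is a decision tree restricted to the three
#' non-sensor features: days since surgery, most recent score, running
#' mean score.
#'
#' @param y_train Training labels.
#' @return A predictor object; see each `predict_*` counterpart.
#' @export
baseline_majority <- function(y_train) {
  y_train <- as.integer(y_train)
  p1 <- mean(y_train == 1L)
  structure(list(class = if (p1 > 0.5) 1L else 0L, p1 = p1),
            class = "persense_majority")
}

#' @rdname baseline_majority
#' @param object Fitted baseline.
#' @param n Number of test rows to predict.
#' @export
predict_majority <- function(object, n) {
  ## a featureless classifier carries no ranking information: its score
  ## is a constant 0.5, so pooled AUC is chance by construction (a
  ## per-fold training prevalence would leak fold composition into the
  ## pooled ranking)
  list(class = rep(object$class, n), prob = rep(0.5, n))
}

#' @rdname baseline_majority
#' @export
baseline_random_weighted <- function(y_train) {
  structure(list(p1 = mean(as.integer(y_train) == 1L)),
            class = "persense_random_weighted")
}

#' @rdname baseline_majority
#'
#' Class draws use the current RNG stream (seed at the experiment
#' level for determinism).
#' @export
predict_random_weighted <- function(object, n) {
  list(class = as.integer(runif(n) < object$p1), prob = rep(0.5, n))
}

#' @rdname baseline_majority
#' @param train Labeled training table containing the three non-sensor
#'   feature columns and `y`.
#' @export
baseline_tree_nonsensor <- function(train) {
  feats <- c("days_since_surgery", "most_recent_score", "running_mean_score")
  stopifnot(all(feats %in% names(train)))
  df <- data.frame(train)[, feats, drop = FALSE]
  df$.y <- factor(train$y, levels = c(0, 1))
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(maxdepth = 5, cp = 0.01))
  structure(list(fit = fit, features = feats), class = "persense_tree_baseline")
}

#' @rdname baseline_majority
#' @param newdata Test table containing the three non-sensor features.
#' @export
predict_tree_nonsensor <- function(object, newdata) {
  pr <- predict(object$fit, newdata = data.frame(newdata)[, object$features, drop = FALSE],
                type = "prob")
  list(class = as.integer(pr[, "1"] > 0.5), prob = as.numeric(pr[, "1"]))
}

## ---- SHAP --------------------------------------------------------------

#' SHAP-style additive feature attribution for boosted trees
#'
#' Exact per-feature TreeSHAP attributions of the model's margin
#' output.  Additivity holds: row attributions plus the base value
#' reproduce the margin prediction to single-precision accumulation
#' error (checked to 1e-4 over hundreds of trees unless disabled).
#'
#' @param model A `persense_model` of a boosting family.
#' @param X Matrix of rows to attribute.
#' @param check_additivity Verify the additivity identity.
#' @param tol Additivity tolerance (default 1e-4).
#' @return List: `values` (n x p attribution matrix), `base_value`,
#'   and `ranking` (a table of features ordered by mean absolute
#'   attribution).
#' @export
shap_summary <- function(model, X, check_additivity = TRUE, tol = 1e-4) {
  if (!model$family %in% c("boosted_trees", "xgb_depthwise")) {
    stop("SHAP attribution is implemented for the boosting families only")
  }
  X <- X[, model$feature_names, drop = FALSE]
  dm <- xgboost::xgb.DMatrix(X)
  contrib <- predict(model$fit, dm, predcontrib = TRUE)
  base <- contrib[, ncol(contrib)]
  vals <- contrib[, -ncol(contrib), drop = FALSE]
  if (check_additivity) {
    margin <- predict(model$fit, dm, outputmargin = TRUE)
    stopifnot(max(abs(rowSums(vals) + base - margin)) < tol)
  }
  ranking <- data.table::data.table(
    feature = colnames(vals),
    mean_abs_shap = colMeans(abs(vals))
  )
  data.table::setorderv(ranking, "mean_abs_shap", order = -1L)
  list(values = vals, base_value = base[1], ranking = ranking[])
}
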