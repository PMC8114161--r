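## Cleaning, imputation, encoding/scaling, feature selection, and
## minority resampling, applied in the pipeline's fixed order:
## hospital-day exclusion -> coverage/participant/feature/day cleaning ->
## label merge -> (per CV fold) imputation -> encoding/scaling ->
## mutual-information selection -> SVM-SMOTE on training rows only.

## columns that are never features
.id_cols <- c("participant_id", "date", "coverage_hours", "y", "label",
              "score", "person_mean")

#' Feature column names of a prepared table
#' @param dt A features/labeled `data.table`.
#' @return Character vector of feature columns (everything that is not
#'   an identifier, coverage, score, or label column).
#' @export
feature_columns <- function(dt) setdiff(names(dt), .id_cols)

#' Drop surgery-date and hospitalized days
#'
#' Removes rows dated on the surgery date, during the inpatient stay
#' (the closed interval from surgery to discharge), or within any
#' readmission interval (also closed), for diary and feature tables
#' alike.
#'
#' @param rows `data.table` with `participant_id` and `date`.
#' @param meta Metadata with `surgery_date`, `discharge_date`, and the
#'   serialized `readmissions` column.
#' @return The retained rows.
#' @export
drop_hospital_days <- function(rows, meta) {
  rows <- data.table::as.data.table(rows)
  readm <- readmissions_list(meta)
  keep <- rep(TRUE, nrow(rows))
  for (i in seq_len(nrow(meta))) {
    pid <- meta$participant_id[i]
    sel <- rows$participant_id == pid
    bad <- rows$date >= meta$surgery_date[i] & rows$date <= meta$discharge_date[i]
    iv <- readm[[i]]
    for (j in seq_len(nrow(iv))) {
      bad <- bad | (rows$date >= iv$start[j] & rows$date <= iv$end[j])
    }
    keep[sel] <- !bad[sel]
  }
  rows[keep]
}

#' Order-faithful cleaning of the day-feature matrix
#'
#' Applies, in this exact order, with strict inequalities throughout:
#' (1) drop days with less than `min_coverage` hours of sensor data;
#' (2) drop participants with fewer than `min_days` remaining days;
#' (3) drop features missing on more than `max_missing` of days or with
#' zero variance; (4) drop days missing more than `max_missing` of the
#' remaining features; (5) if `labels` are supplied, merge them as
#' next-day targets ([align_targets()]) and drop participants with
#' fewer than `min_days` labeled rows.
#'
#' @param features Day-feature table (`participant_id`, `date`,
#'   `coverage_hours`, feature columns).
#' @param labels Optional label table for [align_targets()].
#' @param min_coverage Hours threshold (default 20; a 20.0-hour day is
#'   kept).
#' @param min_days Day-count threshold (default 5; a 5-day participant
#'   is kept).
#' @param max_missing Missingness fraction threshold (default 0.3; a
#'   feature missing exactly 30% of days is kept).
#' @return List: `data` (cleaned, labeled if labels given) and `report`
#'   (a `CleaningReport`-style list of per-step drop counts and final
#'   sizes).
#' @export
clean <- function(features, labels = NULL, min_coverage = 20, min_days = 5,
                  max_missing = 0.3) {
  dt <- data.table::copy(data.table::as.data.table(features))
  fail <- function(step) stop("no rows/columns left after cleaning step: ", step)

  n0 <- nrow(dt)
  dt <- dt[coverage_hours >= min_coverage]
  days_dropped_low_coverage <- n0 - nrow(dt)
  if (nrow(dt) == 0L) fail("low-coverage day exclusion")

  cnt <- dt[, .N, by = participant_id]
  keep_p <- cnt[N >= min_days]$participant_id
  participants_dropped_few_days <- nrow(cnt) - length(keep_p)
  dt <- dt[participant_id %in% keep_p]
  if (nrow(dt) == 0L) fail("few-day participant exclusion")

  fcols <- feature_columns(dt)
  drop_f <- character(0)
  for (f in fcols) {
    v <- dt[[f]]
    miss <- mean(is.na(v))
    zerovar <- if (is.numeric(v)) {
      length(unique(v[!is.na(v)])) <= 1L
    } else {
      length(unique(v[!is.na(v)])) <= 1L
    }
    if (miss > max_missing || zerovar) drop_f <- c(drop_f, f)
  }
  features_dropped_missing_or_constant <- length(drop_f)
  if (length(drop_f)) dt[, (drop_f) := NULL]
  fcols <- feature_columns(dt)
  if (length(fcols) == 0L) fail("feature missingness/variance exclusion")

  miss_frac <- rowMeans(is.na(dt[, fcols, with = FALSE]))
  days_dropped_missing_features <- sum(miss_frac > max_missing)
  dt <- dt[miss_frac <= max_missing]
  if (nrow(dt) == 0L) fail("high-missingness day exclusion")

  participants_dropped_few_labeled <- 0L
  if (!is.null(labels)) {
    dt <- align_targets(dt, labels)
    if (nrow(dt) == 0L) fail("label merge")
    cnt <- dt[, .N, by = participant_id]
    keep_p <- cnt[N >= min_days]$participant_id
    participants_dropped_few_labeled <- nrow(cnt) - length(keep_p)
    dt <- dt[participant_id %in% keep_p]
    if (nrow(dt) == 0L) fail("few-labeled-day participant exclusion")
  }

  report <- list(
    days_dropped_low_coverage = days_dropped_low_coverage,
    participants_dropped_few_days = participants_dropped_few_days,
    features_dropped_missing_or_constant = features_dropped_missing_or_constant,
    days_dropped_missing_features = days_dropped_missing_features,
    participants_dropped_few_labeled = participants_dropped_few_labeled,
    final_n_days = nrow(dt),
    final_n_features = length(feature_columns(dt)),
    final_n_participants = length(unique(dt$participant_id))
  )
  list(data = dt[], report = report)
}

#' Split-aware imputation
#'
#' Continuous features: (1) a missing training value is replaced by the
#' average of that participant's two valid observations nearest in
#' calendar distance (ties broken toward the earlier day; a single valid
#' day is used alone); (2) a missing test value is replaced by the
#' participant's last valid training value; (3) a participant with no
#' valid training value of a feature receives the mean over the other
#' participants' training data.  Categorical features: the mode of the
#' participant's training data, falling back to the mode of the
#' remaining participants' training data; mode ties break to the
#' lexicographically smallest token.  No test value is ever read when
#' computing any fill-in, and observed values are never altered.
#'
#' @param train Training rows (`participant_id`, `date`, features).
#' @param test Optional test rows (same layout).
#' @param feature_cols Columns to impute (default [feature_columns()]).
#' @param .allow_all_missing Internal: leave a feature untouched (NA)
#'   instead of erroring when it has no valid training value anywhere
#'   (used by the fold-loop cache, which fills such cells itself).
#' @return List with completed `train` and `test` tables.
#' @export
impute <- function(train, test = NULL, feature_cols = NULL,
                   .allow_all_missing = FALSE) {
  train <- data.table::copy(data.table::as.data.table(train))
  has_test <- !is.null(test) && nrow(test) > 0L
  if (has_test) test <- data.table::copy(data.table::as.data.table(test))
  if (is.null(feature_cols)) feature_cols <- feature_columns(train)

  tr_pid <- as.character(train$participant_id)
  tr_date <- as.numeric(train$date)
  idx_by_p <- split(seq_len(nrow(train)), tr_pid)
  if (has_test) {
    te_pid <- as.character(test$participant_id)
    te_idx_by_p <- split(seq_len(nrow(test)), te_pid)
  }

  for (f in feature_cols) {
    v <- train[[f]]
    categorical <- is.character(v) || is.factor(v)
    if (categorical) v <- as.character(v)
    tv <- if (has_test) {
      if (categorical) as.character(test[[f]]) else test[[f]]
    } else NULL
    if (all(is.na(v))) {
      if (.allow_all_missing) next
      stop("feature '", f, "' has no valid training value ",
           "for any participant (should have been cleaned)")
    }

    if (!categorical) {
      sum_by_p <- vapply(idx_by_p, function(ii) sum(v[ii], na.rm = TRUE), numeric(1))
      n_by_p <- vapply(idx_by_p, function(ii) sum(!is.na(v[ii])), numeric(1))
      tot_sum <- sum(sum_by_p); tot_n <- sum(n_by_p)
    } else {
      pool_tab <- table(v[!is.na(v)])
    }

    for (p in names(idx_by_p)) {
      ii <- idx_by_p[[p]]
      valid <- ii[!is.na(v[ii])]
      missing <- ii[is.na(v[ii])]
      ti <- if (has_test) te_idx_by_p[[p]] else integer(0)
      tmiss <- ti[is.na(tv[ti])]

      if (length(valid) == 0L) {
        ## rule 3: borrow from the rest of the cohort's training data
        fill <- if (!categorical) {
          if (tot_n - 0 <= 0) stop("no donor values for feature ", f)
          tot_sum / tot_n
        } else {
          .mode_token(pool_tab)
        }
        if (length(missing)) v[missing] <- fill
        if (length(tmiss)) tv[tmiss] <- fill
        next
      }

      if (!categorical) {
        vd <- tr_date[valid]; vv <- v[valid]
        o <- order(vd); vd <- vd[o]; vv <- vv[o]
        for (mi in missing) {
          d <- tr_date[mi]
          ## two valid days nearest in calendar distance, earlier first on ties
          ord <- order(abs(vd - d), vd)
          v[mi] <- mean(vv[ord[seq_len(min(2L, length(ord)))]])
        }
        if (length(tmiss)) tv[tmiss] <- vv[length(vv)]  # last valid training day
      } else {
        own_tab <- table(v[valid])
        fill <- .mode_token(own_tab)
        if (length(missing)) v[missing] <- fill
        if (length(tmiss)) tv[tmiss] <- fill
      }
    }
    ## test participants with no training rows at all: cohort-level fill
    if (has_test) {
      orphan <- which(is.na(tv))
      if (length(orphan)) {
        tv[orphan] <- if (!categorical) tot_sum / tot_n else .mode_token(pool_tab)
      }
    }
    data.table::set(train, j = f, value = v)
    if (has_test) data.table::set(test, j = f, value = tv)
  }
  list(train = train, test = if (has_test) test else NULL)
}

## mode with lexicographic tie-break
.mode_token <- function(tab) {
  if (length(tab) == 0L) stop("empty table in mode computation")
  mx <- max(tab)
  sort(names(tab)[tab == mx])[1]
}

#' One-hot encode and scale a feature table
#'
#' Categorical columns are expanded to indicator columns with the
#' category vocabulary fixed from the training rows only (an unseen test
#' category maps to all zeros).  Numeric columns are scaled with
#' parameters fitted on training rows only; tree-family models
#' (`boosted_trees`, `xgb_depthwise`, `random_forest`, `decision_tree`)
#' receive unscaled numerics because trees are scale-invariant.
#'
#' @param train,test Imputed feature tables (test may be NULL).
#' @param model_family Model family name (see [fit_model()]).
#' @param scaler `"robust"` ((x - median)/IQR, the default), `"minmax"`,
#'   or `"zscore"`.
#' @param feature_cols Columns to encode (default [feature_columns()]).
#' @return List: numeric matrices `train` and `test` (NULL if no test)
#'   with identical column order.
#' @export
encode_and_scale <- function(train, test = NULL, model_family = "boosted_trees",
                             scaler = c("robust", "minmax", "zscore"),
                             feature_cols = NULL) {
  scaler <- match.arg(scaler)
  train <- data.table::as.data.table(train)
  has_test <- !is.null(test) && nrow(test) > 0L
  if (has_test) test <- data.table::as.data.table(test)
  if (is.null(feature_cols)) feature_cols <- feature_columns(train)
  tree_family <- model_family %in% c("boosted_trees", "xgb_depthwise",
                                     "random_forest", "decision_tree")
  tr_cols <- list(); te_cols <- list()
  for (f in feature_cols) {
    v <- train[[f]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      vocab <- sort(unique(v[!is.na(v)]))
      for (lev in vocab) {
        cn <- paste0(f, "=", lev)
        tr_cols[[cn]] <- as.numeric(v == lev)
        if (has_test) te_cols[[cn]] <- as.numeric(as.character(test[[f]]) == lev)
      }
    } else {
      x <- as.numeric(v)
      tx <- if (has_test) as.numeric(test[[f]]) else NULL
      if (!tree_family) {
        pars <- switch(scaler,
          robust = {
            iqr <- stats::IQR(x, na.rm = TRUE)
            c(center = median(x, na.rm = TRUE), scale = if (iqr > 0) iqr else 1)
          },
          minmax = {
            rg <- range(x, na.rm = TRUE)
            c(center = rg[1], scale = if (diff(rg) > 0) diff(rg) else 1)
          },
          zscore = {
            s <- sd(x, na.rm = TRUE)
            c(center = mean(x, na.rm = TRUE), scale = if (!is.na(s) && s > 0) s else 1)
          })
        x <- (x - pars["center"]) / pars["scale"]
        if (has_test) tx <- (tx - pars["center"]) / pars["scale"]
      }
      tr_cols[[f]] <- x
      if (has_test) te_cols[[f]] <- tx
    }
  }
  Xtr <- do.call(cbind, tr_cols)
  rownames(Xtr) <- NULL
  out <- list(train = Xtr, test = NULL)
  if (has_test) {
    Xte <- do.call(cbind, te_cols)
    rownames(Xte) <- NULL
    out$test <- Xte
  }
  out
}

#' Mutual-information feature selection
#'
#' Estimates the mutual information between each (post-encoding) feature
#' and the binary label on training rows, using equal-frequency
#' discretization of continuous features, and returns the top-`k`
#' features.  Ties break by stable original column order.  With
#' `k >= ncol(X)` the selection is the identity.
#'
#' @param X Numeric training matrix with column names.
#' @param y Binary labels (0/1).
#' @param k Number of features to keep (default 75).
#' @param n_bins Discretization bins (default 10).
#' @return Character vector of selected column names, in original
#'   column order.
#' @export
select_features <- function(X, y, k = 75, n_bins = 10) {
  p <- ncol(X)
  if (k >= p) return(colnames(X))
  scores <- vapply(seq_len(p), function(j) mutual_information(X[, j], y, n_bins), numeric(1))
  keep <- order(-scores, seq_len(p))[seq_len(k)]
  colnames(X)[sort(keep)]
}

#' @rdname select_features
#' @param x A single feature vector.
#' @return `mutual_information` returns the plug-in MI estimate in nats.
#' @export
mutual_information <- function(x, y, n_bins = 10) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0L) return(0)
  ux <- unique(x)
  if (length(ux) > n_bins) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2L) return(0)
    xb <- cut(x, breaks = br, include.lowest = TRUE)
  } else {
    if (length(ux) <= 1L) return(0)
    xb <- factor(x)
  }
  tab <- table(xb, y)
  pj <- tab / sum(tab)
  px <- rowSums(pj); py <- colSums(pj)
  sel <- pj > 0
  sum(pj[sel] * log(pj[sel] / outer(px, py)[sel]))
}

#' SVM-SMOTE minority oversampling
#'
#' Oversamples the minority class to parity with the majority.  An SVM
#' is fitted to the (standardized) training data and the minority-class
#' support vectors -- the minority points near the decision boundary --
#' serve as seeds; each synthetic point is a convex combination of a
#' seed and one of its `k_neighbors` nearest minority neighbors, so all
#' synthetic rows lie within the convex hull of the minority class.
#' When the minority class has fewer than `k_neighbors + 1` rows the
#' method falls back to random duplication with a warning.  Applied to
#' TRAINING rows only, after imputation and encoding.  The caller's RNG
#' state is preserved.
#'
#' The boundary SVM is fitted on a stratified subsample of at most
#' `svm_max_rows` rows (the quadratic-programming cost grows
#' quadratically in n while the boundary estimate stabilizes early);
#' seeds are then the minority support vectors of that fit.
#'
#' @param X Numeric training matrix.
#' @param y Binary labels (0/1).
#' @param seed RNG seed; output is deterministic given it.
#' @param k_neighbors Minority neighborhood size (default 5).
#' @param svm_max_rows Row cap for the boundary SVM fit (default 500).
#' @return List: augmented `X` and `y` with equal class counts.
#' @export
resample_minority <- function(X, y, seed = 0, k_neighbors = 5,
                              svm_max_rows = 500) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == n0) return(list(X = X, y = y))
  minority <- if (n1 < n0) 1L else 0L
  n_syn <- abs(n0 - n1)
  min_idx <- which(y == minority)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  if (length(min_idx) < k_neighbors + 1L) {
    warning("minority class smaller than k_neighbors + 1; falling back to random duplication")
    dup <- min_idx[sample.int(length(min_idx), n_syn, replace = TRUE)]
    return(list(X = rbind(X, X[dup, , drop = FALSE]),
                y = c(y, rep(minority, n_syn))))
  }

  ## standardize for boundary detection and neighbor geometry only;
  ## interpolation happens in the original space
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0 | is.na(scl)] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  sub <- seq_along(y)
  if (length(y) > svm_max_rows) {
    ## stratified subsample; always keep every minority row so SV seeds
    ## can come from the full minority class
    maj_idx <- which(y != minority)
    n_maj_keep <- max(svm_max_rows - length(min_idx), length(min_idx))
    sub <- sort(c(min_idx, maj_idx[sample.int(length(maj_idx),
                                              min(length(maj_idx), n_maj_keep))]))
  }
  fit <- tryCatch(
    e1071::svm(x = Xs[sub, , drop = FALSE],
               y = factor(y[sub], levels = c(0, 1)), kernel = "radial",
               scale = FALSE),
    error = function(e) NULL)
  seeds <- if (!is.null(fit)) intersect(sub[fit$index], min_idx) else integer(0)
  if (length(seeds) == 0L) seeds <- min_idx

  Ms <- Xs[min_idx, , drop = FALSE]
  ## k nearest minority neighbors of each seed (excluding itself)
  DD <- as.matrix(stats::dist(Ms))
  synth <- matrix(NA_real_, n_syn, ncol(X))
  for (i in seq_len(n_syn)) {
    s <- seeds[((i - 1L) %% length(seeds)) + 1L]
    d <- DD[match(s, min_idx), ]
    d[match(s, min_idx)] <- Inf
    nb_local <- order(d)[seq_len(min(k_neighbors, length(d) - 1L))]
    nb <- min_idx[sample(nb_local, 1L)]
    u <- runif(1)
    synth[i, ] <- X[s, ] + u * (X[nb, ] - X[s, ])
  }
  colnames(synth) <- colnames(X)
  list(X = rbind(X, synth), y = c(y, rep(minority, n_syn)))
}
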