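#' Training protocol
#'
#' The split/tuning/validation protocol used for every classifier: a
#' class-stratified 80:20 train:test split; hyperparameter search on the
#' training split only, scored by mean validation AUC (binary) or log loss
#' (multiclass) under class-stratified 5-fold cross-validation with early
#' stopping after 150 stagnant boosting rounds and at most 2000 rounds;
#' positive-class weighting by the class imbalance ratio; final accuracy
#' and confusion matrix from class-stratified 10-fold cross-validation on
#' the training split; ROC and AUC from the untouched held-out 20%.
#'
#' @param test_fraction Held-out fraction (default 0.2).
#' @param tune_folds CV folds during tuning (default 5).
#' @param tune_trials Random-search evaluation budget (default 50; 0 skips
#'   the search and keeps the documented default hyperparameters, with the
#'   boosting-round count still selected from the tuning CV learning
#'   curve).
#' @param early_stopping_rounds Early-stopping patience (default 150).
#' @param max_boosting_rounds Boosting-round cap (default 2000).
#' @param final_cv_folds Folds of the final CV (default 10).
#' @param seed Integer seed controlling splits, folds, search and booster.
#' @return A list of class `train_protocol`.
#' @export
train_protocol <- function(test_fraction = 0.2, tune_folds = 5L,
                           tune_trials = 50L, early_stopping_rounds = 150L,
                           max_boosting_rounds = 2000L, final_cv_folds = 10L,
                           seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, tune_folds >= 2,
            final_cv_folds >= 2)
  structure(list(test_fraction = test_fraction,
                 tune_folds = as.integer(tune_folds),
                 tune_trials = as.integer(tune_trials),
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 max_boosting_rounds = as.integer(max_boosting_rounds),
                 final_cv_folds = as.integer(final_cv_folds),
                 seed = as.integer(seed)),
            class = "train_protocol")
}

# default booster hyperparameters and the random-search space
.default_booster_params <- function() {
  list(eta = 0.1, max_depth = 6L, min_child_weight = 1,
       subsample = 0.8, colsample_bytree = 0.8, lambda = 1)
}

.sample_booster_params <- function() {
  list(eta = exp(runif(1, log(0.01), log(0.3))),
       max_depth = sample(3:8, 1),
       min_child_weight = exp(runif(1, log(0.5), log(10))),
       subsample = runif(1, 0.5, 1),
       colsample_bytree = runif(1, 0.3, 1),
       lambda = exp(runif(1, log(1e-3), log(10))))
}

# round-robin class-stratified fold assignment (uses the current RNG state)
make_stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(j) which(fold == j))
}

# class-probability predictions as an n x k matrix regardless of whether
# the booster returned a vector or matrix
prob_matrix <- function(p, k) {
  if (is.matrix(p)) p else matrix(p, ncol = k, byrow = TRUE)
}

# empirical ROC curve of scores for a 0/1 outcome
roc_points <- function(score, y) {
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  tibble(fpr = c(0, fp / max(1, sum(1 - y))),
         tpr = c(0, tp / max(1, sum(y))))
}

auc_from_scores <- function(score, y) {
  # Mann-Whitney form, midrank ties
  r <- rank(score)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train a gradient-boosted spectral classifier
#'
#' Fits a gradient-boosted decision-tree ensemble (xgboost) on a
#' [spectra_features][augment_derivatives] object under a
#' [train_protocol()]: stratified 80:20 split; hyperparameter and
#' boosting-round selection on the training split only; final
#' class-stratified 10-fold CV accuracy and row-normalized confusion
#' matrix on the training split; ROC/AUC on the held-out test set.
#' Identical seeds give identical reports.
#'
#' @param features A `spectra_features` object.
#' @param protocol A [train_protocol()].
#' @return An object of class `spectra_classifier` with elements including
#'   `cv_accuracy`, `fold_accuracy`, `confusion` (row-normalized),
#'   `roc`, `auc`, `importance`, `model`, and the train/test split ids.
#' @export
train_classifier <- function(features, protocol = train_protocol()) {
  fit_booster(features, protocol, multiclass = FALSE)
}

#' @rdname train_classifier
#' @export
train_multiclass <- function(features, protocol = train_protocol()) {
  if (length(unique(features$meta$class_label)) < 3) {
    abort("train_multiclass requires at least 3 classes")
  }
  fit_booster(features, protocol, multiclass = TRUE)
}

fit_booster <- function(features, protocol, multiclass) {
  stopifnot(inherits(features, "spectra_features"))
  withr::local_seed(protocol$seed)
  m <- features$features
  labels <- features$meta$class_label
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 20)) {
    abort(paste0("class '", names(counts)[which(counts < 20)[1]],
                 "' has fewer than 20 spectra"))
  }
  if (any(counts < protocol$final_cv_folds)) {
    abort("every class must have at least as many spectra as CV folds")
  }

  # class-stratified held-out split
  test_idx <- sort(unlist(lapply(classes, function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1, round(protocol$test_fraction * length(idx))))
  })))
  train_idx <- setdiff(seq_len(nrow(m)), test_idx)

  y <- as.integer(factor(labels, levels = classes)) - 1L
  x_tr <- m[train_idx, , drop = FALSE]
  y_tr <- y[train_idx]

  base_params <- if (multiclass) {
    list(objective = "multi:softprob", eval_metric = "mlogloss",
         num_class = length(classes), nthread = 1)
  } else {
    list(objective = "binary:logistic", eval_metric = "auc",
         scale_pos_weight = sum(y_tr == 0) / sum(y_tr == 1), nthread = 1)
  }
  dtrain <- xgboost::xgb.DMatrix(x_tr, label = y_tr)

  tune_folds <- make_stratified_folds(labels[train_idx], protocol$tune_folds)
  run_cv <- function(hp) {
    cv <- xgboost::xgb.cv(
      params = c(base_params, hp), data = dtrain,
      nrounds = protocol$max_boosting_rounds, folds = tune_folds,
      early_stopping_rounds = protocol$early_stopping_rounds,
      maximize = !multiclass, verbose = 0
    )
    metric <- if (multiclass) "test_mlogloss_mean" else "test_auc_mean"
    it <- cv$best_iteration
    if (is.null(it) || is.na(it)) {
      it <- if (multiclass) which.min(cv$evaluation_log[[metric]])
      else which.max(cv$evaluation_log[[metric]])
    }
    list(score = cv$evaluation_log[[metric]][it], nrounds = it)
  }

  best_hp <- .default_booster_params()
  best <- run_cv(best_hp)
  if (protocol$tune_trials > 0) {
    for (trial in seq_len(protocol$tune_trials)) {
      hp <- .sample_booster_params()
      res <- run_cv(hp)
      better <- if (multiclass) res$score < best$score else res$score > best$score
      if (better) {
        best <- res
        best_hp <- hp
      }
    }
  }
  params <- c(base_params, best_hp)
  nrounds <- best$nrounds

  # final stratified CV on the training split
  folds <- make_stratified_folds(labels[train_idx], protocol$final_cv_folds)
  k <- length(classes)
  conf <- matrix(0, k, k, dimnames = list(truth = classes, predicted = classes))
  fold_acc <- numeric(length(folds))
  for (j in seq_along(folds)) {
    hold <- folds[[j]]
    fit <- xgboost::xgb.train(
      params = params,
      data = xgboost::xgb.DMatrix(x_tr[-hold, , drop = FALSE],
                                  label = y_tr[-hold]),
      nrounds = nrounds, verbose = 0
    )
    p <- predict(fit, xgboost::xgb.DMatrix(x_tr[hold, , drop = FALSE]))
    pred <- if (multiclass) {
      max.col(prob_matrix(p, k)) - 1L
    } else {
      as.integer(p > 0.5)
    }
    fold_acc[j] <- mean(pred == y_tr[hold])
    for (i in seq_along(hold)) {
      conf[y_tr[hold[i]] + 1L, pred[i] + 1L] <- conf[y_tr[hold[i]] + 1L, pred[i] + 1L] + 1
    }
  }
  confusion <- conf / pmax(rowSums(conf), 1)

  model <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = nrounds, verbose = 0)

  # held-out evaluation
  p_test <- predict(model, xgboost::xgb.DMatrix(m[test_idx, , drop = FALSE]))
  if (multiclass) {
    pred_test <- max.col(prob_matrix(p_test, k)) - 1L
    test_accuracy <- mean(pred_test == y[test_idx])
    roc <- NULL
    auc <- NA_real_
  } else {
    y_test <- y[test_idx]
    test_accuracy <- mean(as.integer(p_test > 0.5) == y_test)
    roc <- roc_points(p_test, y_test)
    auc <- auc_from_scores(p_test, y_test)
  }

  imp <- xgboost::xgb.importance(model = model)
  importance <- tibble(feature = imp$Feature, gain = imp$Gain)

  structure(list(
    model = model, classes = classes,
    positive = if (!multiclass) classes[2] else NULL,
    params = params, nrounds = nrounds,
    fold_accuracy = fold_acc, cv_accuracy = mean(fold_acc),
    confusion = confusion, confusion_counts = conf,
    roc = roc, auc = auc, test_accuracy = test_accuracy,
    importance = importance,
    augmented = features$augmented, wavenumbers = features$wavenumbers,
    train_ids = features$meta$spectrum_id[train_idx],
    test_ids = features$meta$spectrum_id[test_idx],
    donors = unique(features$meta$donor_id),
    protocol = protocol
  ), class = "spectra_classifier")
}

#' Donor-level training scheme
#'
#' Trains one classifier per donor (motivated by inter-donor variability
#' exceeding between-class differences in pooled data) and pools the
#' results: mean donor-level CV accuracy, and per-donor test ROC curves
#' interpolated onto a common false-positive-rate grid (101 points),
#' bootstrap-averaged over donors with a 95% percentile band.
#'
#' @param x A preprocessed spectra table with at least 2 donors (a single
#'   donor is allowed; the pooled summary then equals that donor's report).
#' @param protocol A [train_protocol()].
#' @param augment,window,polyorder Passed to [augment_derivatives()].
#' @param n_boot Bootstrap resamples over donors (default 1000).
#' @return A list of class `donor_classifiers`: `reports` (per donor),
#'   `mean_cv_accuracy`, `roc_grid` (fpr, mean and 95% band of tpr), and
#'   `skipped` donors.
#' @export
train_per_donor <- function(x, protocol = train_protocol(), augment = TRUE,
                            window = 11L, polyorder = 3L, n_boot = 1000L) {
  x <- as_spectra_tbl(x)
  donors <- sort(unique(x$donor_id))
  reports <- list()
  skipped <- character()
  for (d in donors) {
    sub <- x[x$donor_id == d, ]
    class(sub) <- unique(c("spectra_tbl", class(sub)))
    rep_d <- tryCatch(
      train_classifier(augment_derivatives(sub, augment = augment,
                                           window = window,
                                           polyorder = polyorder),
                       protocol),
      error = function(e) {
        warn(paste0("donor '", d, "' skipped: ", conditionMessage(e)))
        NULL
      })
    if (!is.null(rep_d)) reports[[d]] <- rep_d else skipped <- c(skipped, d)
  }
  if (length(reports) == 0) abort("no donor could be trained")

  grid <- seq(0, 1, length.out = 101)
  tpr_mat <- vapply(reports, function(r) {
    stats::approx(r$roc$fpr, r$roc$tpr, xout = grid, ties = max,
                  rule = 2)$y
  }, numeric(length(grid)))
  tpr_mat <- matrix(tpr_mat, nrow = length(grid))
  withr::local_seed(protocol$seed)
  nb <- max(1L, as.integer(n_boot))
  boot_mean <- matrix(NA_real_, length(grid), nb)
  for (b in seq_len(nb)) {
    pick <- sample(ncol(tpr_mat), replace = TRUE)
    boot_mean[, b] <- rowMeans(tpr_mat[, pick, drop = FALSE])
  }
  roc_grid <- tibble(
    fpr = grid,
    tpr_mean = rowMeans(tpr_mat),
    tpr_lo = apply(boot_mean, 1, quantile, 0.025),
    tpr_hi = apply(boot_mean, 1, quantile, 0.975)
  )
  structure(list(
    reports = reports,
    mean_cv_accuracy = mean(vapply(reports, `[[`, numeric(1), "cv_accuracy")),
    mean_auc = mean(vapply(reports, `[[`, numeric(1), "auc")),
    roc_grid = roc_grid,
    skipped = skipped
  ), class = "donor_classifiers")
}

#' Gain-based importance profile over wavenumbers
#'
#' For models trained on non-derivative-augmented features, converts each
#' donor model's per-feature gain into a per-wavenumber profile:
#' sum-normalized (gain fractions) then min-max scaled to `[0, 1]`, with
#' the across-donor mean and SD reported per wavenumber.
#'
#' @param models A `donor_classifiers` object or list of
#'   `spectra_classifier` reports, all trained with `augment = FALSE`.
#' @return A tibble `wavenumber`, `mean_importance`, `sd_importance`.
#' @export
importance_profile <- function(models) {
  if (inherits(models, "donor_classifiers")) models <- models$reports
  if (inherits(models, "spectra_classifier")) models <- list(models)
  if (any(vapply(models, `[[`, logical(1), "augmented"))) {
    abort("importance profiles require models trained on non-augmented features")
  }
  wn <- models[[1]]$wavenumbers
  labs <- paste0("i_", format_wavenumber(wn))
  prof <- vapply(models, function(r) {
    g <- setNames(rep(0, length(labs)), labs)
    g[r$importance$feature] <- r$importance$gain
    g <- g / max(sum(g), .Machine$double.eps)
    rng <- max(g) - min(g)
    if (rng == 0) rep(0, length(g)) else (g - min(g)) / rng
  }, numeric(length(labs)))
  prof <- matrix(prof, nrow = length(labs))
  tibble(
    wavenumber = wn,
    mean_importance = rowMeans(prof),
    sd_importance = if (ncol(prof) == 1) 0 else apply(prof, 1, sd)
  )
}
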