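# Subject-specific classification and macro-averaged evaluation.
#
# The gradient-boosted model (xgboost, softmax objective) is tuned by
# stratified 5-fold cross-validation over a small grid and refit on all
# training rows. Evaluation builds the 3x3 confusion matrix and the
# macro-averaged precision/recall/F1 (unweighted class means; macro-F1 is
# the harmonic mean of macro-P and macro-R).

feature_matrix <- function(table) {
  meta <- c("subject_id", "state_id", "role")
  as.matrix(table[setdiff(names(table), meta)])
}

#' Stratified fold assignment
#'
#' @param y Integer class labels.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:folds`.
#' @export
stratified_folds <- function(y, folds = 5L, seed = 1L) {
  with_seed(seed, {
    id <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
}

#' Default hyperparameter grid for the boosted model
#'
#' Learning rate, tree depth, boosting rounds and row subsampling; the
#' mean stratified-CV accuracy picks the winner (ties toward the first row).
#'
#' @param compact Use a reduced grid (6 settings) instead of the full 54;
#'   useful for quick runs.
#' @return Data frame with columns `eta`, `max_depth`, `nrounds`,
#'   `subsample`.
#' @export
xgb_grid <- function(compact = FALSE) {
  if (compact) {
    expand.grid(eta = c(0.1, 0.3), max_depth = 3L,
                nrounds = c(50L, 100L), subsample = c(0.8, 1))[c(1:4, 6, 8), ]
  } else {
    expand.grid(eta = c(0.05, 0.1, 0.3), max_depth = 2:4,
                nrounds = c(50L, 100L, 200L), subsample = c(0.8, 1))
  }
}

fit_xgb <- function(x, y, par, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = 3,
                  eta = par$eta, max_depth = par$max_depth,
                  subsample = par$subsample, nthread = 1,
                  seed = seed %% 2147483647),
    data = dtrain, nrounds = par$nrounds, verbose = 0)
}

#' Train a subject-specific boosted fatigue classifier
#'
#' Grid search over [xgb_grid()] maximizing mean stratified `folds`-fold
#' accuracy on the subject's training rows, followed by a refit on all
#' training rows with the winning setting. Deterministic given `seed`
#' (single-threaded fits, seeded fold assignment and subsampling).
#'
#' @param table Feature table restricted to one subject's training rows;
#'   must contain all three classes with at least `folds` rows each.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed.
#' @param grid Hyperparameter grid (default [xgb_grid()]).
#'
#' @return A `model_bundle`: fitted `estimator`, `hyperparams` (winning
#'   row), `cv_accuracy`, `cv_table` (accuracy per grid row), `subject_id`,
#'   `feature_names`, `label_map`.
#' @export
train_subject_model <- function(table, folds = 5L, seed = 1L,
                                grid = xgb_grid()) {
  validate_feature_table(table)
  x <- feature_matrix(table)
  y <- as.integer(table$state_id)
  classes <- sort(unique(y))
  if (!identical(classes, 0:2))
    stop_param("training table must contain all three classes 0, 1, 2")
  if (min(table(y)) < folds)
    stop_param("need at least `folds` samples per class")

  fold_id <- stratified_folds(y, folds, derive_seed(seed, "folds"))
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    par <- grid[g, ]
    accs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_xgb(x[tr, , drop = FALSE], y[tr], par,
                     derive_seed(seed, "cv", g, f))
      prob <- predict(fit, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE],
                                                nthread = 1))
      mean(max.col(prob, ties.method = "first") - 1L == y[!tr])
    }, 0)
    mean(accs)
  }, 0)

  best <- which.max(cv_acc)                 # ties: first grid row
  est <- fit_xgb(x, y, grid[best, ], derive_seed(seed, "final"))
  structure(list(estimator = est,
                 hyperparams = grid[best, ],
                 cv_accuracy = cv_acc[best],
                 cv_table = cbind(grid, cv_accuracy = cv_acc),
                 subject_id = table$subject_id[1],
                 feature_names = colnames(x),
                 label_map = stats::setNames(0:2, c("alert", "moderate",
                                                    "fatigued"))),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> subject %s, cv accuracy %.3f\n",
              x$subject_id, x$cv_accuracy))
  cat("  hyperparams:", paste(names(x$hyperparams),
                              unlist(x$hyperparams), sep = "=",
                              collapse = " "), "\n")
  invisible(x)
}

#' Predict fatigue degrees
#'
#' @param object A `model_bundle`.
#' @param newdata Feature table or numeric feature matrix with the model's
#'   feature columns.
#' @param ... Unused.
#' @return List with `label` (integer classes, argmax of the probabilities,
#'   ties toward the lowest class index) and `prob` (rows on the 3-class
#'   simplex).
#' @export
predict.model_bundle <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (ncol(x) != length(object$feature_names))
    stop_param("feature width mismatch: model expects ",
               length(object$feature_names), " columns, got ", ncol(x))
  prob <- predict(object$estimator, xgboost::xgb.DMatrix(x, nthread = 1))
  list(label = max.col(prob, ties.method = "first") - 1L, prob = prob)
}

#' Build an evaluation report from labels
#'
#' Confusion matrix (rows = true, cols = predicted) over classes 0..2,
#' accuracy, per-class precision/recall, and the macro-averaged metrics:
#' macro-P and macro-R are unweighted means of the per-class values and
#' macro-F1 is their harmonic mean. A class that is never predicted gets
#' precision 0 with a warning.
#'
#' @param true,pred Integer label vectors (values in 0..2).
#' @return An `evaluation_report`.
#' @export
evaluation_report <- function(true, pred) {
  if (!length(true)) stop_param("empty test set")
  lv <- 0:2
  confusion <- table(factor(true, levels = lv), factor(pred, levels = lv))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(true = lv, predicted = lv)
  tp <- diag(confusion)
  colsum <- colSums(confusion)
  rowsum <- rowSums(confusion)
  if (any(colsum == 0 & rowsum > 0))
    warning("class never predicted; its precision set to 0", call. = FALSE)
  precision <- ifelse(colsum > 0, tp / colsum, 0)
  recall <- ifelse(rowsum > 0, tp / rowsum, 0)
  macro_p <- mean(precision)
  macro_r <- mean(recall)
  macro_f1 <- if (macro_p + macro_r > 0)
    2 * macro_p * macro_r / (macro_p + macro_r) else 0
  structure(list(confusion = confusion,
                 accuracy = sum(tp) / sum(confusion),
                 per_class = data.frame(class = lv, precision = precision,
                                        recall = recall),
                 macro_p = macro_p, macro_r = macro_r, macro_f1 = macro_f1,
                 n = length(true)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n=%d acc=%.4f macro-P=%.4f macro-R=%.4f macro-F1=%.4f\n",
    x$n, x$accuracy, x$macro_p, x$macro_r, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a model on a labeled test table
#'
#' @param model A `model_bundle` (or any object with a compatible
#'   [predict()] method returning `$label`).
#' @param test_table Labeled feature table.
#' @return An `evaluation_report`.
#' @export
evaluate_model <- function(model, test_table) {
  validate_feature_table(test_table)
  if (!nrow(test_table)) stop_param("empty test set")
  pred <- predict(model, test_table)$label
  evaluation_report(as.integer(test_table$state_id), pred)
}

# ---- comparison classifiers -------------------------------------------------

# SAMME AdaBoost over rpart trees (multi-class). Weighted resampling-free:
# rpart accepts case weights directly.
adaboost_fit <- function(x, y, nrounds = 100L, maxdepth = 3L, seed = 1L) {
  n <- length(y)
  K <- length(unique(y))
  df <- data.frame(y = factor(y), x)
  w <- rep(1 / n, n)
  fits <- list(); alphas <- numeric(0)
  with_seed(seed, {
    for (b in seq_len(nrounds)) {
      fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(maxdepth = maxdepth,
                                                         cp = 0, xval = 0))
      pred <- predict(fit, df, type = "class")
      mis <- as.numeric(pred != df$y)
      err <- sum(w * mis) / sum(w)
      if (err >= 1 - 1 / K) break
      err <- max(err, 1e-10)
      alpha <- log((1 - err) / err) + log(K - 1)
      fits[[length(fits) + 1]] <- fit
      alphas <- c(alphas, alpha)
      w <- w * exp(alpha * mis)
      w <- w / sum(w)
      if (err < 1e-8) break
    }
  })
  structure(list(fits = fits, alphas = alphas, levels = levels(df$y)),
            class = "adaboost_samme")
}

#' @export
predict.adaboost_samme <- function(object, newdata, ...) {
  df <- data.frame(newdata)
  votes <- matrix(0, nrow(df), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (b in seq_along(object$fits)) {
    pred <- predict(object$fits[[b]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + object$alphas[b]
  }
  as.integer(object$levels[max.col(votes, ties.method = "first")])
}

#' Compare classifiers on one subject's data
#'
#' Fits an RBF-kernel SVM (standardized features), a random forest, SAMME
#' AdaBoost and the boosted model of [train_subject_model()] on the same
#' training rows, each tuned by the same stratified `folds`-fold protocol
#' over a small grid, and evaluates all of them on the same test rows.
#'
#' @param train,test Feature tables (training/test rows of one subject).
#' @param seed Integer seed.
#' @param folds CV folds (default 5).
#' @param xgb_grid_ Grid for the boosted model (default compact, see
#'   [xgb_grid()]).
#' @return List with `reports` (named `evaluation_report`s) and `summary`
#'   (4-row data frame: classifier, accuracy, macro_p, macro_r, macro_f1).
#' @export
compare_classifiers <- function(train, test, seed = 1L, folds = 5L,
                                xgb_grid_ = xgb_grid(compact = TRUE)) {
  validate_feature_table(train); validate_feature_table(test)
  x <- feature_matrix(train); y <- as.integer(train$state_id)
  xt <- feature_matrix(test)
  fold_id <- stratified_folds(y, folds, derive_seed(seed, "cmp-folds"))

  tune <- function(grid, fit_fun, pred_fun) {
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        fit <- fit_fun(x[tr, , drop = FALSE], y[tr], grid[g, ],
                       derive_seed(seed, "cmp", g, f))
        mean(pred_fun(fit, x[!tr, , drop = FALSE]) == y[!tr])
      }, 0))
    }, 0)
    grid[which.max(acc), , drop = FALSE]
  }

  reports <- list()

  svm_grid <- expand.grid(cost = c(1, 10, 100), gamma = c(1 / ncol(x), 0.01))
  svm_fit <- function(x, y, par, s) e1071::svm(x, factor(y, levels = 0:2),
                                               kernel = "radial", scale = TRUE,
                                               cost = par$cost, gamma = par$gamma)
  svm_pred <- function(fit, x) as.integer(as.character(predict(fit, x)))
  best <- tune(svm_grid, svm_fit, svm_pred)
  fit <- svm_fit(x, y, best, seed)
  reports$svm <- evaluation_report(as.integer(test$state_id), svm_pred(fit, xt))

  rf_grid <- expand.grid(ntree = 200L, mtry = unique(pmax(1L,
    round(c(sqrt(ncol(x)), ncol(x) / 3)))))
  rf_fit <- function(x, y, par, s) with_seed(s,
    randomForest::randomForest(x, factor(y, levels = 0:2),
                               ntree = par$ntree, mtry = par$mtry))
  rf_pred <- function(fit, x) as.integer(as.character(predict(fit, x)))
  best <- tune(rf_grid, rf_fit, rf_pred)
  fit <- rf_fit(x, y, best, derive_seed(seed, "rf-final"))
  reports$random_forest <- evaluation_report(as.integer(test$state_id),
                                             rf_pred(fit, xt))

  ada_grid <- expand.grid(nrounds = c(50L, 100L), maxdepth = c(2L, 3L))
  ada_fit <- function(x, y, par, s) adaboost_fit(x, y, par$nrounds,
                                                 par$maxdepth, s)
  ada_pred <- function(fit, x) predict(fit, x)
  best <- tune(ada_grid, ada_fit, ada_pred)
  fit <- ada_fit(x, y, best, derive_seed(seed, "ada-final"))
  reports$adaboost <- evaluation_report(as.integer(test$state_id),
                                        ada_pred(fit, xt))

  model <- train_subject_model(train, folds = folds,
                               seed = derive_seed(seed, "xgb"),
                               grid = xgb_grid_)
  reports$xgboost <- evaluate_model(model, test)

  summary <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(classifier = nm, accuracy = r$accuracy, macro_p = r$macro_p,
               macro_r = r$macro_r, macro_f1 = r$macro_f1)
  }))
  list(reports = reports, summary = summary)
}
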