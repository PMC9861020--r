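# Model training, prediction, and macro-averaged evaluation.

# Well-separated 3-class gaussian feature table for fast classifier tests.
gaussian_table <- function(n_per_class = 30, p = 10, sep = 3, seed = 1,
                           role = "train") {
  set.seed(seed)
  x <- do.call(rbind, lapply(0:2, function(cl) {
    matrix(rnorm(n_per_class * p, mean = cl * sep), n_per_class, p)
  }))
  tab <- as.data.frame(x)
  names(tab) <- paste0("f", seq_len(p))
  tab$subject_id <- "S01"
  tab$state_id <- rep(0:2, each = n_per_class)
  tab$role <- role
  tab
}

test_that("evaluation metrics are exact on hand-enumerated cases", {
  true <- rep(0:2, each = 29)
  r <- evaluation_report(true, true)
  expect_equal(r$accuracy, 1)
  expect_equal(r$macro_p, 1)
  expect_equal(r$macro_r, 1)
  expect_equal(r$macro_f1, 1)
  expect_equal(sum(r$confusion), 87)

  # 10 per class; one sample of each class flipped to the next class
  true2 <- rep(0:2, each = 10)
  pred2 <- true2
  pred2[c(1, 11, 21)] <- c(1, 2, 0)
  r2 <- evaluation_report(true2, pred2)
  expect_equal(r2$accuracy, 27 / 30)
  # every class: TP=9, FP=1, FN=1 -> P_i = R_i = 0.9
  expect_equal(r2$macro_p, 0.9)
  expect_equal(r2$macro_r, 0.9)
  expect_equal(r2$macro_f1, 0.9)
})

test_that("macro metrics reproduce their defining identities on random labelings", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(30:90, 1)
    true <- sample(0:2, n, replace = TRUE)
    pred <- sample(0:2, n, replace = TRUE)
    if (length(unique(true)) < 3) next
    r <- suppressWarnings(evaluation_report(true, pred))
    cm <- r$confusion
    expect_equal(sum(cm), n)
    expect_true(all(cm >= 0))
    expect_equal(r$accuracy, sum(diag(cm)) / n)
    P <- vapply(1:3, function(k) {
      cs <- sum(cm[, k]); if (cs == 0) 0 else cm[k, k] / cs
    }, 0)
    R <- vapply(1:3, function(k) {
      rs <- sum(cm[k, ]); if (rs == 0) 0 else cm[k, k] / rs
    }, 0)
    expect_equal(r$macro_p, mean(P))
    expect_equal(r$macro_r, mean(R))
    expect_equal(r$macro_f1,
                 if (mean(P) + mean(R) > 0)
                   2 * mean(P) * mean(R) / (mean(P) + mean(R)) else 0)
  }
})

test_that("balanced test sets make accuracy equal macro recall", {
  set.seed(11)
  true <- rep(0:2, each = 20)
  pred <- sample(0:2, 60, replace = TRUE)
  r <- suppressWarnings(evaluation_report(true, pred))
  expect_equal(r$accuracy, r$macro_r)
})

test_that("a never-predicted class yields zero precision with a warning", {
  true <- rep(0:2, each = 5)
  pred <- rep(c(0, 1, 1), each = 5)
  expect_warning(r <- evaluation_report(true, pred), "never predicted")
  expect_equal(r$per_class$precision[3], 0)
  expect_error(evaluation_report(integer(0), integer(0)), "empty")
})

test_that("training is deterministic and prediction respects the contract", {
  tab <- gaussian_table(n_per_class = 20, sep = 2, seed = 2)
  g <- xgb_grid(compact = TRUE)
  m1 <- train_subject_model(tab, seed = 5, grid = g)
  m2 <- train_subject_model(tab, seed = 5, grid = g)
  expect_equal(m1$hyperparams, m2$hyperparams)
  expect_equal(m1$cv_table$cv_accuracy, m2$cv_table$cv_accuracy)
  expect_gte(m1$cv_accuracy, 0.9)

  test_tab <- gaussian_table(n_per_class = 15, sep = 2, seed = 3,
                             role = "test")
  pr <- predict(m1, test_tab)
  expect_equal(rowSums(pr$prob), rep(1, nrow(test_tab)), tolerance = 1e-6)
  expect_true(all(pr$prob >= 0))
  # argmax consistency
  expect_equal(pr$label, max.col(pr$prob, ties.method = "first") - 1L)
  rep_ <- evaluate_model(m1, test_tab)
  expect_gte(rep_$accuracy, 0.9)

  expect_error(predict(m1, as.matrix(test_tab[, 1:4])), "width mismatch")
})

test_that("training rejects degenerate label sets", {
  tab <- gaussian_table(n_per_class = 10)
  expect_error(train_subject_model(tab[tab$state_id != 2, ]),
               "three classes")
  expect_error(train_subject_model(tab[c(1:3, 11:20, 21:30), ], folds = 5),
               "folds")
})

test_that("an overcapacity model memorizes its training data", {
  tab <- gaussian_table(n_per_class = 15, sep = 0.5, seed = 6)
  deep <- data.frame(eta = 0.3, max_depth = 8L, nrounds = 300L,
                     subsample = 1)
  m <- train_subject_model(tab, seed = 1, grid = deep)
  expect_gte(evaluate_model(m, tab)$accuracy, 0.99)
})

test_that("SAMME AdaBoost learns separable classes", {
  tab <- gaussian_table(n_per_class = 20, sep = 2.5, seed = 7)
  x <- as.matrix(tab[paste0("f", 1:10)])
  y <- tab$state_id
  fit <- eegfatigue:::adaboost_fit(x, y, nrounds = 30, maxdepth = 2,
                                   seed = 1)
  expect_gte(mean(predict(fit, x) == y), 0.95)
})

test_that("the four-classifier comparison emits a well-formed table", {
  train <- gaussian_table(n_per_class = 20, sep = 2, seed = 8)
  test <- gaussian_table(n_per_class = 10, sep = 2, seed = 9, role = "test")
  cmp <- compare_classifiers(train, test, seed = 4)
  expect_equal(nrow(cmp$summary), 4)
  expect_setequal(cmp$summary$classifier,
                  c("svm", "random_forest", "adaboost", "xgboost"))
  expect_true(all(cmp$summary$accuracy > 0.5))   # all beat chance
  cmp2 <- compare_classifiers(train, test, seed = 4)
  expect_equal(cmp$summary, cmp2$summary)        # deterministic
})
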