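test_that("min-max scaling uses training bounds and never clips the test set", {
  tr <- matrix(c(0, 10, 5, 7), ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  te <- matrix(c(20, 6), ncol = 2, dimnames = list(NULL, c("a", "b")))
  sc <- minmax_scale(tr, te)
  expect_equal(sc$train[, "a"], c(0, 1))
  expect_equal(unname(sc$test[1, "a"]), 2.0)    # outside [0, 1], not clipped

  const <- matrix(c(1, 1, 0, 9), ncol = 2,
                  dimnames = list(NULL, c("c", "d")))
  expect_warning(scc <- minmax_scale(const), "constant")
  expect_equal(scc$train[, "c"], c(0, 0))
  expect_error(minmax_scale(matrix(1, nrow = 1)), "2 training rows")
})

test_that("stratified splitting is reproducible and proportion-preserving", {
  set.seed(1)
  X <- matrix(rnorm(300 * 3), ncol = 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c("healthy", "chf"), times = c(115, 185))
  sp <- split_dataset(X, y, 0.2, seed = 5)
  expect_equal(nrow(sp$train_X), 240L)
  expect_equal(nrow(sp$test_X), 60L)
  expect_equal(sum(sp$test_y == "healthy"), 23L)   # round(0.2 * 115)
  expect_equal(sum(sp$test_y == "chf"), 37L)

  sp2 <- split_dataset(X, y, 0.2, seed = 5)
  expect_identical(sp$test_idx, sp2$test_idx)
  expect_error(split_dataset(X, rep("chf", 300), 0.2, 1), "both classes")
})

test_that("cross-validation scores separable data at 1 and permuted labels near chance", {
  blobs <- make_blobs(30, shift = 5)
  expect_equal(crossval_score("knn_fine", list(), blobs$X, blobs$y,
                              k = 10, seed = 2), 1.0)
  set.seed(3)
  y_perm <- sample(blobs$y)
  acc <- crossval_score("knn_medium", list(), blobs$X, y_perm,
                        k = 10, seed = 2)
  expect_lt(abs(acc - 0.5), 0.12)
  expect_error(crossval_score("knn_fine", list(), blobs$X[1:10, ],
                              blobs$y[c(1:5, 31:35)], k = 10, seed = 1),
               "exceeds")
})

test_that("baseline presets honour their contracts", {
  blobs <- make_blobs(30, shift = 3)
  # k = 1 memorises its own training set
  m1 <- train_baseline("knn_fine", blobs$X, blobs$y, seed = 1, cv_folds = 0)
  expect_equal(mean(predict(m1, blobs$X) == blobs$y), 1.0)

  # coarse tree limited to at most 4 splits
  mc <- train_baseline("dt_coarse", blobs$X, blobs$y, seed = 1, cv_folds = 0)
  n_splits <- sum(mc$fit$fit$frame$var != "<leaf>")
  expect_lte(n_splits, 4L)

  # the scaler comes from training rows only
  expect_equal(mc$scaler$min, apply(blobs$X, 2, min))

  expect_error(train_baseline("bogus", blobs$X, blobs$y), "unknown")
})

test_that("RUSBoost recovers minority recall on imbalanced data", {
  set.seed(17)
  n_maj <- 180; n_min <- 20
  X <- rbind(matrix(rnorm(n_maj * 4, 0), ncol = 4),
             matrix(rnorm(n_min * 4, 1.2), ncol = 4))
  colnames(X) <- paste0("f", 1:4)
  y <- c(rep("healthy", n_maj), rep("chf", n_min))
  sp <- split_dataset(X, y, 0.3, seed = 6)
  rus <- train_baseline("em_rusboost", sp$train_X, sp$train_y,
                        seed = 4, cv_folds = 0)
  bag <- train_baseline("em_bagged", sp$train_X, sp$train_y,
                        seed = 4, cv_folds = 0)
  rec <- function(m) mean(predict(m, sp$test_X)[sp$test_y == "chf"] == "chf")
  expect_gte(rec(rus), rec(bag))
})

test_that("BO-SVM solves separable and XOR-pattern data deterministically", {
  blobs <- make_blobs(30, shift = 5)
  sp <- split_dataset(blobs$X, blobs$y, 0.2, seed = 8)
  m <- bo_svm_train(sp$train_X, sp$train_y, n_iter = 15, seed = 4)
  expect_equal(evaluate_model(m, sp$test_X, sp$test_y)$Acc, 1.0)
  expect_true(all(diff(cummax(m$trace$cv_accuracy)) >= 0))

  # XOR pattern: RBF via BO succeeds where every linear-cost setting fails
  set.seed(9)
  n <- 30
  centers <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  Xx <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(n * 2, 0, 0.15), ncol = 2), 2, centers[i, ], "+")))
  colnames(Xx) <- c("f1", "f2")
  yx <- rep(c("healthy", "healthy", "chf", "chf"), each = n)
  mx <- bo_svm_train(Xx, yx, n_iter = 20, seed = 4)
  expect_gte(mx$cv_score, 0.9)
  lin_best <- max(vapply(10^seq(-3, 3, by = 1), function(cc) {
    folds <- rep_len(1:10, nrow(Xx))
    mean(vapply(1:10, function(f) {
      fit <- e1071::svm(Xx[folds != f, ], factor(yx[folds != f]),
                        kernel = "linear", cost = cc, scale = FALSE)
      mean(predict(fit, Xx[folds == f, ]) == yx[folds == f])
    }, numeric(1)))
  }, numeric(1)))
  expect_lte(lin_best, 0.7)

  m2 <- bo_svm_train(sp$train_X, sp$train_y, n_iter = 15, seed = 4)
  expect_identical(m$trace, m2$trace)
  expect_error(bo_svm_train(sp$train_X, sp$train_y, n_iter = 3), "at least")
})

test_that("metric identities hold on the worked example and random matrices", {
  m <- metrics_report(TP = 29, FN = 5, TN = 22, FP = 4)
  expect_equal(m$Acc, 0.8500, tolerance = 1e-4)
  expect_equal(m$Se, 0.8529, tolerance = 1e-4)
  expect_equal(m$Sp, 0.8462, tolerance = 1e-4)
  expect_equal(m$Ps, 0.8788, tolerance = 1e-4)
  expect_equal(m$F1, 0.8657, tolerance = 1e-4)

  set.seed(19)
  for (i in 1:25) {
    cnt <- rpois(4, 20) + 1
    r <- metrics_report(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(r$Acc, (r$TP + r$TN) / sum(cnt))
    expect_equal(r$Se, r$TP / (r$TP + r$FN))
    expect_equal(r$Sp, r$TN / (r$TN + r$FP))
    expect_equal(r$Ps, r$TP / (r$TP + r$FP))
    expect_equal(r$F1, 2 * r$Se * r$Ps / (r$Se + r$Ps))
    expect_gte(r$Acc, min(r$Se, r$Sp) - 1e-12)
    expect_lte(r$Acc, max(r$Se, r$Sp) + 1e-12)
  }
  expect_error(metrics_report(0, 0, 10, 5), "no positive")
})

test_that("evaluation produces perfect metrics on perfect predictions", {
  blobs <- make_blobs(20, shift = 8)
  sp <- split_dataset(blobs$X, blobs$y, 0.25, seed = 3)
  m <- train_baseline("knn_fine", sp$train_X, sp$train_y, seed = 1,
                      cv_folds = 0)
  r <- evaluate_model(m, sp$test_X, sp$test_y)
  expect_equal(unlist(r[c("Acc", "Se", "Sp", "Ps", "F1")]),
               c(Acc = 1, Se = 1, Sp = 1, Ps = 1, F1 = 1))
  expect_error(evaluate_model(m, sp$test_X, rep("healthy", nrow(sp$test_X))),
               "no positive")
})
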