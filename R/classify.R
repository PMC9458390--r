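## Classification of KS feature vectors: min-max scaling, stratified
## splitting and cross-validation, eleven baseline presets (decision trees,
## nearest neighbours, naive Bayes, boosted/bagged ensembles) and the
## Bayesian-optimised RBF support vector machine. The CHF class is the
## positive class throughout.

.model_families <- c("dt_fine", "dt_medium", "dt_coarse",
                     "knn_fine", "knn_medium", "knn_cosine",
                     "nb_gaussian", "nb_kernel",
                     "em_adaboost", "em_bagged", "em_rusboost",
                     "bo_svm")

#' The twelve classifier family identifiers
#' @return Character vector of family names.
#' @export
model_families <- function() .model_families

as_class_factor <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), c("healthy", "chf"))
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  factor(y, levels = c("healthy", "chf"))
}

#' Min-max scale feature matrices with training-derived bounds
#'
#' Each feature is mapped through `(x - min) / (max - min)` using the
#' training minima and maxima only; test values may fall outside \[0, 1\]
#' and are deliberately not clipped. Constant training columns map to 0
#' with a warning.
#'
#' @param train_X Training feature matrix (>= 2 rows).
#' @param test_X Optional test matrix with the same columns.
#' @return List with `train`, `test` (or `NULL`) and the `scaler`
#'   (list of `min`, `range`).
#' @export
minmax_scale <- function(train_X, test_X = NULL) {
  train_X <- as.matrix(train_X)
  if (nrow(train_X) < 2L) stop("need at least 2 training rows")
  mins <- apply(train_X, 2L, min)
  rng <- apply(train_X, 2L, max) - mins
  if (any(rng == 0)) {
    warning("constant training column(s) scaled to 0: ",
            paste(colnames(train_X)[rng == 0], collapse = ", "))
  }
  scaler <- list(min = mins, range = rng)
  list(train = apply_scaler(train_X, scaler),
       test = if (!is.null(test_X)) apply_scaler(as.matrix(test_X), scaler),
       scaler = scaler)
}

apply_scaler <- function(X, scaler) {
  rng <- ifelse(scaler$range == 0, 1, scaler$range)
  out <- sweep(sweep(X, 2L, scaler$min), 2L, rng, "/")
  out[, scaler$range == 0] <- 0
  out
}

#' Stratified train/test split
#'
#' Randomly assigns `round(test_frac * n_c)` rows of each class to the test
#' partition, so class proportions are preserved within one sample.
#'
#' @param X Feature matrix or data frame.
#' @param y Class labels (`"healthy"`/`"chf"`).
#' @param test_frac Test fraction (default 0.2).
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return List with `train_X`, `train_y`, `test_X`, `test_y`,
#'   `test_idx`, `seed`.
#' @export
split_dataset <- function(X, y, test_frac = 0.2, seed = 1L) {
  X <- as.matrix(X)
  y <- as_class_factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  if (min(table(y)) < 10L) stop("need at least 10 samples per class")
  test_idx <- with_local_seed(seed, {
    unlist(lapply(levels(y), function(cl) {
      rows <- which(y == cl)
      sample(rows, round(test_frac * length(rows)))
    }))
  })
  list(train_X = X[-test_idx, , drop = FALSE], train_y = y[-test_idx],
       test_X = X[test_idx, , drop = FALSE], test_y = y[test_idx],
       test_idx = sort(test_idx), seed = seed)
}

stratified_folds <- function(y, k, seed) {
  y <- as_class_factor(y)
  if (k > min(table(y))) stop("k exceeds the smallest class count")
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (cl in levels(y)) {
      rows <- sample(which(y == cl))
      folds[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  folds
}

#' Stratified k-fold cross-validated accuracy
#'
#' Min-max scaling is refit inside every fold on that fold's training rows,
#' so no information from held-out rows leaks into the model.
#'
#' @param family One of [model_families()] (not `"bo_svm"`; its
#'   hyperparameters come from the optimiser).
#' @param hyperparams Named list of hyperparameters for the family.
#' @param X Unscaled feature matrix.
#' @param y Class labels.
#' @param k Fold count (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Mean accuracy across folds.
#' @export
crossval_score <- function(family, hyperparams = list(), X, y,
                           k = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as_class_factor(y)
  folds <- stratified_folds(y, k, seed)
  accs <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    sc <- minmax_scale(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
    fit <- fit_family(family, sc$train, y[tr], hyperparams, seed = seed + f)
    mean(predict_family(fit, sc$test) == y[!tr])
  }, numeric(1))
  mean(accs)
}

## ---- family fitting -------------------------------------------------------

dt_presets <- c(dt_fine = 100L, dt_medium = 20L, dt_coarse = 4L)

fit_family <- function(family, X, y, hyperparams = list(), seed = 1L) {
  fit <- switch(
    family,
    dt_fine = , dt_medium = , dt_coarse =
      fit_pruned_tree(X, y, max_splits = dt_presets[[family]], seed = seed),
    knn_fine = list(kind = "knn", X = X, y = y, k = 1L, metric = "euclidean"),
    knn_medium = list(kind = "knn", X = X, y = y, k = 10L,
                      metric = "euclidean"),
    knn_cosine = list(kind = "knn", X = X, y = y, k = 10L, metric = "cosine"),
    nb_gaussian = list(kind = "nb_gaussian",
                       fit = e1071::naiveBayes(as.data.frame(X), y)),
    nb_kernel = fit_kernel_nb(X, y),
    em_adaboost = fit_adaboost(X, y, n_rounds = 30L, seed = seed),
    em_bagged = list(kind = "bagged",
                     fit = with_local_seed(seed,
                       randomForest::randomForest(X, y, ntree = 30L,
                                                  mtry = ncol(X)))),
    em_rusboost = fit_rusboost(X, y, n_rounds = 30L, seed = seed),
    bo_svm = {
      hp <- hyperparams
      if (is.null(hp$cost) || is.null(hp$gamma))
        stop("bo_svm requires cost and gamma hyperparameters")
      list(kind = "svm",
           fit = e1071::svm(X, y, kernel = "radial", cost = hp$cost,
                            gamma = hp$gamma, scale = FALSE))
    },
    stop("unknown model family: ", family)
  )
  fit$family <- family
  fit$hyperparams <- hyperparams
  class(fit) <- "ks_fit"
  fit
}

fit_pruned_tree <- function(X, y, max_splits, seed) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  tree <- with_local_seed(seed,
    rpart::rpart(.y ~ ., data = df, method = "class",
                 control = rpart::rpart.control(cp = 0, minsplit = 4L,
                                                minbucket = 2L, xval = 0L,
                                                maxdepth = 30L)))
  ct <- tree$cptable
  ok <- ct[ct[, "nsplit"] <= max_splits, , drop = FALSE]
  tree <- rpart::prune(tree, cp = ok[nrow(ok), "CP"])
  list(kind = "tree", fit = tree)
}

fit_kernel_nb <- function(X, y) {
  classes <- levels(y)
  by_class <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    bw <- apply(Xi, 2L, function(v) {
      b <- tryCatch(stats::bw.nrd0(v), error = function(e) 0)
      if (!is.finite(b) || b <= 0) 1e-3 else b
    })
    list(X = Xi, bw = bw, log_prior = log(mean(y == cl)))
  })
  names(by_class) <- classes
  list(kind = "nb_kernel", by_class = by_class, classes = classes)
}

## discrete AdaBoost.M1 with depth-1 rpart stumps
fit_adaboost <- function(X, y, n_rounds, seed, sampler = NULL) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(.y = y, X, check.names = FALSE)
  stumps <- list(); alphas <- numeric(0)
  with_local_seed(seed, {
    for (r in seq_len(n_rounds)) {
      fit_df <- df; fit_w <- w
      if (!is.null(sampler)) {                    # RUS: balanced subsample
        idx <- sampler(y, w)
        fit_df <- df[idx, , drop = FALSE]
        fit_w <- rep(1 / length(idx), length(idx))
      }
      stump <- rpart::rpart(.y ~ ., data = fit_df, weights = fit_w,
                            method = "class",
                            control = rpart::rpart.control(
                              maxdepth = 1L, cp = -1, minsplit = 2L,
                              minbucket = 1L, xval = 0L))
      pred <- predict(stump, df, type = "class")
      err <- sum(w[pred != y])
      if (err <= 1e-10) {
        stumps[[length(stumps) + 1L]] <- stump
        alphas <- c(alphas, 10)                   # perfect learner dominates
        break
      }
      if (err >= 0.5) break
      alpha <- 0.5 * log((1 - err) / err)
      stumps[[length(stumps) + 1L]] <- stump
      alphas <- c(alphas, alpha)
      w <- w * exp(alpha * ifelse(pred != y, 1, -1))
      w <- w / sum(w)
    }
  })
  if (length(stumps) == 0L) {                     # fall back to the majority
    maj <- levels(y)[which.max(tabulate(y))]
    return(list(kind = "majority", class = maj))
  }
  list(kind = "boost", stumps = stumps, alphas = alphas, levels = levels(y))
}

## random-undersampling boosting: each round trains on all minority rows plus
## an equally sized weighted draw of the majority class
fit_rusboost <- function(X, y, n_rounds, seed) {
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  sampler <- function(yy, ww) {
    mino <- which(yy == minority)
    majo <- which(yy != minority)
    size <- min(length(mino), length(majo))
    pr <- ww[majo] / sum(ww[majo])
    c(mino, sample(majo, size, prob = pr))
  }
  fit_adaboost(X, y, n_rounds, seed, sampler = sampler)
}

## ---- prediction -----------------------------------------------------------

predict_family <- function(fit, X) {
  X <- as.matrix(X)
  lv <- c("healthy", "chf")
  out <- switch(
    fit$kind,
    tree = predict(fit$fit, data.frame(X, check.names = FALSE),
                   type = "class"),
    knn = knn_predict(fit$X, fit$y, X, fit$k, fit$metric),
    nb_gaussian = predict(fit$fit, as.data.frame(X)),
    nb_kernel = kernel_nb_predict(fit, X),
    bagged = predict(fit$fit, X),
    boost = boost_predict(fit, X),
    svm = predict(fit$fit, X),
    majority = factor(rep(fit$class, nrow(X)), levels = lv),
    stop("unknown fit kind: ", fit$kind)
  )
  factor(as.character(out), levels = lv)
}

## majority-vote KNN; voting ties go to the class of the single nearest
## neighbour
knn_predict <- function(train_X, train_y, test_X, k, metric) {
  if (metric == "cosine") {
    norm_rows <- function(M) {
      nr <- sqrt(rowSums(M^2)); nr[nr == 0] <- 1
      M / nr
    }
    train_X <- norm_rows(train_X); test_X <- norm_rows(test_X)
  }
  tr2 <- rowSums(train_X^2)
  out <- character(nrow(test_X))
  for (i in seq_len(nrow(test_X))) {
    d2 <- tr2 - 2 * drop(train_X %*% test_X[i, ])   # + const
    o <- order(d2)[seq_len(k)]
    votes <- table(train_y[o])
    top <- names(votes)[votes == max(votes)]
    out[i] <- if (length(top) == 1L) top else as.character(train_y[o[1]])
  }
  out
}

kernel_nb_predict <- function(fit, X) {
  ll <- vapply(fit$classes, function(cl) {
    comp <- fit$by_class[[cl]]
    apply(X, 1L, function(row) {
      sum(vapply(seq_along(row), function(j) {
        log(mean(stats::dnorm(row[j], comp$X[, j], comp$bw[j])) +
              .Machine$double.xmin)
      }, numeric(1))) + comp$log_prior
    })
  }, numeric(nrow(X)))
  fit$classes[max.col(matrix(ll, nrow = nrow(X)))]
}

boost_predict <- function(fit, X) {
  df <- data.frame(X, check.names = FALSE)
  score <- numeric(nrow(X))
  for (r in seq_along(fit$stumps)) {
    pred <- predict(fit$stumps[[r]], df, type = "class")
    score <- score + fit$alphas[r] * ifelse(pred == "chf", 1, -1)
  }
  ifelse(score > 0, "chf", "healthy")
}

## ---- trained-model surface ------------------------------------------------

#' Train a baseline classifier preset
#'
#' Presets: decision trees grown with `rpart` and pruned to at most 100/20/4
#' splits (fine/medium/coarse); nearest neighbours with k=1 Euclidean (fine),
#' k=10 Euclidean (medium), k=10 cosine; Gaussian and kernel-density naive
#' Bayes; and 30-learner ensembles (AdaBoost on depth-1 stumps, bagged trees,
#' random-undersampling boosting). The min-max scaler is fitted on the
#' training rows only and stored with the model.
#'
#' @param family One of [model_families()] except `"bo_svm"`.
#' @param train_X Unscaled training feature matrix.
#' @param train_y Class labels.
#' @param seed Integer seed (ensembles, fold assignment).
#' @param cv_folds Folds for the stored training CV accuracy; `0` skips it.
#' @return A `trained_model`: list with `family`, `hyperparams`, `scaler`,
#'   `fit`, `cv_score`.
#' @export
train_baseline <- function(family, train_X, train_y, seed = 1L,
                           cv_folds = 10L) {
  if (!family %in% setdiff(.model_families, "bo_svm"))
    stop("unknown baseline family: ", family)
  train_X <- as.matrix(train_X)
  train_y <- as_class_factor(train_y)
  if (nlevels(droplevels(train_y)) < 2L) stop("both classes must be present")
  cv <- if (cv_folds > 0L)
    crossval_score(family, list(), train_X, train_y, k = cv_folds, seed = seed)
  else NA_real_
  sc <- minmax_scale(train_X)
  fit <- fit_family(family, sc$train, train_y, seed = seed)
  structure(list(family = family, hyperparams = fit$hyperparams,
                 scaler = sc$scaler, fit = fit, cv_score = cv, seed = seed),
            class = "trained_model")
}

#' Train the Bayesian-optimised RBF SVM
#'
#' Hyperparameter search over `log10(cost) in [-3, 3]` and
#' `log10(gamma) in [-4, 1]` (RBF kernel coefficient) by Bayesian
#' optimisation: a Gaussian-process surrogate with a squared-exponential
#' kernel, expected-improvement acquisition over a random candidate set,
#' 5 Latin-hypercube initial points and `n_iter` total objective
#' evaluations. The objective is 10-fold cross-validated accuracy with
#' scaling refit per fold. The best observed objective is non-decreasing
#' by construction; the trajectory is deterministic given `seed`.
#'
#' @param train_X Unscaled training feature matrix.
#' @param train_y Class labels.
#' @param n_iter Total objective evaluations (default 30, >= the 5-point
#'   initial design).
#' @param seed Integer seed.
#' @param cv_folds CV folds for the objective (default 10).
#' @return A `trained_model` with `hyperparams$cost`, `hyperparams$gamma`,
#'   `cv_score` (best CV accuracy) and the search `trace` (data frame of
#'   evaluated points).
#' @export
bo_svm_train <- function(train_X, train_y, n_iter = 30L, seed = 1L,
                         cv_folds = 10L) {
  n_init <- 5L
  if (n_iter < n_init) stop("n_iter must be at least the initial design (5)")
  train_X <- as.matrix(train_X)
  train_y <- as_class_factor(train_y)
  lo <- c(-3, -4); hi <- c(3, 1)                 # log10 cost, log10 gamma

  objective <- function(u) {                     # u in unit square
    th <- lo + u * (hi - lo)
    crossval_score("bo_svm",
                   list(cost = 10^th[1], gamma = 10^th[2]),
                   train_X, train_y, k = cv_folds, seed = seed)
  }

  U <- with_local_seed(seed, lhs::randomLHS(n_init, 2L))
  yobs <- apply(U, 1L, objective)
  cand_all <- with_local_seed(seed + 1L,
                              matrix(stats::runif(2L * 500L * n_iter),
                                     ncol = 2L))
  for (it in seq_len(n_iter - n_init)) {
    cand <- cand_all[((it - 1L) * 500L + 1L):(it * 500L), , drop = FALSE]
    u_next <- gp_ei_argmax(U, yobs, cand)
    U <- rbind(U, u_next)
    yobs <- c(yobs, objective(u_next))
  }
  best <- which.max(yobs)
  th <- lo + U[best, ] * (hi - lo)
  hp <- list(cost = 10^th[1], gamma = 10^th[2])

  sc <- minmax_scale(train_X)
  fit <- fit_family("bo_svm", sc$train, train_y, hyperparams = hp, seed = seed)
  trace <- data.frame(log10_cost = lo[1] + U[, 1] * (hi[1] - lo[1]),
                      log10_gamma = lo[2] + U[, 2] * (hi[2] - lo[2]),
                      cv_accuracy = yobs)
  structure(list(family = "bo_svm", hyperparams = hp, scaler = sc$scaler,
                 fit = fit, cv_score = yobs[best], trace = trace, seed = seed),
            class = "trained_model")
}

## GP posterior + expected improvement; fixed length scale on the unit
## square, signal variance from the observations, small noise nugget
gp_ei_argmax <- function(U, yobs, cand, ell = 0.2, noise = 1e-4) {
  sf2 <- max(stats::var(yobs), 1e-6)
  k_fun <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sf2 * exp(-pmax(d2, 0) / (2 * ell^2))
  }
  K <- k_fun(U, U) + diag(noise + 1e-8, nrow(U))
  mu0 <- mean(yobs)
  a <- solve(K, yobs - mu0)
  Ks <- k_fun(cand, U)
  mu <- mu0 + drop(Ks %*% a)
  v <- pmax(sf2 - rowSums((Ks %*% solve(K)) * Ks), 1e-12)
  s <- sqrt(v)
  best <- max(yobs)
  z <- (mu - best) / s
  ei <- (mu - best) * stats::pnorm(z) + s * stats::dnorm(z)
  cand[which.max(ei), ]
}

#' Predict class labels with a trained model
#'
#' @param object A `trained_model`.
#' @param newdata Unscaled feature matrix with the training columns.
#' @param ... Unused.
#' @return Factor of predicted labels (`healthy`/`chf`).
#' @export
predict.trained_model <- function(object, newdata, ...) {
  predict_family(object$fit, apply_scaler(as.matrix(newdata), object$scaler))
}

## ---- metrics --------------------------------------------------------------

#' Build a metrics report from confusion counts
#'
#' Computes accuracy, sensitivity, specificity, precision and F1 from the
#' confusion counts and asserts the defining identities on construction.
#' CHF is the positive class.
#'
#' @param TP,FN,TN,FP Confusion counts.
#' @return A `metrics_report`: list with the four counts and `Acc`, `Se`,
#'   `Sp`, `Ps`, `F1`.
#' @export
metrics_report <- function(TP, FN, TN, FP) {
  if (TP + FN == 0) stop("sensitivity undefined: no positive samples")
  if (TN + FP == 0) stop("specificity undefined: no negative samples")
  Acc <- (TP + TN) / (TP + FN + TN + FP)
  Se <- TP / (TP + FN)
  Sp <- TN / (TN + FP)
  Ps <- if (TP + FP > 0) TP / (TP + FP) else 0
  F1 <- if (Se + Ps > 0) 2 * Se * Ps / (Se + Ps) else 0
  stopifnot(abs(Acc - (TP + TN) / (TP + FN + TN + FP)) < 1e-12,
            Acc >= min(Se, Sp) - 1e-12, Acc <= max(Se, Sp) + 1e-12)
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP,
                 Acc = Acc, Se = Se, Sp = Sp, Ps = Ps, F1 = F1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> TP=%d FN=%d TN=%d FP=%d | Acc %.4f Se %.4f Sp %.4f Ps %.4f F1 %.4f\n",
    x$TP, x$FN, x$TN, x$FP, x$Acc, x$Se, x$Sp, x$Ps, x$F1))
  invisible(x)
}

#' Evaluate a trained model on a test set
#'
#' @param model A `trained_model`.
#' @param test_X Unscaled test feature matrix.
#' @param test_y True labels.
#' @return A [metrics_report()].
#' @export
evaluate_model <- function(model, test_X, test_y) {
  if (nrow(as.matrix(test_X)) == 0L) stop("empty test set")
  test_y <- as_class_factor(test_y)
  pred <- predict(model, test_X)
  metrics_report(TP = sum(pred == "chf" & test_y == "chf"),
                 FN = sum(pred == "healthy" & test_y == "chf"),
                 TN = sum(pred == "healthy" & test_y == "healthy"),
                 FP = sum(pred == "chf" & test_y == "healthy"))
}
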