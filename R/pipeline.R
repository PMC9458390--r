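## End-to-end experiment orchestration: feature tables from record sets, and
## the full feature-set x classifier evaluation grid.

#' Build a feature table from a list of records
#'
#' @param records List of [audio_record]s, or of `generate_record()` results
#'   (anything with a `$record` element).
#' @param config A [run_config()].
#' @return Data frame with the 46 feature columns plus `label` and
#'   `source_id`.
#' @export
extract_feature_table <- function(records, config = run_config()) {
  rows <- lapply(records, function(r) {
    rec <- if (inherits(r, "audio_record")) r else r$record
    fv <- extract_features(rec, config)
    c(as.list(unclass(fv)), list(label = rec$label, source_id = rec$source_id))
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
}

#' Run the full classification experiment
#'
#' For each feature set (A: energy + statistical + entropy, 33 features;
#' B: statistical + entropy + MFCC, 27; C: all 46) and each of the twelve
#' classifier presets: one stratified 80/20 split (fixed by `seed`),
#' min-max scaling fitted on the training rows, 10-fold cross-validation on
#' the training split, a final fit, and test-set evaluation. The split is
#' shared across sets and models so results are comparable.
#'
#' @param feature_table Data frame from [extract_feature_table()] (46
#'   feature columns plus `label`).
#' @param seed Integer seed; expands into fixed per-stage seeds for the
#'   split, fold assignment, ensemble resampling and the BO search.
#' @param families Model families to run (default all twelve).
#' @param feature_sets Feature sets to run (default A, B, C).
#' @param bo_iter BO objective evaluations for the SVM (default 30).
#' @param cv_folds Cross-validation folds (default 10).
#' @return An `experiment_report`: list with `grid` (data frame: set,
#'   family, cv accuracy, Acc/Se/Sp/Ps/F1 and confusion counts),
#'   `predictions` (per set/family factor of test predictions), `split`,
#'   `seed`, `families`, `feature_sets`.
#' @export
run_experiment <- function(feature_table, seed = 1L,
                           families = model_families(),
                           feature_sets = c("A", "B", "C"),
                           bo_iter = 30L, cv_folds = 10L) {
  stopifnot(all(families %in% model_families()),
            all(feature_sets %in% c("A", "B", "C")))
  y <- feature_table$label
  X_all <- as.matrix(feature_table[, feature_set_names("C")])
  split <- split_dataset(X_all, y, test_frac = 0.2, seed = seed)

  grid <- list(); preds <- list()
  for (set in feature_sets) {
    nm <- feature_set_names(set)
    tr_X <- split$train_X[, nm, drop = FALSE]
    te_X <- split$test_X[, nm, drop = FALSE]
    for (fam in families) {
      model <- if (fam == "bo_svm") {
        bo_svm_train(tr_X, split$train_y, n_iter = bo_iter,
                     seed = seed + 101L, cv_folds = cv_folds)
      } else {
        train_baseline(fam, tr_X, split$train_y, seed = seed + 202L,
                       cv_folds = cv_folds)
      }
      m <- evaluate_model(model, te_X, split$test_y)
      key <- paste(set, fam, sep = ".")
      preds[[key]] <- predict(model, te_X)
      grid[[key]] <- data.frame(
        feature_set = set, family = fam, cv_accuracy = model$cv_score,
        Acc = m$Acc, Se = m$Se, Sp = m$Sp, Ps = m$Ps, F1 = m$F1,
        TP = m$TP, FN = m$FN, TN = m$TN, FP = m$FP)
    }
  }
  structure(list(grid = do.call(rbind, c(grid, make.row.names = FALSE)),
                 predictions = preds, split = split, seed = seed,
                 families = families, feature_sets = feature_sets),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> seed", x$seed, "\n")
  g <- x$grid
  g[, c("cv_accuracy", "Acc", "Se", "Sp", "Ps", "F1")] <-
    round(g[, c("cv_accuracy", "Acc", "Se", "Sp", "Ps", "F1")], 4)
  print(g[, c("feature_set", "family", "cv_accuracy", "Acc", "Se", "Sp",
              "Ps", "F1")], row.names = FALSE)
  invisible(x)
}
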