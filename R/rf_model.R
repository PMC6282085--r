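#' Stratified train/test split of a predictor table
#'
#' Splits a per-species predictor table into training and test sets,
#' stratified by the binary label so both sets preserve the class ratio to
#' within one species per class. Reproducible under `seed`.
#'
#' @param table Data.frame with a `label` column
#'   (`"threatened"`/`"not_threatened"`) and predictor columns.
#' @param train_fraction Fraction assigned to training (default 0.75); must
#'   leave both sets non-empty.
#' @param seed Integer seed.
#' @return List with `train` and `test` data.frames.
#' @export
split_train_test <- function(table, train_fraction = 0.75, seed = 1) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  if (nrow(table) < 8) stop("need at least 8 rows to split")
  classes <- unique(table$label)
  if (length(classes) < 2) stop("both classes must be present to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1): both sets must be non-empty")
  }
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in sort(classes)) {
    idx <- which(table$label == cl)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1), length(idx) - 1)  # keep both sets populated per class
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[-train_idx, , drop = FALSE])
}

# Encode categorical predictors as target-agnostic integer codes (sorted
# level order) and median-impute missing numeric values. Encoders/medians
# are learned from the supplied data only, so applying this inside a CV
# fold keeps the fold leak-free.
.make_encoder <- function(data, predictors) {
  levels_map <- list()
  medians <- list()
  for (p in predictors) {
    v <- data[[p]]
    if (is.character(v) || is.factor(v)) {
      levels_map[[p]] <- sort(unique(as.character(v[!is.na(v)])))
    }
  }
  enc <- list(levels_map = levels_map)
  X <- .apply_encoder_raw(data, predictors, enc)
  for (p in predictors) {
    med <- stats::median(X[[p]], na.rm = TRUE)
    medians[[p]] <- if (is.na(med)) 0 else med
  }
  enc$medians <- medians
  enc
}

.apply_encoder_raw <- function(data, predictors, enc) {
  X <- data[, predictors, drop = FALSE]
  for (p in names(enc$levels_map)) {
    X[[p]] <- match(as.character(X[[p]]), enc$levels_map[[p]])
  }
  for (p in predictors) X[[p]] <- as.numeric(X[[p]])
  X
}

.apply_encoder <- function(data, predictors, enc) {
  X <- .apply_encoder_raw(data, predictors, enc)
  for (p in predictors) {
    miss <- !is.finite(X[[p]])
    if (any(miss)) X[[p]][miss] <- enc$medians[[p]]
  }
  X
}

#' Fit a random forest to a predictor table
#'
#' Thin wrapper around [randomForest::randomForest()] that adds the
#' encoding and imputation contract used throughout the package:
#' categorical predictors become target-agnostic integer codes (persisted
#' with the fit), missing numerics are median-imputed with medians learned
#' from the supplied data only, and the forest is grown with `keep.inbag`
#' so out-of-bag permutation importance can be computed afterwards.
#'
#' @param train Data.frame with `label` plus predictors (a `species_id`
#'   column is carried along but never used as a predictor).
#' @param mtry Predictors tried per split.
#' @param nodesize Minimum terminal node size.
#' @param ntree Number of trees (default 500).
#' @param seed Integer seed.
#' @return An `rf_fit` list: `model`, `encoder`, `predictors`, `params`.
#' @export
rf_fit <- function(train, mtry = 4, nodesize = 5, ntree = 500, seed = 1) {
  stopifnot("label" %in% names(train))
  predictors <- setdiff(names(train), c("label", "species_id"))
  if (length(predictors) == 0) stop("no predictor columns")
  mtry <- min(mtry, length(predictors))
  enc <- .make_encoder(train, predictors)
  X <- .apply_encoder(train, predictors, enc)
  y <- factor(train$label, levels = c("not_threatened", "threatened"))
  if (any(is.na(y))) stop("labels must be threatened/not_threatened")
  set.seed(seed)
  model <- randomForest::randomForest(
    x = X, y = y, ntree = ntree, mtry = mtry, nodesize = nodesize,
    keep.inbag = TRUE, keep.forest = TRUE)
  structure(list(model = model, encoder = enc, predictors = predictors,
                 X = X, y = y,
                 params = list(mtry = mtry, nodesize = nodesize,
                               ntree = ntree, seed = seed)),
            class = "rf_fit")
}

#' Predict threat status with a fitted random forest
#'
#' @param fit An `rf_fit` object.
#' @param newdata Data.frame with the fit's predictor columns.
#' @param type `"prob"` for the probability of the threatened class,
#'   `"class"` for hard labels.
#' @return Numeric vector of threat probabilities, or character labels.
#' @export
predict_rf <- function(fit, newdata, type = c("prob", "class")) {
  type <- match.arg(type)
  X <- .apply_encoder(newdata, fit$predictors, fit$encoder)
  if (type == "prob") {
    unname(stats::predict(fit$model, X, type = "prob")[, "threatened"])
  } else {
    as.character(stats::predict(fit$model, X, type = "response"))
  }
}

#' Default hyperparameter grid for random-forest tuning
#'
#' A small, documented grid — 500 trees, 2/4/8 variables per split, minimum
#' node sizes 1 and 5 — sized for desk-scale reruns of the whole protocol.
#'
#' @return Data.frame with columns `mtry`, `nodesize`.
#' @export
rf_default_grid <- function() {
  expand.grid(mtry = c(2, 4, 8), nodesize = c(1, 5))
}

#' Tune a random forest by repeated cross-validation on ROC area
#'
#' The supervised-learning protocol: the training set is split into
#' `cv_folds` stratified folds, repeated `cv_repeats` times; every
#' hyperparameter combination in `grid` is scored by the mean area under
#' the ROC curve over all held-out folds; the best combination is refitted
#' on the full training set. Encoding and imputation are re-learned inside
#' every fold, so no information leaks from the held-out part. A fold whose
#' training part loses a class is resampled with a warning (only possible
#' for tiny or extremely imbalanced training sets).
#'
#' @param train Training data.frame (`label` + predictors).
#' @param cv_folds Folds per repeat (default 10).
#' @param cv_repeats Repeats (default 5).
#' @param grid Hyperparameter data.frame (`mtry`, `nodesize`), default
#'   [rf_default_grid()].
#' @param ntree Trees per forest (default 500).
#' @param seed Integer seed controlling folds and fits.
#' @return List: `fit` (the refitted `rf_fit`), `best` (chosen row of the
#'   grid with its mean AUC), `tuning` (full trace: one row per grid row
#'   with mean AUC).
#' @export
tune_and_fit <- function(train, cv_folds = 10, cv_repeats = 5,
                         grid = rf_default_grid(), ntree = 500, seed = 1) {
  stopifnot("label" %in% names(train), nrow(grid) >= 1)
  y_all <- factor(train$label, levels = c("not_threatened", "threatened"))
  if (nlevels(droplevels(y_all)) < 2) stop("both classes must be present")
  set.seed(seed)
  # stratified fold assignments per repeat
  folds <- lapply(seq_len(cv_repeats), function(r) {
    f <- integer(nrow(train))
    for (cl in levels(y_all)) {
      idx <- which(y_all == cl)
      f[idx] <- sample(rep(seq_len(cv_folds), length.out = length(idx)))
    }
    f
  })
  auc_mat <- matrix(NA_real_, nrow = nrow(grid), ncol = cv_repeats * cv_folds)
  col <- 0
  for (r in seq_len(cv_repeats)) {
    for (k in seq_len(cv_folds)) {
      col <- col + 1
      hold <- folds[[r]] == k
      if (nlevels(droplevels(y_all[!hold])) < 2 || !any(hold)) {
        warning("degenerate fold resampled (single-class training part)")
        redo <- sample(nrow(train))
        hold <- redo <= max(1, floor(nrow(train) / cv_folds))
      }
      tr <- train[!hold, , drop = FALSE]
      te <- train[hold, , drop = FALSE]
      for (g in seq_len(nrow(grid))) {
        fit_g <- rf_fit(tr, mtry = grid$mtry[g], nodesize = grid$nodesize[g],
                        ntree = ntree, seed = seed + 1000 * g + col)
        prob <- predict_rf(fit_g, te, type = "prob")
        auc_mat[g, col] <- .roc_auc(te$label, prob)
      }
    }
  }
  tuning <- cbind(grid, mean_auc = rowMeans(auc_mat, na.rm = TRUE))
  best_g <- which.max(tuning$mean_auc)
  fit <- rf_fit(train, mtry = grid$mtry[best_g], nodesize = grid$nodesize[best_g],
                ntree = ntree, seed = seed)
  list(fit = fit, best = tuning[best_g, , drop = FALSE], tuning = tuning)
}

# AUC of threat probability against the binary label; NA when the held-out
# fold has a single class (dropped from the fold mean).
.roc_auc <- function(label, prob) {
  y <- factor(label, levels = c("not_threatened", "threatened"))
  if (nlevels(droplevels(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                 levels = c("not_threatened", "threatened"),
                                 direction = "<", quiet = TRUE)))
}

#' Held-out ROC area of a fitted forest
#'
#' @param fit An `rf_fit`.
#' @param test Data.frame with `label` and predictors.
#' @return AUC in `[0, 1]`.
#' @export
rf_test_auc <- function(fit, test) {
  .roc_auc(test$label, predict_rf(fit, test, type = "prob"))
}

#' Out-of-bag permutation importance (mean decrease in accuracy)
#'
#' For every predictor: permute its values, re-predict with each tree, and
#' measure the drop in that tree's accuracy on its own out-of-bag samples;
#' the importance is the mean drop over trees and permutation replicates.
#' This is the classic forest importance measure, computed here directly
#' from the kept in-bag matrix so the procedure is explicit and testable.
#' An uninformative predictor scores near zero; predictors the forest
#' relies on score their accuracy cost.
#'
#' @param fit An `rf_fit` (grown with `keep.inbag`, as [rf_fit()] does).
#' @param n_reps Permutation replicates per predictor (default 3).
#' @param seed Integer seed for the permutations.
#' @return Data.frame sorted by decreasing importance: `predictor`,
#'   `mean_decrease_accuracy`.
#' @export
permutation_importance <- function(fit, n_reps = 3, seed = 1) {
  stopifnot(inherits(fit, "rf_fit"))
  X <- fit$X
  y <- as.character(fit$y)
  oob <- fit$model$inbag == 0           # n x ntree
  n_oob <- colSums(oob)
  pred_all <- stats::predict(fit$model, X, predict.all = TRUE)$individual
  base_acc <- colSums((pred_all == y) * oob) / n_oob
  set.seed(seed)
  imp <- vapply(fit$predictors, function(p) {
    drops <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      Xp <- X
      Xp[[p]] <- X[[p]][sample(nrow(X))]
      pred_p <- stats::predict(fit$model, Xp, predict.all = TRUE)$individual
      perm_acc <- colSums((pred_p == y) * oob) / n_oob
      drops[r] <- mean(base_acc - perm_acc)
    }
    mean(drops)
  }, numeric(1))
  out <- data.frame(predictor = fit$predictors,
                    mean_decrease_accuracy = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_decrease_accuracy), ]
  rownames(out) <- NULL
  out
}
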