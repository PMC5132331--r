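#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP))`. When any
#' factor of the MCC denominator is zero (e.g. a degenerate classifier
#' predicting a single class) the MCC is defined as 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts. Alternatively pass
#'   a list/vector with named elements via `tp`.
#' @return List with elements `acc`, `se`, `sp`, `mcc`.
#' @export
compute_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn) && (is.list(tp) || length(tp) == 4L)) {
    counts <- tp
    tp <- counts[["tp"]]; tn <- counts[["tn"]]
    fp <- counts[["fp"]]; fn <- counts[["fn"]]
  }
  total <- tp + tn + fp + fn
  if (total <= 0) stop("no evaluated instances")
  acc <- (tp + tn) / total
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  mcc <- if (denom == 0) 0 else {
    (tp * tn - fp * fn) / sqrt(denom)
  }
  list(acc = acc, se = se, sp = sp, mcc = mcc)
}

#' Train a random-forest classifier
#'
#' Thin wrapper around [randomForest::randomForest()] with the
#' method's default hyperparameters: 1000 trees and 20 candidate
#' features per split (clamped to the feature count when fewer are
#' available). Training is deterministic given `seed`.
#'
#' @param features Numeric feature data frame.
#' @param labels Class labels (`"positive"`/`"negative"` or a factor).
#' @param ntree Number of trees.
#' @param mtry Candidate features per split; default `min(20, p)`.
#' @param seed Integer seed.
#' @return Object of class `dnabind_model` wrapping the fitted forest
#'   and the training feature names.
#' @export
train_rf <- function(features, labels, ntree = 1000L, mtry = NULL,
                     seed = 1L) {
  features <- as.data.frame(features)
  labels <- as_class_factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training requires both classes to be present")
  }
  if (is.null(mtry)) mtry <- min(20L, ncol(features))
  if (mtry > ncol(features)) mtry <- ncol(features)
  set.seed(seed)
  fit <- randomForest::randomForest(x = features, y = labels,
                                    ntree = ntree, mtry = mtry)
  structure(list(forest = fit, feature_names = names(features),
                 ntree = ntree, mtry = mtry, seed = seed),
            class = "dnabind_model")
}

as_class_factor <- function(labels) {
  if (is.factor(labels)) {
    if (!setequal(levels(labels), c("negative", "positive"))) {
      labels <- factor(as.character(labels),
                       levels = c("negative", "positive"))
    }
  } else {
    labels <- factor(as.character(labels),
                     levels = c("negative", "positive"))
  }
  if (anyNA(labels)) stop("labels must be 'positive' or 'negative'")
  labels
}

#' Stratified k-fold cross-validation of the random forest
#'
#' Rows are split per class into `folds` random parts (sizes differing
#' by at most one within a class); each fold in turn is held out, a
#' forest is trained on the remainder and the held-out confusion counts
#' recorded. Aggregate metrics are computed from the pooled confusion
#' counts; per-fold metric means are also reported. Deterministic given
#' `seed`.
#'
#' @param features Numeric feature data frame.
#' @param labels Class labels.
#' @param folds Number of folds (each class must have at least this
#'   many members).
#' @param ntree,mtry Forest hyperparameters, as in [train_rf()].
#' @param seed Integer seed for fold assignment and training.
#' @return Object of class `metric_report`: list with pooled `acc`,
#'   `se`, `sp`, `mcc`, a `fold_mean` list of per-fold metric averages,
#'   and `per_fold` (data frame of per-fold confusion counts).
#' @export
cross_validate <- function(features, labels, folds = 5L, ntree = 1000L,
                           mtry = NULL, seed = 1L) {
  features <- as.data.frame(features)
  labels <- as_class_factor(labels)
  counts <- table(labels)
  if (any(counts < folds)) {
    stop("each class needs at least ", folds, " members for ", folds,
         "-fold cross-validation")
  }
  set.seed(seed)
  fold_of <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  per_fold <- data.frame(fold = seq_len(folds), tp = 0L, tn = 0L,
                         fp = 0L, fn = 0L)
  for (f in seq_len(folds)) {
    test <- fold_of == f
    model <- train_rf(features[!test, , drop = FALSE], labels[!test],
                      ntree = ntree, mtry = mtry,
                      seed = seed + f)
    pred <- predict_binding(model, features[test, , drop = FALSE])$class
    truth <- labels[test]
    per_fold$tp[f] <- sum(pred == "positive" & truth == "positive")
    per_fold$tn[f] <- sum(pred == "negative" & truth == "negative")
    per_fold$fp[f] <- sum(pred == "positive" & truth == "negative")
    per_fold$fn[f] <- sum(pred == "negative" & truth == "positive")
  }

  pooled <- compute_metrics(sum(per_fold$tp), sum(per_fold$tn),
                            sum(per_fold$fp), sum(per_fold$fn))
  fold_metrics <- lapply(seq_len(folds), function(f) {
    compute_metrics(per_fold$tp[f], per_fold$tn[f], per_fold$fp[f],
                    per_fold$fn[f])
  })
  fold_mean <- lapply(c(acc = "acc", se = "se", sp = "sp", mcc = "mcc"),
                      function(m) {
                        mean(vapply(fold_metrics, `[[`, numeric(1L), m))
                      })
  structure(c(pooled, list(fold_mean = fold_mean, per_fold = per_fold)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "cross-validation (pooled): ACC %.4f  SE %.4f  SP %.4f  MCC %.3f\n",
    x$acc, x$se, x$sp, x$mcc))
  invisible(x)
}

#' Per-feature two-sample t-test between classes
#'
#' For every feature, a two-sided two-sample t-test of positive against
#' negative rows; Welch's unequal-variance form by default. Features
#' constant within both classes get p = 1 when the class means agree
#' (no evidence of separation) and p = 0 otherwise, with a warning.
#'
#' @param features Numeric feature data frame.
#' @param labels Class labels.
#' @param var_equal Use the pooled-variance (Student) form instead of
#'   Welch's.
#' @return Named numeric vector of p-values in \[0, 1\].
#' @export
feature_ttest <- function(features, labels, var_equal = FALSE) {
  features <- as.data.frame(features)
  labels <- as_class_factor(labels)
  pos <- labels == "positive"
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    stop("both classes need at least 2 rows")
  }
  degenerate <- character(0)
  out <- vapply(names(features), function(nm) {
    a <- features[[nm]][pos]
    b <- features[[nm]][!pos]
    if (sd(a) == 0 && sd(b) == 0) {
      degenerate <<- c(degenerate, nm)
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    t.test(a, b, var.equal = var_equal)$p.value
  }, numeric(1L))
  if (length(degenerate)) {
    warning("zero within-class variance for: ",
            paste(degenerate, collapse = ", "))
  }
  out
}
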