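# Evaluation protocol: confusion counts with fall as the positive class,
# sensitivity/specificity, stratified k-fold cross-validation, and ROC
# construction from ensemble margins.

#' Confusion counts
#'
#' Pairwise tally of true vs predicted labels. For the binary summary, `TP`
#' is the number of falls correctly identified, `FN` the falls missed, `TN`
#' the no-falls correctly identified and `FP` the no-falls missed (any
#' non-positive class counts as negative, which also gives the one-vs-rest
#' view for the 3-class task). The full per-class matrix is kept alongside.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive the positive class (default `"fall"`).
#' @return object of class `confusion_counts`: fields `TP`, `FN`, `TN`,
#'   `FP`, `table` (true in rows, predicted in columns), `positive`.
#' @export
confusion <- function(y_true, y_pred, positive = "fall") {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  levels <- sort(unique(c(y_true, y_pred)))
  tab <- table(factor(y_true, levels), factor(y_pred, levels))
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  structure(list(TP = tp, FN = fn, TN = tn, FP = fp,
                 table = tab, positive = positive),
            class = "confusion_counts")
}

#' Sensitivity (fall hit rate)
#'
#' `TP / (TP + FN)`: the fraction of true falls the system identifies.
#'
#' @param c a `confusion_counts`.
#' @return fraction in `[0, 1]`, or `NA` (with a warning) when there are no
#'   positive samples.
#' @export
sensitivity <- function(c) {
  if (c$TP + c$FN == 0) {
    warning("no positive samples: sensitivity undefined")
    return(NA_real_)
  }
  c$TP / (c$TP + c$FN)
}

#' Specificity (no-fall correct-rejection rate)
#'
#' `TN / (TN + FP)`. (Note: one published formulation of this quantity
#' prints TP in the numerator, which is not a specificity and can exceed 1;
#' the standard definition is used here.)
#'
#' @param c a `confusion_counts`.
#' @return fraction in `[0, 1]`, or `NA` (with a warning) when there are no
#'   negative samples.
#' @export
specificity <- function(c) {
  if (c$TN + c$FP == 0) {
    warning("no negative samples: specificity undefined")
    return(NA_real_)
  }
  c$TN / (c$TN + c$FP)
}

#' Overall accuracy
#'
#' Fraction of correctly classified samples; equals
#' `(TP + TN) / (TP + TN + FP + FN)` for the 2-class task.
#'
#' @param c a `confusion_counts`.
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(c) {
  sum(diag(c$table)) / sum(c$table)
}

#' Stratified k-fold cross-validation of a boosted ensemble
#'
#' Samples of each class are assigned to folds by a seeded stratified
#' shuffle; each fold is held out in turn, the classifier trained on the
#' rest, and the held-out predictions pooled into a single confusion matrix.
#'
#' @param X numeric matrix of feature vectors.
#' @param y class labels; each class must have at least `folds` samples.
#' @param folds number of folds (default 10).
#' @param trainer list of arguments for [train_boosted()]: `base`, `rounds`,
#'   `max_depth`, `min_leaf`.
#' @param seed integer seed for the fold assignment.
#' @param positive positive class for the binary metrics.
#' @return object of class `cv_report`: pooled `confusion`, `accuracy`,
#'   `sensitivity`/`specificity` (2-class), per-fold accuracies, pooled
#'   `margins` and ROC points/AUC (2-class), and the fold assignment.
#' @export
kfold_cv <- function(X, y, folds = 10L,
                     trainer = list(base = "tree", rounds = 10L,
                                    max_depth = Inf, min_leaf = 1L),
                     seed = 1L, positive = "fall") {
  X <- as.matrix(X)
  y <- as.character(y)
  if (folds < 2L) stop("folds must be >= 2")
  counts <- table(y)
  if (any(counts < folds))
    stop("class(es) with fewer samples than folds: ",
         paste(names(counts)[counts < folds], collapse = ", "))

  n <- nrow(X)
  fold_id <- integer(n)
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(y == cl)
      fold_id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })

  pred <- character(n)
  margin <- rep(NA_real_, n)
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    ens <- train_boosted(X[!test, , drop = FALSE], y[!test],
                         K = trainer$rounds %||% 10L,
                         base = trainer$base %||% "tree",
                         max_depth = trainer$max_depth %||% Inf,
                         min_leaf = trainer$min_leaf %||% 1L,
                         positive = if (positive %in% y[!test]) positive)
    p <- predict(ens, X[test, , drop = FALSE])
    pred[test] <- p$label
    margin[test] <- p$margin
    fold_acc[f] <- mean(p$label == y[test])
  }

  cm <- confusion(y, pred, positive = positive)
  two_class <- length(unique(y)) == 2L
  roc <- if (two_class && positive %in% y && !all(is.na(margin)))
    roc_points(margin, y, positive = positive)
  structure(list(
    confusion = cm,
    accuracy = accuracy(cm),
    sensitivity = if (two_class) sensitivity(cm) else NA_real_,
    specificity = if (two_class) specificity(cm) else NA_real_,
    fold_accuracy = fold_acc,
    fold_id = fold_id,
    predictions = pred,
    margins = margin,
    roc = roc,
    auc = if (!is.null(roc)) roc_auc_from_points(roc),
    folds = folds,
    trainer = trainer,
    seed = seed,
    positive = positive),
    class = "cv_report")
}

#' ROC points from classifier margins
#'
#' Standard threshold sweep over the distinct margin values, most confident
#' first; tied margins move together. Points run from (0, 0) to (1, 1) and
#' are monotone non-decreasing in both coordinates.
#'
#' @param margins numeric scores (larger = more positive).
#' @param y_true labels.
#' @param positive the positive class.
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(margins, y_true, positive = "fall") {
  y_true <- as.character(y_true)
  is_pos <- y_true == positive
  P <- sum(is_pos); N <- sum(!is_pos)
  if (P == 0L || N == 0L)
    stop("ROC needs at least one positive and one negative sample")
  ord <- order(margins, decreasing = TRUE)
  tp <- cumsum(is_pos[ord])
  fp <- cumsum(!is_pos[ord])
  # keep only the last point of each tie group
  last <- c(diff(margins[ord]) != 0, TRUE)
  data.frame(fpr = c(0, fp[last] / N), tpr = c(0, tp[last] / P))
}

roc_auc_from_points <- function(pts) {
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_points()]; equals the pairwise concordance
#' probability `P(margin+ > margin-) + 0.5 P(tie)`.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(margins, y_true, positive = "fall") {
  roc_auc_from_points(roc_points(margins, y_true, positive))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s, %d round(s))\n",
              x$folds, x$trainer$base %||% "tree", x$trainer$rounds %||% 10L))
  cat(sprintf("  accuracy:    %.4f\n", x$accuracy))
  if (!is.na(x$sensitivity))
    cat(sprintf("  sensitivity: %.4f\n  specificity: %.4f\n",
                x$sensitivity, x$specificity))
  if (!is.null(x$auc)) cat(sprintf("  ROC AUC:     %.4f\n", x$auc))
  cat("  confusion (true rows x predicted columns):\n")
  print(x$confusion$table)
  invisible(x)
}
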