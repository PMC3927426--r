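#' Train a Gaussian-kernel soft-margin SVM syllable classifier
#'
#' Labels sound-event feature summaries (introductory notes, syllables,
#' cage noise, ...) with a radial-basis-function support vector machine.
#' Features are z-scored on the training set; hyperparameters (`cost`,
#' `gamma`) are selected by grid search inside stratified k-fold
#' cross-validation, and the reported `cv_accuracy` is the CV accuracy of
#' the selected pair. Following the deployment criterion used for online
#' song detection, the model is flagged deployable only when its
#' cross-validated accuracy reaches `accuracy_floor` (98% by default).
#'
#' Rows are internally sorted into a canonical order (by label, then
#' feature values) before fold assignment, so permuting the training
#' examples leaves `cv_accuracy` exactly unchanged for a fixed `seed`.
#'
#' @param x `data.frame` or matrix of event summaries (e.g. the 11 feature
#'   columns of [summarize_events()]).
#' @param labels Class labels (>= 2 classes, >= `folds` examples each).
#' @param folds Number of stratified CV folds.
#' @param seed Integer seed for fold assignment.
#' @param cost_grid,gamma_scale_grid Hyperparameter grids; `gamma` values
#'   are `gamma_scale_grid / ncol(x)`.
#' @param accuracy_floor Deployment threshold on CV accuracy.
#' @return An object of class `syllable_classifier`: the fitted SVM,
#'   feature centers/scales, `cv_accuracy`, selected hyperparameters, and
#'   `deployable`.
#' @export
train_syllable_classifier <- function(x, labels, folds = 5, seed = 1,
                                      cost_grid = c(1, 10, 100),
                                      gamma_scale_grid = c(0.5, 1, 2),
                                      accuracy_floor = 0.98) {
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("training data must contain >= 2 classes")
  if (any(table(labels) < folds))
    stop("every class needs at least `folds` examples")
  keep_cols <- apply(x, 2, function(col) all(is.finite(col)))
  if (!any(keep_cols)) stop("no finite feature columns")
  x <- x[, keep_cols, drop = FALSE]

  # canonical row order: label then lexicographic feature values
  ord <- do.call(order, c(list(labels), lapply(seq_len(ncol(x)),
                                               function(j) x[, j])))
  x <- x[ord, , drop = FALSE]
  labels <- labels[ord]

  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  z <- scale(x, ctr, scl)

  set.seed(seed)
  fold_id <- integer(nrow(z))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  d <- ncol(z)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_scale_grid / d)
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- e1071::svm(z[tr, , drop = FALSE], labels[tr],
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE)
      pred <- predict(fit, z[!tr, , drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    correct / nrow(z)
  }, 0)
  best <- which.max(cv_acc)
  fit <- e1071::svm(z, labels, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best], scale = FALSE,
                    probability = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl,
                 feature_names = colnames(x), labels = levels(labels),
                 cv_accuracy = cv_acc[best], cv_grid = cbind(grid, cv_acc),
                 cost = grid$cost[best], gamma = grid$gamma[best],
                 folds = folds, seed = seed,
                 accuracy_floor = accuracy_floor,
                 deployable = cv_acc[best] >= accuracy_floor),
            class = "syllable_classifier")
}

#' @export
print.syllable_classifier <- function(x, ...) {
  cat("Gaussian-kernel SVM syllable classifier\n")
  cat("  classes:", paste(x$labels, collapse = ", "), "\n")
  cat(sprintf("  cv accuracy: %.1f%% (%d-fold, cost=%g, gamma=%.3g)\n",
              100 * x$cv_accuracy, x$folds, x$cost, x$gamma))
  cat("  deployable:", x$deployable,
      sprintf("(floor %.0f%%)\n", 100 * x$accuracy_floor))
  invisible(x)
}

#' Classify sound events with a trained classifier
#'
#' @param object A [train_syllable_classifier()] model.
#' @param newdata Event summaries with the training feature columns.
#' @param ... Unused.
#' @return `data.frame` with `label` and `margin` (difference between the
#'   aggregated pairwise decision values of the top two classes; its sign
#'   is consistent with the label in the two-class case).
#' @export
predict.syllable_classifier <- function(object, newdata, ...) {
  nd <- as.matrix(as.data.frame(newdata)[, object$feature_names,
                                         drop = FALSE])
  if (ncol(nd) != length(object$feature_names))
    stop("feature dimensionality mismatch")
  storage.mode(nd) <- "double"
  nd[!is.finite(nd)] <- 0
  z <- scale(nd, object$center, object$scale)
  pred <- predict(object$fit, z, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  lv <- object$labels
  # per-class aggregated decision score from pairwise decision values
  score <- matrix(0, nrow(z), length(lv), dimnames = list(NULL, lv))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    score[, pair[1]] <- score[, pair[1]] + dv[, cn]
    score[, pair[2]] <- score[, pair[2]] - dv[, cn]
  }
  margin <- apply(score, 1, function(s) {
    o <- sort(s, decreasing = TRUE)
    if (length(o) > 1) o[1] - o[2] else o[1]
  })
  if (length(lv) == 2) {
    # signed margin: positive for the first class level
    margin <- score[, 1] - score[, 2]
  }
  data.frame(label = as.character(pred), margin = as.numeric(margin))
}

#' Classify a single event summary
#'
#' Thin wrapper around [predict.syllable_classifier()] that enforces the
#' deployment gate used during online detection.
#'
#' @param model A `syllable_classifier`.
#' @param summary One-row event summary.
#' @param require_deployable Refuse classification if the model missed its
#'   CV accuracy floor.
#' @return List with `label` and `margin`.
#' @export
classify_event <- function(model, summary, require_deployable = TRUE) {
  stopifnot(inherits(model, "syllable_classifier"))
  if (require_deployable && !model$deployable)
    stop("classifier is not deployable (cv accuracy below floor)")
  p <- predict(model, summary)
  list(label = p$label[1], margin = p$margin[1])
}
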