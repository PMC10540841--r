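#' SVM configuration
#'
#' Defaults are the tuned hyper-parameters of the screening classifier:
#' soft-margin penalty C = 50, RBF kernel, gamma = 1e-5.
#'
#' @param C positive soft-margin penalty.
#' @param kernel one of `"rbf"`, `"linear"`, `"polynomial"`, `"sigmoid"`.
#' @param gamma positive kernel width parameter (RBF:
#'   `K(x, y) = exp(-gamma * ||x - y||^2)`).
#' @param seed integer seed.
#' @return object of class `svm_config`.
#' @export
svm_config <- function(C = 50, kernel = "rbf", gamma = 1e-5, seed = 1L) {
  kernel <- match.arg(kernel, c("rbf", "linear", "polynomial", "sigmoid"))
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  if (gamma <= 0 && kernel != "linear") {
    stop("gamma must be > 0", call. = FALSE)
  }
  structure(list(C = C, kernel = kernel, gamma = gamma,
                 seed = as.integer(seed)), class = "svm_config")
}

#' Class label from an NRS-2002 score
#'
#' The positive class is NRS-2002 < 3 (no nutritional risk); scores >= 3
#' form the negative class (at risk, i.e. flagged by the screening tool).
#'
#' @param nrs_score integer vector of scores in 0..5.
#' @return factor with levels `positive`, `negative`.
#' @export
nrs_class <- function(nrs_score) {
  stopifnot(all(nrs_score %in% 0:5))
  factor(ifelse(nrs_score < 3, "positive", "negative"),
         levels = c("positive", "negative"))
}

svm_kernel_name <- function(kernel) {
  c(rbf = "radial", linear = "linear", polynomial = "polynomial",
    sigmoid = "sigmoid")[[kernel]]
}

#' Train the soft-margin kernel SVM
#'
#' Fits a C-classification support vector machine on reduced feature
#' vectors (no further scaling is applied; features are expected to come
#' from the standardize + PCA stage). The quadratic program is solved by
#' libsvm via \pkg{e1071}.
#'
#' @param features numeric matrix, rows = samples.
#' @param labels factor as returned by [nrs_class()] (or any 2-level
#'   factor).
#' @param config an [svm_config()].
#' @param class_weights optional named weights per class (default none).
#' @return object of class `nrs_svm` wrapping the fitted model.
#' @importFrom e1071 svm
#' @export
train_svm <- function(features, labels, config = svm_config(),
                      class_weights = NULL) {
  labels <- as.factor(labels)
  if (any(!is.finite(features))) stop("non-finite features", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  set.seed(config$seed)
  fit <- e1071::svm(x = features, y = labels, scale = FALSE,
                    type = "C-classification",
                    kernel = svm_kernel_name(config$kernel),
                    cost = config$C, gamma = config$gamma,
                    class.weights = class_weights)
  structure(list(fit = fit, config = config, levels = levels(labels)),
            class = "nrs_svm")
}

#' @rdname train_svm
#' @param object a fitted `nrs_svm`.
#' @param newdata feature matrix to predict.
#' @param ... unused.
#' @export
predict.nrs_svm <- function(object, newdata, ...) {
  predict(object$fit, newdata)
}

#' Exhaustive hyper-parameter grid search by cross-validation
#'
#' Evaluates every row of `grid` by k-fold cross-validated accuracy and
#' returns the best configuration. Folds are assigned deterministically
#' from `seed`; ties break toward smaller C, then smaller gamma, then grid
#' order.
#'
#' @param features,labels as in [train_svm()].
#' @param grid data.frame with columns among `C`, `gamma`, `kernel`
#'   (missing columns take the [svm_config()] defaults).
#' @param folds number of cross-validation folds (>= 2, <= n).
#' @param seed integer seed for the fold assignment.
#' @return list with `config` (best [svm_config()]), `accuracy` (its CV
#'   accuracy) and `results` (the grid with a `cv_accuracy` column).
#' @export
grid_search <- function(features, labels, grid, folds = 5, seed = 1L) {
  labels <- as.factor(labels)
  n <- nrow(features)
  if (nrow(grid) == 0) stop("empty grid", call. = FALSE)
  if (folds < 2 || folds > n) {
    stop("folds must lie in [2, n_samples]", call. = FALSE)
  }
  if (!"C" %in% names(grid)) grid$C <- 50
  if (!"gamma" %in% names(grid)) grid$gamma <- 1e-5
  if (!"kernel" %in% names(grid)) grid$kernel <- "rbf"
  set.seed(as.integer(seed))
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    cfg <- svm_config(C = grid$C[g], gamma = grid$gamma[g],
                      kernel = grid$kernel[g], seed = seed)
    correct <- 0L
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      if (nlevels(droplevels(labels[tr])) < 2) return(NA_real_)
      m <- train_svm(features[tr, , drop = FALSE], labels[tr], cfg)
      pred <- predict(m, features[!tr, , drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    correct / n
  }, numeric(1))
  grid$cv_accuracy <- acc
  ord <- order(-acc, grid$C, grid$gamma, seq_len(nrow(grid)))
  best <- ord[1]
  list(config = svm_config(C = grid$C[best], gamma = grid$gamma[best],
                           kernel = grid$kernel[best], seed = seed),
       accuracy = acc[best], results = grid)
}

#' Confusion counts
#'
#' Tallies TP/TN/FP/FN with the screening convention that `positive` means
#' NRS-2002 < 3.
#'
#' @param truth,pred factors (or vectors coercible to the same levels) of
#'   equal, positive length.
#' @param positive label of the positive class.
#' @return named list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(truth, pred, positive = "positive") {
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  tpos <- truth == positive
  ppos <- pred == positive
  list(TP = sum(tpos & ppos), TN = sum(!tpos & !ppos),
       FP = sum(!tpos & ppos), FN = sum(tpos & !ppos))
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/total, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R). A metric whose denominator is zero is reported as `NA`
#' (undefined) rather than 0.
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN` (see [confusion()]).
#' @return named list `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    total <- TP + TN + FP + FN
    if (total == 0) stop("all-zero confusion counts", call. = FALSE)
    precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
    recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    list(accuracy = (TP + TN) / total, precision = precision,
         recall = recall, f1 = f1)
  })
}
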