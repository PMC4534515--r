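#' Classification accuracy from confusion counts
#'
#' `accuracy(TP, FP, TN, FN) = (TP + TN) / (TP + TN + FP + FN)`, with TP the
#' correctly classified actives and TN the correctly classified inactives.
#'
#' @param counts A [confusion_counts()] object.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' classification_accuracy(confusion_counts(tp = 8, fp = 2, tn = 7, fn = 3))
#' @export
classification_accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total < 1) stop("accuracy undefined for all-zero counts", call. = FALSE)
  (counts$tp + counts$tn) / total
}

#' @rdname classification_accuracy
#' @param tp,fp,tn,fn Non-negative integer counts of true positives, false
#'   positives, true negatives, and false negatives.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  for (v in list(tp, fp, tn, fn)) {
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}

# Internal: confusion counts of predicted vs true labels (+1 = active).
count_confusion <- function(truth, predicted) {
  confusion_counts(tp = sum(truth == 1L & predicted == 1L),
                   fp = sum(truth == -1L & predicted == 1L),
                   tn = sum(truth == -1L & predicted == -1L),
                   fn = sum(truth == 1L & predicted == -1L))
}

# Internal: deterministic stratified fold assignment.  Within each class the
# row indices are permuted under `fold_seed` and dealt round-robin, so the
# assignment is a pure function of (fold_seed, labels).
make_stratified_folds <- function(labels, n_folds, fold_seed) {
  folds <- integer(length(labels))
  withr::with_seed(as.integer(fold_seed), {
    for (cls in c(-1L, 1L)) {
      idx <- which(labels == cls)
      if (length(idx) < n_folds)
        stop("each class needs at least `n_folds` members for stratified CV",
             call. = FALSE)
      folds[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

# Internal: one RBF-SVM fit.  Training (the weight-vector optimization) is
# delegated to libsvm via e1071; `scale = FALSE` because bits are already 0/1.
fit_rbf_svm <- function(features, labels, point) {
  e1071::svm(x = features,
             y = factor(labels, levels = c(-1L, 1L)),
             type = "C-classification", kernel = "radial",
             cost = hp_C(point), gamma = hp_gamma(point),
             scale = FALSE)
}

#' Cross-validated SVM accuracy objective
#'
#' Constructs the black-box objective `f(lambda)`: the mean stratified
#' k-fold cross-validated accuracy of an RBF-kernel SVM trained at
#' hyperparameters `lambda = (C, gamma)` on `dataset`.  The fold assignment
#' is frozen at construction (a deterministic function of `fold_seed` and the
#' labels), so every strategy run against one objective instance is compared
#' on identical splits and repeated evaluation at one `lambda` returns the
#' identical value.  Values are cached by `lambda` rounded to 12 decimals in
#' log10 coordinates; `eval_count(obj)` counts distinct solver evaluations.
#'
#' @param dataset An `fp_dataset` with at least `n_folds` members per class.
#' @param n_folds Number of CV folds (default 5, stratified).
#' @param fold_seed Integer seed fixing the fold assignment.
#' @return An object of class `svm_objective`.
#' @seealso [evaluate_point()], [eval_count()], [final_evaluate()]
#' @export
svm_objective <- function(dataset, n_folds = 5L, fold_seed = 1L) {
  stopifnot(inherits(dataset, "fp_dataset"))
  if (!is.numeric(n_folds) || n_folds < 2)
    stop("`n_folds` must be >= 2", call. = FALSE)
  n_folds <- as.integer(n_folds)
  folds <- make_stratified_folds(dataset$labels, n_folds, fold_seed)
  state <- new.env(parent = emptyenv())
  state$cache <- new.env(parent = emptyenv(), hash = TRUE)
  state$eval_count <- 0L
  structure(
    list(dataset = dataset, n_folds = n_folds,
         fold_seed = as.integer(fold_seed), folds = folds, state = state),
    class = "svm_objective"
  )
}

#' Evaluate an objective at a hyperparameter point
#'
#' Generic evaluation contract shared by the CV objective and the analytic
#' benchmark surfaces: strategies see an objective only through
#' `evaluate_point(obj, point)` and the search-space box.
#'
#' @param obj An objective (e.g. from [svm_objective()] or
#'   [analytic_objective()]).
#' @param point A [hyperparam_point()].
#' @param ... Passed to methods.
#' @return The objective value in `[0, 1]`.
#' @export
evaluate_point <- function(obj, point, ...) UseMethod("evaluate_point")

# Cache key: log10 coordinates rounded to 12 decimals (EI maximization can
# re-propose near-duplicates).
point_cache_key <- function(point) {
  sprintf("%.12f|%.12f", round(point$log10_C, 12), round(point$log10_gamma, 12))
}

#' @export
evaluate_point.svm_objective <- function(obj, point, ...) {
  stopifnot(inherits(point, "hyperparam_point"))
  key <- point_cache_key(point)
  st <- obj$state
  hit <- get0(key, envir = st$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  accs <- numeric(obj$n_folds)
  for (k in seq_len(obj$n_folds)) {
    train <- obj$folds != k
    fit <- fit_rbf_svm(obj$dataset$features[train, , drop = FALSE],
                       obj$dataset$labels[train], point)
    pred <- as.integer(as.character(
      stats::predict(fit, obj$dataset$features[!train, , drop = FALSE])))
    accs[k] <- classification_accuracy(
      count_confusion(obj$dataset$labels[!train], pred))
  }
  val <- mean(accs)
  assign(key, val, envir = st$cache)
  st$eval_count <- st$eval_count + 1L
  val
}

#' @rdname svm_objective
#' @param obj An `svm_objective`.
#' @param point A [hyperparam_point()].
#' @export
cv_accuracy <- function(obj, point) evaluate_point(obj, point)

#' @rdname svm_objective
#' @export
eval_count <- function(obj) obj$state$eval_count

#' Train on one dataset and evaluate accuracy on another
#'
#' Fits a single RBF-SVM at `point` on all of `train` and returns its
#' accuracy on `test`.  This is the outer hold-out alternative to reporting
#' the inner cross-validated value at the selected hyperparameters.
#'
#' @param train,test `fp_dataset` objects sharing the same bit length.
#' @param point A [hyperparam_point()].
#' @return Accuracy on `test`, in `[0, 1]`.
#' @export
final_evaluate <- function(train, test, point) {
  stopifnot(inherits(train, "fp_dataset"), inherits(test, "fp_dataset"))
  if (train$d != test$d)
    stop("train and test differ in fingerprint length (", train$d, " vs ",
         test$d, ")", call. = FALSE)
  if (nrow(test$features) == 0L) stop("test set is empty", call. = FALSE)
  fit <- fit_rbf_svm(train$features, train$labels, point)
  pred <- as.integer(as.character(stats::predict(fit, test$features)))
  classification_accuracy(count_confusion(test$labels, pred))
}
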