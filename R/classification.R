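#' Classifier specification
#'
#' The four supervised classifiers with their tuned hyperparameters:
#' polynomial-kernel SVM (`C = 1`, degree 3), RBF SVM (`C = 1`,
#' `gamma = 0.01`), k-nearest neighbours (`k = 5`, Euclidean distance) and
#' random forest (tree depth 8, 55 trees, square-root feature subsampling).
#'
#' @param kind One of `"svm_poly"`, `"svm_rbf"`, `"knn"`, `"rfc"`.
#' @param C Regularization parameter (SVMs).
#' @param gamma RBF kernel width (`svm_rbf` only).
#' @param k Neighbour count (`knn` only).
#' @param max_depth,n_estimators Tree depth and count (`rfc` only).
#' @return An object of class `classifier_spec`.
#' @examples
#' classifier_spec("svm_rbf")
#' @export
classifier_spec <- function(kind = c("svm_poly", "svm_rbf", "knn", "rfc"),
                            C = 1, gamma = 0.01, k = 5,
                            max_depth = 8, n_estimators = 55) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    svm_poly = list(kind = kind, C = C, degree = 3),
    svm_rbf = list(kind = kind, C = C, gamma = gamma),
    knn = list(kind = kind, k = as.integer(k), distance = "euclidean"),
    rfc = list(kind = kind, max_depth = as.integer(max_depth),
               n_estimators = as.integer(n_estimators)))
  structure(spec, class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat(sprintf("classifier %s (%s)\n", x$kind,
              paste(names(pars), unlist(pars), sep = "=", collapse = ", ")))
  invisible(x)
}

default_classifiers <- function() {
  lapply(c("svm_poly", "svm_rbf", "knn", "rfc"), classifier_spec)
}

as_feature_matrix <- function(features) {
  X <- if (is.matrix(features)) features else do.call(rbind, features)
  if (ncol(X) != 24)
    stop("feature vectors must have exactly 24 entries, got ", ncol(X))
  if (any(!is.finite(X))) {
    bad <- which(rowSums(!is.finite(X)) > 0)
    nm <- rownames(X)[bad[1]]
    stop("non-finite feature value in row ",
         if (is.null(nm) || is.na(nm)) bad[1] else nm)
  }
  X
}

#' Fit a classifier on 24-feature vectors
#'
#' Features are standardized (z-score fitted on the training set; constant
#' dimensions get unit scale) before any distance- or margin-based learner
#' sees them; the standardizer is stored and re-applied at prediction time.
#' SVMs use [e1071::svm()] with internal scaling disabled, kNN is a lazy
#' learner (the standardized training set is stored), and the random forest
#' is a [ranger::ranger()] with `max.depth` and square-root `mtry`.
#'
#' @param features n x 24 matrix or list of named feature vectors.
#' @param labels Integer labels, 0 = benign, 1 = malignant.
#' @param spec A [classifier_spec()].
#' @param seed Integer seed (controls tree randomness; SVM and kNN fits are
#'   deterministic).
#' @return An object of class `cenbi_model`.
#' @export
fit_classifier <- function(features, labels, spec = classifier_spec("svm_rbf"),
                           seed = 1L) {
  X <- as_feature_matrix(features)
  y <- as.integer(labels)
  if (length(y) != nrow(X)) stop("length(labels) must match nrow(features)")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0 (benign) or 1 (malignant)")
  if (length(unique(y)) < 2) stop("training set contains a single class")
  if (min(table(y)) < 2) stop("need at least 2 examples per class")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(spec$kind,
    svm_poly = e1071::svm(Z, yf, kernel = "polynomial", degree = spec$degree,
                          cost = spec$C, gamma = 1 / ncol(Z), coef0 = 0,
                          scale = FALSE),
    svm_rbf = e1071::svm(Z, yf, kernel = "radial", cost = spec$C,
                         gamma = spec$gamma, scale = FALSE),
    knn = list(train = Z, cl = yf),
    rfc = {
      set.seed(seed)
      ranger::ranger(x = as.data.frame(Z), y = yf,
                     num.trees = spec$n_estimators,
                     max.depth = spec$max_depth,
                     mtry = floor(sqrt(ncol(Z))),
                     seed = seed)
    })
  structure(list(spec = spec, center = mu, scale = sd, fit = fit,
                 n_train = nrow(X), seed = as.integer(seed)),
            class = "cenbi_model")
}

#' Predict benign/malignant labels
#'
#' @param object A fitted `cenbi_model`.
#' @param features n x 24 matrix or list of feature vectors.
#' @param ... Unused.
#' @return Integer vector of 0/1 labels, one per input row, in input order.
#' @export
predict.cenbi_model <- function(object, features, ...) {
  X <- as_feature_matrix(features)
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  spec <- object$spec
  pred <- switch(spec$kind,
    svm_poly = ,
    svm_rbf = stats::predict(object$fit, Z),
    knn = class::knn(object$fit$train, Z, object$fit$cl, k = spec$k),
    rfc = stats::predict(object$fit, data = as.data.frame(Z))$predictions)
  as.integer(as.character(pred))
}

# parameter grids searched during tuning (ascending canonical order)
tuning_grid <- function(kind) {
  switch(kind,
    svm_poly = data.frame(C = 10^(-3:3)),
    svm_rbf = expand.grid(gamma = 10^(-3:3), C = 10^(-3:3))[, c("C", "gamma")],
    knn = data.frame(k = 1:20),
    rfc = expand.grid(n_estimators = seq(10, 100, by = 5),
                      max_depth = 1:20)[, c("max_depth", "n_estimators")],
    stop("unknown classifier kind: ", kind))
}

# patient-grouped, label-stratified fold assignment
make_folds <- function(patient_ids, labels, n_folds, seed, grouped = TRUE) {
  if (!grouped) {
    set.seed(seed)
    return(sample(rep_len(seq_len(n_folds), length(labels))))
  }
  pat <- unique(patient_ids)
  if (length(pat) < n_folds)
    stop("fewer patients (", length(pat), ") than folds (", n_folds,
         "); reduce the number of folds")
  pat_label <- vapply(pat, function(p) labels[patient_ids == p][1], numeric(1))
  fold_of <- stats::setNames(integer(length(pat)), pat)
  set.seed(seed)
  for (lv in sort(unique(pat_label))) {
    ps <- sample(pat[pat_label == lv])
    fold_of[ps] <- rep_len(seq_len(n_folds), length(ps))
  }
  unname(fold_of[patient_ids])
}

#' Hyperparameter tuning by grid search with 10-fold cross-validation
#'
#' Exhaustive search over the canonical grids — `C` and `gamma` over
#' `0.001..1000` in ten-fold increments (7 values), `k` and tree depth over
#' `1..20`, tree count over `10..100` in steps of 5 (19 values) — scored by
#' mean cross-validated accuracy. Folds are grouped by patient (all images
#' of a patient fall in one fold, preventing leakage between near-duplicate
#' frames) and stratified by label; a flag restores ungrouped folds. Ties
#' are broken toward the smallest parameter values in the documented grid
#' order.
#'
#' @param features n x 24 matrix or list of feature vectors.
#' @param labels 0/1 labels.
#' @param kind Classifier kind (see [classifier_spec()]).
#' @param patient_ids Patient id per row (required when `grouped = TRUE`).
#' @param seed Integer seed for fold assignment and tree randomness.
#' @param n_folds Number of folds, default 10.
#' @param grouped Group folds by patient (default `TRUE`).
#' @param grid Optional custom grid (data.frame of parameter columns).
#' @return A list: `spec` (the selected [classifier_spec()]), `cv_accuracy`
#'   (its mean CV accuracy), and `results` (the full grid with scores).
#' @export
grid_search_cv <- function(features, labels, kind, patient_ids = NULL,
                           seed = 1L, n_folds = 10L, grouped = TRUE,
                           grid = NULL) {
  X <- as_feature_matrix(features)
  y <- as.integer(labels)
  if (length(y) < 20) stop("grid search needs at least 20 examples")
  if (grouped && is.null(patient_ids))
    stop("`patient_ids` required for patient-grouped folds")
  if (is.null(patient_ids)) patient_ids <- as.character(seq_along(y))
  folds <- make_folds(patient_ids, y, n_folds, seed, grouped)
  for (f in seq_len(n_folds)) {
    if (length(unique(y[folds != f])) < 2)
      stop("fold ", f, ": training part lost a class; use fewer folds")
  }
  if (is.null(grid)) grid <- tuning_grid(kind)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    spec <- do.call(classifier_spec, c(list(kind = kind), as.list(grid[g, , drop = FALSE])))
    fold_acc <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      if (!any(!tr)) return(NA_real_)
      model <- fit_classifier(X[tr, , drop = FALSE], y[tr], spec, seed = seed)
      mean(predict(model, X[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    acc[g] <- mean(fold_acc, na.rm = TRUE)
  }
  best <- which(acc > max(acc) - 1e-12)[1L]  # first max = smallest parameters
  list(spec = do.call(classifier_spec,
                      c(list(kind = kind), as.list(grid[best, , drop = FALSE]))),
       cv_accuracy = acc[best],
       results = cbind(grid, cv_accuracy = acc))
}
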