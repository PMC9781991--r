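# One-vs-all soft-margin SVM classification and stratified k-fold
# cross-validation. The quadratic program is solved by libsvm (via e1071);
# the one-against-all decomposition, standardization and fold logic live
# here.

#' SVM specification
#'
#' @param kernel `"gaussian"` (RBF) or `"linear"`.
#' @param C Soft-margin regularization weight (> 0, default 1).
#' @param gamma Gaussian kernel width; `NULL` (default) uses
#'   `1 / (n_features * var(x))` computed on the (standardized) training
#'   data.
#' @param standardize Z-score the features with training-set statistics
#'   before fitting (default `TRUE`); the time-domain predictors span
#'   orders of magnitude and kernel SVMs are scale-sensitive.
#' @return An object of class `svm_spec`.
#' @export
svm_spec <- function(kernel = c("gaussian", "linear"), C = 1, gamma = NULL,
                     standardize = TRUE) {
  kernel <- match.arg(kernel)
  C <- check_positive(C, "C")
  if (!is.null(gamma)) gamma <- check_positive(gamma, "gamma")
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 standardize = isTRUE(standardize)), class = "svm_spec")
}

resolve_xy <- function(x, y) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- feature_classes(x)
    x <- x$values
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(y)) stop_param("class labels y are required")
  y <- factor(y)
  if (length(y) != nrow(x)) stop_param("length(y) must equal nrow(x)")
  list(x = x, y = y)
}

#' Train a one-vs-all multi-class SVM
#'
#' Fits one binary soft-margin SVM per class (that class against all
#' others). Prediction evaluates every per-class decision function on the
#' standardized features and assigns the class with the highest decision
#' value; exact ties break to the lowest class index, so prediction is
#' deterministic given the model.
#'
#' @param x Feature matrix (`feature_matrix` or numeric matrix).
#' @param y Class labels (taken from `x` when it is a `feature_matrix`).
#' @param spec An [svm_spec()].
#' @return An object of class `ova_svm` with per-class machines, class
#'   order, kernel parameters and training standardization constants.
#' @export
ova_svm <- function(x, y = NULL, spec = svm_spec()) {
  d <- resolve_xy(x, y)
  x <- d$x; y <- d$y
  if (nlevels(y) < 2L) stop_param("one-vs-all needs at least 2 classes")
  if (any(table(y) < 1L)) stop_param("every class needs at least 1 row")
  if (spec$standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2L, sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  } else {
    center <- rep(0, ncol(x))
    scale_ <- rep(1, ncol(x))
  }
  xs <- scale(x, center = center, scale = scale_)
  gamma <- spec$gamma %||% {
    v <- var(as.vector(xs))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(xs) * v)
  }
  kern <- if (spec$kernel == "gaussian") "radial" else "linear"
  classes <- levels(y)
  machines <- vector("list", length(classes))
  signs <- numeric(length(classes))
  for (i in seq_along(classes)) {
    yi <- factor(ifelse(y == classes[i], "pos", "neg"),
                 levels = c("pos", "neg"))
    m <- e1071::svm(xs, yi, type = "C-classification", kernel = kern,
                    cost = spec$C, gamma = gamma, scale = FALSE)
    # libsvm orients the decision value toward whichever label it saw
    # first; normalize so positive always means "this class"
    dv <- attr(predict(m, xs[1L, , drop = FALSE], decision.values = TRUE),
               "decision.values")
    signs[i] <- if (colnames(dv)[1L] == "pos/neg") 1 else -1
    machines[[i]] <- m
  }
  structure(list(machines = machines, signs = signs, classes = classes,
                 center = center, scale = scale_, gamma = gamma,
                 spec = spec, n_features = ncol(x)),
            class = "ova_svm")
}

#' @export
print.ova_svm <- function(x, ...) {
  cat("One-vs-all SVM:", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), "),", x$spec$kernel,
      "kernel, C =", x$spec$C,
      if (x$spec$kernel == "gaussian") paste(", gamma =", signif(x$gamma, 4)),
      ",", x$n_features, "features\n")
  invisible(x)
}

#' Predict classes or decision values from a one-vs-all SVM
#'
#' @param object An `ova_svm` model.
#' @param newdata Feature matrix with the columns the model was trained on.
#' @param type `"class"` (default) for labels, `"decision"` for the
#'   n x classes matrix of decision values.
#' @param ... Unused.
#' @return Factor of predicted labels, or a decision-value matrix.
#' @export
predict.ova_svm <- function(object, newdata, type = c("class", "decision"),
                            ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop_param("newdata has ", ncol(newdata), " columns; model expects ",
               object$n_features)
  }
  xs <- scale(newdata, center = object$center, scale = object$scale)
  dec <- vapply(seq_along(object$machines), function(i) {
    dv <- attr(predict(object$machines[[i]], xs, decision.values = TRUE),
               "decision.values")
    object$signs[i] * as.numeric(dv)
  }, numeric(nrow(xs)))
  dec <- matrix(dec, nrow = nrow(xs),
                dimnames = list(NULL, object$classes))
  if (type == "decision") return(dec)
  factor(object$classes[max.col(dec, ties.method = "first")],
         levels = object$classes)
}

#' Stratified k-fold assignment
#'
#' Shuffles each class separately (seeded) and deals its rows over the `k`
#' folds, so folds are disjoint, exhaustive and class-balanced.
#'
#' @param y Class labels.
#' @param k Fold count (>= 2); every class must have at least `k` rows.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per row.
#' @export
stratified_folds <- function(y, k = 10, seed = 1L) {
  y <- factor(y)
  k <- check_count(k, "k", min = 2L)
  if (any(table(y) < k)) {
    small <- names(which(table(y) < k))
    stop_param("class(es) smaller than k = ", k, ": ",
               paste(small, collapse = ", "))
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated mean classification error
#'
#' Stratified k-fold cross-validation of the one-vs-all SVM; the mean
#' misclassification fraction over folds is the fitness minimized by the
#' wrapper selectors.
#'
#' @param x Feature matrix (`feature_matrix` or numeric matrix).
#' @param y Class labels (taken from `x` when it is a `feature_matrix`).
#' @param spec An [svm_spec()].
#' @param k Fold count (default 10).
#' @param seed Seed for the fold assignment.
#' @return An object of class `cv_result`: `$k`, `$fold_errors`,
#'   `$mean_error`, `$folds`.
#' @export
cv_mean_error <- function(x, y = NULL, spec = svm_spec(), k = 10,
                          seed = 1L) {
  d <- resolve_xy(x, y)
  folds <- stratified_folds(d$y, k, seed)
  errs <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    model <- ova_svm(d$x[tr, , drop = FALSE], d$y[tr], spec)
    pred <- predict(model, d$x[!tr, , drop = FALSE])
    mean(pred != d$y[!tr])
  }, numeric(1))
  structure(list(k = k, fold_errors = errs, mean_error = mean(errs),
                 folds = folds), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean error %.4f (fold range %.4f-%.4f)\n",
              x$k, x$mean_error, min(x$fold_errors), max(x$fold_errors)))
  invisible(x)
}
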