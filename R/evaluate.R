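# Confusion-matrix metrics, macro averages, and leave-one-feature-out
# sensitivity analysis.

#' Efficiency: the mean of accuracy, sensitivity and specificity
#'
#' Works on any consistent scale (fractions or percentages); vectorized.
#'
#' @param accuracy,sensitivity,specificity Numeric vectors.
#' @return `(accuracy + sensitivity + specificity) / 3`.
#' @export
efficiency <- function(accuracy, sensitivity, specificity) {
  (accuracy + sensitivity + specificity) / 3
}

#' Per-class metrics from one-vs-rest confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and their mean, the efficiency. A zero denominator yields
#' `NA` (an explicit undefined-metric marker, never a silent zero).
#'
#' @param TP,TN,FP,FN Non-negative counts (vectorized).
#' @return Data frame of counts and the four metrics as fractions in
#'   `[0, 1]`.
#' @export
class_metrics <- function(TP, TN, FP, FN) {
  if (any(c(TP, TN, FP, FN) < 0)) stop_param("counts must be non-negative")
  total <- TP + TN + FP + FN
  if (any(total == 0)) stop_param("total count must be positive")
  sens <- ifelse(TP + FN > 0, TP / (TP + FN), NA_real_)
  spec <- ifelse(TN + FP > 0, TN / (TN + FP), NA_real_)
  acc <- (TP + TN) / total
  data.frame(TP = TP, TN = TN, FP = FP, FN = FN,
             accuracy = acc, sensitivity = sens, specificity = spec,
             efficiency = efficiency(acc, sens, spec))
}

#' Per-class performance report for a multi-class prediction
#'
#' Reduces each class to its one-vs-rest confusion counts and evaluates
#' the four metrics, plus their unweighted macro averages.
#'
#' @param truth True class labels.
#' @param predicted Predicted labels (same length).
#' @return An object of class `performance_report`: `$per_class` data frame
#'   (one row per class) and `$macro`, the named vector of unweighted means
#'   (`NA` metrics are excluded with a warning).
#' @export
performance_report <- function(truth, predicted) {
  truth <- factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  if (length(truth) != length(predicted)) {
    stop_param("truth and predicted must have equal length")
  }
  per <- do.call(rbind, lapply(levels(truth), function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    fp <- sum(truth != cl & predicted == cl)
    tn <- sum(truth != cl & predicted != cl)
    cbind(class = cl, class_metrics(tp, tn, fp, fn))
  }))
  macro <- macro_average(per)
  structure(list(per_class = per, macro = macro, n = length(truth)),
            class = "performance_report")
}

#' Unweighted macro averages of per-class metrics
#'
#' @param report A `performance_report` or its `per_class` data frame.
#' @return Named vector with the mean accuracy, sensitivity, specificity
#'   and efficiency over classes. Undefined (`NA`) per-class values are
#'   excluded with a warning.
#' @export
macro_average <- function(report) {
  per <- if (inherits(report, "performance_report")) report$per_class
         else report
  cols <- c("accuracy", "sensitivity", "specificity", "efficiency")
  if (anyNA(per[, cols])) {
    warning("undefined per-class metrics excluded from macro averages")
  }
  vapply(per[cols], mean, numeric(1), na.rm = TRUE)
}

#' @export
print.performance_report <- function(x, digits = 2, ...) {
  per <- x$per_class
  show <- per
  for (m in c("accuracy", "sensitivity", "specificity", "efficiency")) {
    show[[m]] <- sprintf(paste0("%.", digits, "f%%"), 100 * per[[m]])
  }
  cat("Per-class performance (", x$n, " observations):\n", sep = "")
  print(show, row.names = FALSE)
  cat(sprintf(
    "Macro averages: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, efficiency %.2f%%\n",
    100 * x$macro["accuracy"], 100 * x$macro["sensitivity"],
    100 * x$macro["specificity"], 100 * x$macro["efficiency"]))
  invisible(x)
}

#' Write a performance report as CSV or JSON
#'
#' @param report A `performance_report`.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_performance_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(per_class = report$per_class,
                              macro = as.list(report$macro),
                              n = report$n),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(report$per_class, path, row.names = FALSE)
  }
  invisible(path)
}

#' Evaluate a one-vs-all SVM on labelled data
#'
#' @param model An `ova_svm`.
#' @param x Feature matrix (`feature_matrix` or numeric matrix) with the
#'   training columns.
#' @param y True labels (taken from `x` when it is a `feature_matrix`).
#' @return A [performance_report()].
#' @export
evaluate_model <- function(model, x, y = NULL) {
  d <- resolve_xy(x, y)
  performance_report(d$y, predict(model, d$x))
}

#' Leave-one-feature-out sensitivity analysis
#'
#' Trains the reference model on the masked feature columns and records its
#' test accuracy Y1 (in percent). Then, for each selected feature i, the
#' model is retrained without feature i (the reduced set X2), its test
#' accuracy Y2 recorded, and the impact reported as the difference
#' `Y2 - Y1` and the percentage change `(Y2 - Y1) / Y1 * 100`. A strongly
#' negative percentage change marks a feature the classification depends
#' on.
#'
#' @param x_train,y_train Training features and labels.
#' @param x_test,y_test Held-out features and labels.
#' @param mask Logical/0-1 vector over columns selecting >= 2 features, or
#'   `NULL` for all columns.
#' @param spec An [svm_spec()].
#' @return An object of class `sensitivity_report`: a data frame with one
#'   reference row (feature `"(none)"`, delta 0) and one row per removed
#'   feature with Y1, Y2, delta and pct_change.
#' @export
sensitivity_analysis <- function(x_train, y_train = NULL, x_test,
                                 y_test = NULL, mask = NULL,
                                 spec = svm_spec()) {
  tr <- resolve_xy(x_train, y_train)
  te <- resolve_xy(x_test, y_test)
  if (is.null(mask)) mask <- rep(TRUE, ncol(tr$x))
  mask <- as.logical(mask)
  sel <- which(mask)
  if (length(sel) < 2L) {
    stop_param("sensitivity analysis needs a mask of >= 2 features")
  }
  acc <- function(cols) {
    m <- ova_svm(tr$x[, cols, drop = FALSE], tr$y, spec)
    100 * mean(predict(m, te$x[, cols, drop = FALSE]) == te$y)
  }
  y1 <- acc(sel)
  rows <- lapply(seq_along(sel), function(i) {
    y2 <- acc(sel[-i])
    data.frame(feature = colnames(tr$x)[sel[i]] %||% as.character(sel[i]),
               Y1 = y1, Y2 = y2, delta = y2 - y1,
               pct_change = (y2 - y1) / y1 * 100,
               stringsAsFactors = FALSE)
  })
  out <- rbind(data.frame(feature = "(none)", Y1 = y1, Y2 = y1, delta = 0,
                          pct_change = 0, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' Bundled reference performance tables
#'
#' Per-class sensitivity/specificity/accuracy/efficiency tables (in
#' percent) for the EMG movement-classification experiments the package
#' reproduces: the right-leg database with GA-selected features, and the
#' right-arm database with GA- and PSO-selected features, each at the
#' training and validation stages. Values are transcribed as printed, so
#' each cell carries its original decimal precision (available through the
#' `"printed"` attribute).
#'
#' @param which One of `"leg_ga_train"`, `"leg_ga_valid"`, `"arm_ga_train"`,
#'   `"arm_ga_valid"`, `"arm_pso_train"`, `"arm_pso_valid"`.
#' @return Data frame with columns `class`, `sensitivity`, `specificity`,
#'   `accuracy`, `efficiency` (numeric, percent) and the verbatim strings
#'   in `attr(, "printed")`.
#' @export
reference_performance <- function(which = c("leg_ga_train", "leg_ga_valid",
                                            "arm_ga_train", "arm_ga_valid",
                                            "arm_pso_train",
                                            "arm_pso_valid")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("perf_", which, ".csv"),
                      package = "emgselect", mustWork = TRUE)
  raw <- read.csv(path, colClasses = "character")
  out <- raw
  for (col in c("sensitivity", "specificity", "accuracy", "efficiency")) {
    out[[col]] <- as.numeric(raw[[col]])
  }
  attr(out, "printed") <- raw
  out
}
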