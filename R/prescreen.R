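# ANOVA-based predictor elimination ahead of wrapper selection.

#' One-way ANOVA prescreen of a feature matrix
#'
#' For every (channel, predictor) column a classical one-way ANOVA F-test
#' across movement classes is computed. A predictor is eliminated at
#' whole-predictor granularity -- across all channels at once -- when the
#' median of its per-channel p-values exceeds `alpha`, i.e. when for most
#' channels the class means are statistically indistinguishable. Eliminating
#' `p` predictors therefore removes exactly `channels * p` columns.
#'
#' @param fm A `feature_matrix` with the full channel-major predictor grid.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `prescreen_result`: per-column p-values
#'   (`$p_table`, a data frame with channel, predictor, p), per-predictor
#'   aggregated p (`$p_predictor`), `$eliminated` predictor names and
#'   `$alpha`.
#' @export
anova_prescreen <- function(fm, alpha = 0.05) {
  if (!inherits(fm, "feature_matrix")) stop_param("fm must be a feature_matrix")
  g <- feature_classes(fm)
  if (nlevels(g) < 2L) stop_param("prescreen needs at least 2 classes")
  if (any(table(g) < 2L)) {
    stop_param("every class needs at least 2 rows for ANOVA")
  }
  p <- apply(fm$values, 2L, function(col) {
    oneway.test(col ~ g, var.equal = TRUE)$p.value
  })
  tab <- data.frame(
    channel = rep(seq_len(fm$channels), each = length(fm$predictors)),
    predictor = rep(fm$predictors, times = fm$channels),
    p = as.numeric(p), stringsAsFactors = FALSE)
  p_pred <- tapply(tab$p, tab$predictor, median)
  p_pred <- p_pred[fm$predictors]  # restore canonical order
  eliminated <- names(p_pred)[p_pred > alpha]
  structure(list(p_table = tab, p_predictor = p_pred,
                 eliminated = eliminated, alpha = alpha),
            class = "prescreen_result")
}

#' @export
print.prescreen_result <- function(x, ...) {
  cat("ANOVA prescreen (alpha =", x$alpha, "):",
      length(x$eliminated), "of", length(x$p_predictor),
      "predictors eliminated\n")
  if (length(x$eliminated)) {
    cat(" eliminated:", paste(x$eliminated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Apply a prescreen result to a feature matrix
#'
#' @param fm A `feature_matrix` with the same predictor grid the prescreen
#'   was run on.
#' @param ps A `prescreen_result`.
#' @return The reduced `feature_matrix` (unchanged if nothing was
#'   eliminated).
#' @export
apply_prescreen <- function(fm, ps) {
  if (!length(ps$eliminated)) return(fm)
  drop_predictors(fm, ps$eliminated)
}

#' Write a prescreen report as CSV
#'
#' Columns: channel, predictor, p, eliminated.
#'
#' @param ps A `prescreen_result`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_prescreen_report <- function(ps, path) {
  tab <- ps$p_table
  tab$eliminated <- tab$predictor %in% ps$eliminated
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
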