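# Shared machinery for the wrapper selectors: the cached cross-validated
# fitness over binary feature masks, and the selection-run result object.

# Fitness closure over masks: mean CV error of the masked matrix, with a
# cache keyed by the gene string. The all-zero mask is unclassifiable and
# scores the worst possible error, 1.0, without touching the SVM. The CV
# fold seed is fixed for the whole run so the fitness landscape is static.
make_mask_fitness <- function(x, y, spec, k, cv_seed) {
  d <- resolve_xy(x, y)
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  fit <- function(mask) {
    if (!any(mask)) return(1.0)
    key <- paste(as.integer(mask), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    err <- cv_mean_error(d$x[, mask, drop = FALSE], d$y, spec, k,
                         seed = cv_seed)$mean_error
    evals <<- evals + 1L
    cache[[key]] <- err
    err
  }
  attr(fit, "n_evals") <- function() evals
  fit
}

new_selection_run <- function(method, best_mask, best_fitness, history,
                              n_evaluations, config, feature_names) {
  structure(list(method = method, best_mask = best_mask,
                 best_fitness = best_fitness, history = history,
                 n_evaluations = n_evaluations, config = config,
                 feature_names = feature_names),
            class = "selection_run")
}

#' @export
print.selection_run <- function(x, ...) {
  cat(toupper(x$method), "feature selection:", sum(x$best_mask), "of",
      length(x$best_mask), "features kept;",
      sprintf("best CV mean error %.4f after %d iterations (%d CV evaluations)\n",
              x$best_fitness, length(x$history), x$n_evaluations))
  invisible(x)
}

#' Plot the best-fitness history of a selection run
#'
#' @param x A `selection_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.selection_run <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "s",
                 xlab = "iteration", ylab = "best CV mean error",
                 main = paste(toupper(x$method), "selection"), ...)
  invisible(x)
}

#' Selected feature mask of a selection run
#'
#' @param object A `selection_run`.
#' @param ... Unused.
#' @return Named logical vector over feature columns.
#' @export
coef.selection_run <- function(object, ...) {
  stats::setNames(as.logical(object$best_mask), object$feature_names)
}

#' Write a selection run's mask and fitness history as CSV
#'
#' The run log has columns `iteration,best_error,n_selected`; the mask file
#' has columns `feature,selected`, aligned to the feature-matrix columns.
#'
#' @param run A `selection_run`.
#' @param log_path,mask_path Output CSV paths (either may be `NULL` to
#'   skip).
#' @return `run`, invisibly.
#' @export
write_selection_run <- function(run, log_path = NULL, mask_path = NULL) {
  if (!is.null(log_path)) {
    log <- if (length(run$history)) {
      data.frame(selector = run$method,
                 iteration = seq_along(run$history),
                 best_error = run$history,
                 n_selected = sum(run$best_mask))
    } else {
      data.frame(selector = run$method, iteration = NA_integer_,
                 best_error = NA_real_, n_selected = sum(run$best_mask))
    }
    write.csv(log, log_path, row.names = FALSE)
  }
  if (!is.null(mask_path)) {
    write.csv(data.frame(feature = run$feature_names %||%
                           seq_along(run$best_mask),
                         selected = as.integer(run$best_mask)),
              mask_path, row.names = FALSE)
  }
  invisible(run)
}

#' Exhaustive search over all non-empty feature masks
#'
#' Brute-force oracle for small instances: evaluates every non-empty subset
#' of the columns with the same cross-validated fitness the selectors use.
#'
#' @param x Feature matrix (`feature_matrix` or numeric matrix).
#' @param y Class labels.
#' @param spec An [svm_spec()].
#' @param k CV fold count.
#' @param cv_seed Seed for the CV folds.
#' @return List with `best_mask`, `best_fitness`, and the full `fitness`
#'   vector indexed by subset number.
#' @export
exhaustive_mask_search <- function(x, y = NULL, spec = svm_spec(), k = 10,
                                   cv_seed = 1L) {
  d <- resolve_xy(x, y)
  p <- ncol(d$x)
  if (p > 16L) stop_param("exhaustive search limited to 16 features")
  fit <- make_mask_fitness(d$x, d$y, spec, k, cv_seed)
  n_masks <- 2^p - 1L
  fitness <- numeric(n_masks)
  best <- Inf; best_mask <- NULL
  for (m in seq_len(n_masks)) {
    mask <- as.logical(bitwAnd(m, 2^(seq_len(p) - 1L)))
    fitness[m] <- fit(mask)
    if (fitness[m] < best) {
      best <- fitness[m]
      best_mask <- mask
    }
  }
  list(best_mask = best_mask, best_fitness = best, fitness = fitness)
}
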