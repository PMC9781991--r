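# Config-driven end-to-end orchestration: synthesis (or loading), filtering,
# feature extraction, prescreening, wrapper selection, window classification,
# evaluation and sensitivity analysis, with every stochastic stage seeded.

default_pipeline_config <- function() {
  list(
    database = list(n_subjects = 4, movements = c("AP", "AT", "LP", "RR"),
                    n_reps = 6, n_channels = 4, fs = 1000, duration = 2,
                    rest_lead = 0.4, rest_label = "RR", seed = 1,
                    input_dir = NULL),
    filter = list(enabled = TRUE, low_hz = 10, high_hz = 500, order = 4),
    window = list(length_ms = 250, overlap_ms = 190),
    trim = list(start_s = 0.4, end_s = 0),
    predictors = emg_predictors(),
    prescreen = list(enabled = TRUE, alpha = 0.05),
    selector = list(method = "ga", pop_size = 20, mutation_rate = 0.02,
                    max_iterations = 10, n_particles = 10, w = 0.9,
                    c1 = 2, c2 = 2, v_clamp = 6, seed = 1),
    svm = list(kernel = "gaussian", C = 1, gamma = NULL,
               standardize = TRUE),
    cv = list(k = 5),
    split = list(select_frac = 0.7, train_frac = 0.25, seed = 1)
  )
}

#' Build a pipeline configuration
#'
#' Starts from the package defaults (a small synthetic database, GA
#' selection with a Gaussian-kernel SVM fitness) and overrides them with
#' the supplied nested list or YAML file. See the packaged configs under
#' `system.file("configs", package = "emgselect")` for full-size examples.
#'
#' @param config Nested list of overrides, or the path of a YAML file.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_param("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_param("config must be a list or YAML path")
  cfg <- modifyList(default_pipeline_config(), config)
  cfg$predictors <- unlist(cfg$predictors)
  cfg$database$movements <- unlist(cfg$database$movements)
  if (!cfg$selector$method %in% c("ga", "pso", "none")) {
    stop_param("selector.method must be ga, pso or none")
  }
  if (cfg$split$select_frac <= 0 || cfg$split$select_frac >= 1 ||
      cfg$split$train_frac <= 0 || cfg$split$train_frac >= 1) {
    stop_param("split fractions must lie in (0, 1)")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

# Stratified split of recordings by movement class; returns logical
# "selected" per recording. All windows of one repetition inherit the
# recording's side of the split, so overlapping windows never leak across.
split_recordings <- function(meta, frac, seed) {
  sel <- logical(nrow(meta))
  with_seed(seed, {
    for (cl in unique(meta$movement)) {
      idx <- which(meta$movement == cl)
      n_take <- max(1L, round(frac * length(idx)))
      sel[sample(idx, n_take)] <- TRUE
    }
  })
  sel
}

stage <- function(out_dir, name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full movement-classification pipeline
#'
#' Executes, in order: database synthesis (or loading), band-pass
#' filtering, unsegmented feature extraction, optional ANOVA prescreen,
#' signal-level stratified split, wrapper feature selection on the
#' unsegmented training signals (the fast surrogate for the windows),
#' windowed feature extraction restricted to the selected columns,
#' repetition-level window split, SVM training, evaluation on the training
#' and validation windows, and leave-one-feature-out sensitivity analysis.
#' All artifacts are written as CSV/JSON under `out_dir` together with a
#' manifest echoing the full configuration, so identical configs reproduce
#' byte-identical masks and metric tables.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results (database
#'   spec, prescreen, selection run, model, train/validation reports,
#'   sensitivity report) and the artifact paths.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  db <- stage(out_dir, "synth", {
    if (!is.null(cfg$database$input_dir)) {
      read_database(cfg$database$input_dir)
    } else {
      dspec <- do.call(database_spec,
                       cfg$database[setdiff(names(cfg$database), "input_dir")])
      generate_database(dspec)
    }
  })

  if (isTRUE(cfg$filter$enabled)) {
    db <- stage(out_dir, "filter", {
      fsp <- filter_spec(cfg$filter$low_hz, cfg$filter$high_hz,
                         cfg$filter$order)
      out <- suppressWarnings(lapply(db, bandpass, fspec = fsp))
      class(out) <- class(db)
      attributes(out)$spec <- attr(db, "spec")
      out
    })
  }

  preds <- cfg$predictors
  fm_full <- stage(out_dir, "features", {
    extract_features(db, preds, wspec = NULL,
                     trim_start = cfg$trim$start_s,
                     trim_end = cfg$trim$end_s)
  })

  ps <- NULL
  if (isTRUE(cfg$prescreen$enabled)) {
    ps <- stage(out_dir, "prescreen", anova_prescreen(fm_full,
                                                      cfg$prescreen$alpha))
    write_prescreen_report(ps, p("prescreen.csv"))
    fm_full <- apply_prescreen(fm_full, ps)
  }

  svm <- svm_spec(cfg$svm$kernel, cfg$svm$C, cfg$svm$gamma,
                  cfg$svm$standardize)
  sel_rows <- split_recordings(fm_full$meta, cfg$split$select_frac,
                               cfg$split$seed)
  fm_sel <- fm_full
  fm_sel$values <- fm_full$values[sel_rows, , drop = FALSE]
  fm_sel$meta <- fm_full$meta[sel_rows, , drop = FALSE]

  run <- stage(out_dir, "select", {
    s <- cfg$selector
    if (s$method == "ga") {
      run_ga(fm_sel, spec = svm,
             config = ga_config(n_genes = ncol(fm_sel$values),
                                pop_size = s$pop_size,
                                mutation_rate = s$mutation_rate,
                                max_iterations = s$max_iterations,
                                seed = s$seed),
             k = cfg$cv$k)
    } else if (s$method == "pso") {
      run_pso(fm_sel, spec = svm,
              config = pso_config(n_genes = ncol(fm_sel$values),
                                  n_particles = s$n_particles, w = s$w,
                                  c1 = s$c1, c2 = s$c2,
                                  max_iterations = s$max_iterations,
                                  v_clamp = s$v_clamp, seed = s$seed),
              k = cfg$cv$k)
    } else {
      new_selection_run("none", rep(TRUE, ncol(fm_sel$values)), NA_real_,
                        numeric(0), 0L, NULL, colnames(fm_sel$values))
    }
  })
  write_selection_run(run, log_path = p("selection_log.csv"),
                      mask_path = p("mask.csv"))

  fm_win <- stage(out_dir, "window features", {
    wspec <- window_spec(cfg$window$length_ms, cfg$window$overlap_ms)
    fmw <- extract_features(db, fm_full$predictors, wspec = wspec,
                            trim_start = cfg$trim$start_s,
                            trim_end = cfg$trim$end_s)
    select_columns(fmw, run$best_mask)
  })

  rep_meta <- unique(fm_win$meta[, c("subject", "movement", "repetition")])
  rep_meta$key <- paste(rep_meta$subject, rep_meta$movement,
                        rep_meta$repetition)
  train_rep <- split_recordings(rep_meta, cfg$split$train_frac,
                                cfg$split$seed + 1L)
  win_key <- paste(fm_win$meta$subject, fm_win$meta$movement,
                   fm_win$meta$repetition)
  tr_rows <- win_key %in% rep_meta$key[train_rep]

  model <- stage(out_dir, "train", {
    ova_svm(fm_win$values[tr_rows, , drop = FALSE],
            fm_win$meta$movement[tr_rows], svm)
  })

  report_train <- stage(out_dir, "evaluate", {
    performance_report(fm_win$meta$movement[tr_rows],
                       predict(model, fm_win$values[tr_rows, , drop = FALSE]))
  })
  report_valid <- performance_report(
    fm_win$meta$movement[!tr_rows],
    predict(model, fm_win$values[!tr_rows, , drop = FALSE]))
  write_performance_report(report_train, p("performance_train.csv"))
  write_performance_report(report_valid, p("performance_valid.csv"))
  write_performance_report(report_valid, p("performance_valid.json"))

  sens <- NULL
  if (sum(run$best_mask) >= 2L) {
    sens <- stage(out_dir, "sensitivity", {
      sensitivity_analysis(fm_win$values[tr_rows, , drop = FALSE],
                           fm_win$meta$movement[tr_rows],
                           fm_win$values[!tr_rows, , drop = FALSE],
                           fm_win$meta$movement[!tr_rows],
                           mask = NULL, spec = svm)
    })
    write.csv(sens, p("sensitivity.csv"), row.names = FALSE)
  }

  manifest <- list(config = unclass(cfg),
                   n_recordings = length(db),
                   unsegmented_dim = dim(fm_full$values),
                   segmented_dim = dim(fm_win$values),
                   n_selected = sum(run$best_mask))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")

  invisible(list(config = cfg, prescreen = ps, selection = run,
                 model = model, report_train = report_train,
                 report_valid = report_valid, sensitivity = sens,
                 dir = out_dir))
}
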