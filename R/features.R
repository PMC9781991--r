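# The 26 classical time-domain EMG predictors and labelled feature matrices.
#
# Closed forms, for a window x[1..N] (D[i] = x[i+1] - x[i]):
#   MAV    mean(|x|)
#   IEMG   sum(|x|)
#   SSI    sum(x^2)
#   VAR    sum(x^2) / (N - 1)            (zero-mean EMG convention)
#   RMS    sqrt(mean(x^2))
#   STD    sqrt(sum((x - mean(x))^2) / (N - 1))
#   WL     sum(|D|)                       (waveform length)
#   AAC    sum(|D|) / (N - 1)             (average amplitude change)
#   AAV    sum(|D|) / N                   (differenced MAV scaled by window
#                                          length; distinct from AAC)
#   DASDV  sqrt(sum(D^2) / (N - 1))
#   ZC     #{i : x[i] * x[i+1] < 0 and |D[i]| >= zc_threshold}
#   SSC    #{i : -D[i-1] * D[i] > ssc_threshold}
#   WAMP   #{i : |D[i]| >= wamp_threshold}
#   MYOP   mean(|x| >= myop_threshold)
#   LOG    exp(mean(log(|x| + 1e-12)))    (log detector)
#   MAVSLP mean of consecutive MAV differences over `mavslp_segments`
#          equal segments (one scalar per window)
#   MMAV1  mean(w * |x|), w = 1 on the middle half, 0.5 outside
#   MMAV2  mean(w * |x|), w = 1 on the middle half, 4i/N rising and
#          4(N - i)/N falling outside
#   K      m4 / m2^2                      (Pearson kurtosis, central moments)
#   SK     m3 / m2^(3/2)                  (skewness)
#   MAD    median(|x - median(x)|)        (unscaled)
#   Y3-Y5  |mean(x^k)|, k = 3, 4, 5       (absolute higher moments)
#   FC     Higuchi fractal dimension, k_max = higuchi_kmax
#   SE     sample entropy, m = sampen_m, r = sampen_r * sd(x)
#   MYOP/WAMP thresholds default to 0.02 in normalized amplitude units; ZC
#   and SSC thresholds default to 0. All are configurable via td_options().

#' The 26 time-domain predictor names
#'
#' @return Character vector of predictor abbreviations, in canonical column
#'   order.
#' @export
emg_predictors <- function() {
  c("AAC", "AAV", "DASDV", "FC", "SE", "K", "SK", "MAD", "WAMP",
    "Y3", "Y4", "Y5", "MYOP", "VAR", "WL", "ZC", "LOG", "MAV",
    "MAVSLP", "MMAV1", "MMAV2", "RMS", "SSC", "SSI", "STD", "IEMG")
}

#' Options for time-domain feature computation
#'
#' @param zc_threshold Amplitude-difference threshold for a zero crossing to
#'   count (default 0).
#' @param ssc_threshold Threshold on the slope product for a slope-sign
#'   change (default 0, strict inequality).
#' @param wamp_threshold Willison-amplitude threshold (default 0.02,
#'   normalized amplitude units).
#' @param myop_threshold Myopulse threshold (default 0.02).
#' @param mavslp_segments Number of equal segments for MAVSLP (default 3).
#' @param higuchi_kmax Maximum delay for the Higuchi fractal-dimension
#'   estimate (default 8).
#' @param sampen_m Sample-entropy embedding dimension (default 2).
#' @param sampen_r Sample-entropy tolerance as a fraction of the window
#'   standard deviation (default 0.2).
#' @return A list of class `td_options`.
#' @export
td_options <- function(zc_threshold = 0, ssc_threshold = 0,
                       wamp_threshold = 0.02, myop_threshold = 0.02,
                       mavslp_segments = 3, higuchi_kmax = 8,
                       sampen_m = 2, sampen_r = 0.2) {
  structure(list(zc_threshold = zc_threshold, ssc_threshold = ssc_threshold,
                 wamp_threshold = wamp_threshold,
                 myop_threshold = myop_threshold,
                 mavslp_segments = as.integer(mavslp_segments),
                 higuchi_kmax = as.integer(higuchi_kmax),
                 sampen_m = as.integer(sampen_m), sampen_r = sampen_r),
            class = "td_options")
}

# Vectorized engine: X is a samples x windows matrix; returns a
# windows x length(predictors) matrix.
td_features <- function(X, predictors = emg_predictors(),
                        opts = td_options()) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  n <- nrow(X)
  if (n < 3L) stop_param("windows must have at least 3 samples")
  unknown <- setdiff(predictors, emg_predictors())
  if (length(unknown)) {
    stop_param("unknown predictor(s): ", paste(unknown, collapse = ", "))
  }
  k <- ncol(X)
  absX <- abs(X)
  D <- X[-1L, , drop = FALSE] - X[-n, , drop = FALSE]
  absD <- abs(D)
  sumAbsD <- colSums(absD)
  sumSq <- colSums(X * X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  m2 <- colMeans(Xc^2)
  val <- function(name) {
    switch(name,
      MAV = colMeans(absX),
      IEMG = colSums(absX),
      SSI = sumSq,
      VAR = sumSq / (n - 1L),
      RMS = sqrt(sumSq / n),
      STD = sqrt(colSums(Xc^2) / (n - 1L)),
      WL = sumAbsD,
      AAC = sumAbsD / (n - 1L),
      AAV = sumAbsD / n,
      DASDV = sqrt(colSums(D * D) / (n - 1L)),
      ZC = colSums((X[-n, , drop = FALSE] * X[-1L, , drop = FALSE] < 0) &
                      (absD >= opts$zc_threshold)),
      SSC = colSums(-(D[-(n - 1L), , drop = FALSE] *
                         D[-1L, , drop = FALSE]) > opts$ssc_threshold),
      WAMP = colSums(absD >= opts$wamp_threshold),
      MYOP = colMeans(absX >= opts$myop_threshold),
      LOG = exp(colMeans(log(absX + 1e-12))),
      MAVSLP = td_mavslp(absX, opts$mavslp_segments),
      MMAV1 = colSums(absX * mmav_weights(n, type = 1L)) / n,
      MMAV2 = colSums(absX * mmav_weights(n, type = 2L)) / n,
      K = colMeans(Xc^4) / m2^2,
      SK = colMeans(Xc^3) / m2^1.5,
      MAD = apply(X, 2L, function(v) median(abs(v - median(v)))),
      Y3 = abs(colMeans(X^3)),
      Y4 = colMeans(X^4),
      Y5 = abs(colMeans(X^5)),
      FC = .higuchi_mat(X, opts$higuchi_kmax),
      SE = .sampen_mat(X, opts$sampen_m, opts$sampen_r * sqrt(m2 * n / (n - 1L)))
    )
  }
  out <- vapply(predictors, val, numeric(k))
  out <- matrix(out, nrow = k, ncol = length(predictors),
                dimnames = list(NULL, predictors))
  out
}

td_mavslp <- function(absX, segments) {
  n <- nrow(absX)
  bounds <- round(seq(0, n, length.out = segments + 1L))
  mavs <- vapply(seq_len(segments), function(s) {
    rows <- (bounds[s] + 1L):bounds[s + 1L]
    colMeans(absX[rows, , drop = FALSE])
  }, numeric(ncol(absX)))
  if (ncol(absX) == 1L) mavs <- matrix(mavs, nrow = 1L)
  (mavs[, segments] - mavs[, 1L]) / (segments - 1L)
}

mmav_weights <- function(n, type) {
  i <- seq_len(n)
  w <- rep(1, n)
  lo <- i < 0.25 * n
  hi <- i > 0.75 * n
  if (type == 1L) {
    w[lo | hi] <- 0.5
  } else {
    w[lo] <- 4 * i[lo] / n
    w[hi] <- 4 * (n - i[hi]) / n
  }
  w
}

#' Compute a single time-domain predictor on one window
#'
#' @param x Numeric vector (one channel of one window, length >= 3).
#' @param name Predictor abbreviation (one of [emg_predictors()]).
#' @param opts A [td_options()] list.
#' @return A finite scalar.
#' @examples
#' compute_predictor(c(1, -1, 1, -1), "MAV")  # 1
#' compute_predictor(c(1, -1, 1, -1), "ZC")   # 3
#' @export
compute_predictor <- function(x, name, opts = td_options()) {
  unname(td_features(matrix(as.numeric(x), ncol = 1L), name, opts)[1L, 1L])
}

#' Assemble a feature matrix from components
#'
#' Builds the labelled container [extract_features()] returns from an
#' existing numeric matrix, e.g. when composing features outside the
#' package. Columns must follow the channel-major layout
#' (`channels * length(predictors)` columns).
#'
#' @param values Numeric matrix of feature values.
#' @param channels Channel count.
#' @param predictors Predictor names (one set per channel).
#' @param meta Per-row metadata data frame; a `movement` column (the class
#'   label) is required, `subject`, `repetition` and `window` are filled
#'   with `NA` when absent.
#' @return A `feature_matrix`.
#' @export
as_feature_matrix <- function(values, channels, predictors, meta) {
  values <- as.matrix(values)
  if (ncol(values) != channels * length(predictors)) {
    stop_param("values must have channels * predictors = ",
               channels * length(predictors), " columns")
  }
  if (is.null(meta$movement)) stop_param("meta must contain a movement column")
  if (nrow(meta) != nrow(values)) {
    stop_param("meta must have one row per values row")
  }
  for (col in c("subject", "repetition", "window")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA
  }
  new_feature_matrix(values, channels, predictors, meta)
}

new_feature_matrix <- function(values, channels, predictors, meta) {
  colnames(values) <- paste0("ch", rep(seq_len(channels),
                                       each = length(predictors)),
                             "_", rep(predictors, times = channels))
  structure(list(values = values, channels = channels,
                 predictors = predictors, meta = meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$values), "rows x", ncol(x$values),
      "columns (", x$channels, "channels x", length(x$predictors),
      "predictors ),", length(unique(x$meta$movement)), "classes\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' Class labels of a feature matrix
#' @param fm A `feature_matrix`.
#' @return Factor of movement labels, one per row.
#' @export
feature_classes <- function(fm) factor(fm$meta$movement)

#' Extract a labelled feature matrix from recordings
#'
#' Computes the requested predictors per channel and assembles them in
#' channel-major column order (all predictors of channel 1, then channel 2,
#' ...). In unsegmented mode each recording contributes one row computed on
#' the (trimmed) whole signal; in segmented mode each overlapping window
#' contributes a row. Row order is the database order (subject-major, then
#' movement, then repetition), windows in temporal order within a recording.
#'
#' @param db An `emg_database` (or list of `emg_recording`s) sharing one
#'   channel count.
#' @param predictors Character vector of predictor names.
#' @param wspec A [window_spec()] for segmented extraction, or `NULL`
#'   (default) for whole-signal rows.
#' @param trim_start,trim_end Seconds discarded from each recording before
#'   feature computation or windowing.
#' @param opts A [td_options()] list.
#' @return A `feature_matrix`: values, channel count, predictor names, and
#'   per-row metadata (subject, movement, repetition, window).
#' @export
extract_features <- function(db, predictors = emg_predictors(), wspec = NULL,
                             trim_start = 0, trim_end = 0,
                             opts = td_options()) {
  if (inherits(db, "emg_recording")) db <- list(db)
  nch <- vapply(db, function(r) ncol(r$samples), integer(1))
  if (length(unique(nch)) != 1L) {
    stop_param("all recordings must share one channel count")
  }
  nch <- nch[1L]
  blocks <- vector("list", length(db))
  metas <- vector("list", length(db))
  for (i in seq_along(db)) {
    rec <- db[[i]]
    if (is.null(wspec)) {
      i0 <- floor(trim_start * rec$fs) + 1L
      i1 <- nrow(rec$samples) - floor(trim_end * rec$fs)
      chans <- lapply(seq_len(nch), function(ch) {
        td_features(rec$samples[i0:i1, ch, drop = FALSE], predictors, opts)
      })
      metas[[i]] <- data.frame(subject = rec$subject,
                               movement = rec$movement,
                               repetition = rec$repetition, window = NA_integer_,
                               stringsAsFactors = FALSE)
    } else {
      ws <- segment(rec, wspec, trim_start, trim_end)
      idx <- outer(0:(ws$window_samples - 1L), ws$offsets, "+")
      chans <- lapply(seq_len(nch), function(ch) {
        W <- matrix(rec$samples[, ch][idx], nrow = ws$window_samples)
        td_features(W, predictors, opts)
      })
      metas[[i]] <- data.frame(subject = rec$subject,
                               movement = rec$movement,
                               repetition = rec$repetition,
                               window = seq_along(ws$offsets),
                               stringsAsFactors = FALSE)
    }
    blocks[[i]] <- do.call(cbind, chans)
  }
  values <- do.call(rbind, blocks)
  meta <- do.call(rbind, metas)
  rownames(values) <- NULL
  rownames(meta) <- NULL
  if (anyNA(values) || any(!is.finite(values))) {
    stop_param("non-finite feature values produced")
  }
  new_feature_matrix(values, nch, predictors, meta)
}

#' Keep a subset of feature columns
#'
#' @param fm A `feature_matrix`.
#' @param mask Logical or 0/1 vector over columns; at least one column must
#'   be kept. Order and labels of retained columns are preserved.
#' @return A `feature_matrix` with the masked columns. Since a column subset
#'   generally breaks the full channels x predictors grid, the result keeps
#'   explicit column names and records the selection in `$mask`.
#' @export
select_columns <- function(fm, mask) {
  mask <- as.logical(mask)
  if (length(mask) != ncol(fm$values)) {
    stop_param("mask length ", length(mask), " != ", ncol(fm$values),
               " columns")
  }
  if (!any(mask)) stop_param("mask selects no columns")
  out <- fm
  out$values <- fm$values[, mask, drop = FALSE]
  out$mask <- mask
  out
}

#' Drop whole predictors across all channels
#'
#' Removing `p` predictors from a `channels x predictors` layout removes
#' exactly `channels * p` columns.
#'
#' @param fm A `feature_matrix` with the full channel-major grid.
#' @param names Predictor abbreviations to drop.
#' @return A `feature_matrix` over the remaining predictors.
#' @export
drop_predictors <- function(fm, names) {
  unknown <- setdiff(names, fm$predictors)
  if (length(unknown)) {
    stop_param("predictors not present: ", paste(unknown, collapse = ", "))
  }
  keep <- !(fm$predictors %in% names)
  col_keep <- rep(keep, times = fm$channels)
  if (!any(col_keep)) stop_param("all predictors dropped")
  new_feature_matrix(fm$values[, col_keep, drop = FALSE], fm$channels,
                     fm$predictors[keep], fm$meta)
}

#' Write / read a feature matrix as CSV
#'
#' Layout: a two-row header (channel row, predictor row) over the feature
#' columns, preceded by the label columns `subject,movement,repetition,window`.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path.
#' @return `read_feature_matrix()` returns a `feature_matrix`;
#'   `write_feature_matrix()` returns `path` invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  labels <- c("subject", "movement", "repetition", "window")
  channel_row <- c(rep("", length(labels)),
                   paste0("ch", rep(seq_len(fm$channels),
                                    each = length(fm$predictors))))
  pred_row <- c(labels, rep(fm$predictors, times = fm$channels))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(channel_row, collapse = ","), con)
  writeLines(paste(pred_row, collapse = ","), con)
  body <- cbind(fm$meta$subject, fm$meta$movement, fm$meta$repetition,
                fm$meta$window,
                matrix(sprintf("%.12g", fm$values), nrow = nrow(fm$values)))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 3L) stop_format("feature matrix file too short: ", path)
  channel_row <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  pred_row <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  nlab <- sum(!nzchar(channel_row))
  channels <- unique(channel_row[nzchar(channel_row)])
  predictors <- unique(pred_row[-seq_len(nlab)])
  df <- read.csv(text = lines[-(1:2)], header = FALSE,
                 stringsAsFactors = FALSE)
  names(df) <- c(pred_row[seq_len(nlab)],
                 paste0(channel_row[-seq_len(nlab)], "_",
                        pred_row[-seq_len(nlab)]))
  meta <- df[, seq_len(nlab)]
  meta$window <- suppressWarnings(as.integer(meta$window))
  values <- as.matrix(df[, -seq_len(nlab)])
  new_feature_matrix(values, length(channels), predictors, meta)
}
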