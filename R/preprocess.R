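# Digital band-pass filtering and overlapping-window segmentation.

#' Band-pass filter specification
#'
#' Fourth-order digital Butterworth band-pass, 10--500 Hz by default. The
#' stated order is the realized order of the band-pass (a band-pass designed
#' from an order-`order/2` low-pass prototype), and the filter is applied as
#' a single causal pass, mirroring the analog acquisition chain it stands in
#' for.
#'
#' @param low_cut Lower cutoff in Hz (default 10).
#' @param high_cut Upper cutoff in Hz (default 500).
#' @param order Realized band-pass order; must be even (default 4).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 10, high_cut = 500, order = 4) {
  low_cut <- check_positive(low_cut, "low_cut")
  high_cut <- check_positive(high_cut, "high_cut")
  order <- check_count(order, "order", min = 2L)
  if (order %% 2L != 0L) stop_param("order must be even for a band-pass")
  if (low_cut >= high_cut) stop_param("low_cut must be < high_cut")
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order,
                 family = "butterworth"), class = "filter_spec")
}

# Butterworth band-pass coefficients at a given sampling rate. When the
# upper cutoff reaches Nyquist (e.g. 500 Hz at fs = 1 kHz) it is clipped to
# 0.99 * fs/2, with a warning unless suppressed.
butter_coefficients <- function(low_cut, high_cut, order, fs, warn = TRUE) {
  nyq <- fs / 2
  if (low_cut >= nyq) {
    stop_param("low_cut (", low_cut, " Hz) must be below Nyquist (", nyq,
               " Hz)")
  }
  if (high_cut >= nyq) {
    clipped <- 0.99 * nyq
    if (warn) {
      warning(sprintf(
        "high_cut %g Hz is at or above Nyquist (%g Hz); clipped to %g Hz",
        high_cut, nyq, clipped))
    }
    high_cut <- clipped
  }
  if (low_cut >= high_cut) {
    stop_param("cutoffs invalid after Nyquist clipping: ", low_cut, " >= ",
               high_cut, " Hz")
  }
  signal::butter(order / 2, c(low_cut, high_cut) / nyq, type = "pass")
}

#' Band-pass filter a recording
#'
#' Applies the causal Butterworth band-pass of `fspec` to every channel.
#' When the upper cutoff is at or above Nyquist it is clipped to
#' `0.99 * fs/2` with a warning.
#'
#' @param rec An `emg_recording`.
#' @param fspec A [filter_spec()].
#' @return The filtered recording (same shape and metadata).
#' @export
bandpass <- function(rec, fspec = filter_spec()) {
  if (!inherits(rec, "emg_recording")) stop_param("rec must be an emg_recording")
  if (!inherits(fspec, "filter_spec")) stop_param("fspec must be a filter_spec")
  bp <- butter_coefficients(fspec$low_cut, fspec$high_cut, fspec$order,
                            rec$fs)
  out <- rec
  for (ch in seq_len(ncol(rec$samples))) {
    out$samples[, ch] <- as.numeric(signal::filter(bp, rec$samples[, ch]))
  }
  out
}

#' Overlapping-window specification
#'
#' Defaults follow the standard myoelectric-control choice of 250 ms windows
#' with 190 ms overlap (60 ms step).
#'
#' @param length_ms Window duration in ms.
#' @param overlap_ms Overlap between consecutive windows in ms
#'   (`0 <= overlap_ms < length_ms`).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_ms = 250, overlap_ms = 190) {
  length_ms <- check_positive(length_ms, "length_ms")
  if (!is.numeric(overlap_ms) || overlap_ms < 0 || overlap_ms >= length_ms) {
    stop_param("overlap_ms must satisfy 0 <= overlap_ms < length_ms")
  }
  structure(list(length_ms = length_ms, overlap_ms = overlap_ms,
                 step_ms = length_ms - overlap_ms), class = "window_spec")
}

#' Number of full windows in a signal
#'
#' `floor((n - w) / s) + 1` for a signal of `n` samples, window of `w`
#' samples and step of `s` samples; trailing samples that do not fill a
#' window are discarded.
#'
#' @param n Signal length in samples.
#' @param w Window length in samples.
#' @param s Step in samples.
#' @return Integer window count (0 if `n < w`).
#' @export
n_windows <- function(n, w, s) {
  if (n < w) return(0L)
  as.integer(floor((n - w) / s) + 1L)
}

#' Segment a recording into overlapping windows
#'
#' Durations are converted to samples as `round(ms * fs / 1000)`. Optional
#' start/end trims (in seconds) restrict segmentation to the movement
#' portion of the recording.
#'
#' @param rec An `emg_recording`.
#' @param wspec A [window_spec()].
#' @param trim_start,trim_end Seconds discarded from the start / end before
#'   windowing (default 0).
#' @return An object of class `window_set`: window sample offsets (1-based
#'   start indices into the recording), window length and step in samples,
#'   and the source recording.
#' @export
segment <- function(rec, wspec = window_spec(), trim_start = 0,
                    trim_end = 0) {
  if (!inherits(rec, "emg_recording")) stop_param("rec must be an emg_recording")
  w <- round(wspec$length_ms * rec$fs / 1000)
  s <- round(wspec$step_ms * rec$fs / 1000)
  if (s < 1) stop_param("window step is below one sample at fs = ", rec$fs)
  i0 <- floor(trim_start * rec$fs) + 1L
  i1 <- nrow(rec$samples) - floor(trim_end * rec$fs)
  n <- i1 - i0 + 1L
  nw <- n_windows(n, w, s)
  if (nw < 1L) {
    stop_param("recording too short for one ", wspec$length_ms,
               " ms window (", n, " usable samples, ", w, " needed)")
  }
  offsets <- i0 + s * (seq_len(nw) - 1L)
  structure(list(offsets = as.integer(offsets), window_samples = as.integer(w),
                 step_samples = as.integer(s), recording = rec),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("Window set:", length(x$offsets), "windows of", x$window_samples,
      "samples (step", x$step_samples, ") over recording of",
      nrow(x$recording$samples), "samples\n")
  invisible(x)
}

#' Materialize one window of a window set
#'
#' @param ws A `window_set`.
#' @param i Window index.
#' @return A samples x channels matrix.
#' @export
get_window <- function(ws, i) {
  off <- ws$offsets[i]
  ws$recording$samples[off:(off + ws$window_samples - 1L), , drop = FALSE]
}
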