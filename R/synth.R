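#' Describe a synthetic surface-EMG database
#'
#' A `database_spec` fixes everything the synthetic generator needs: the
#' factorial design (subjects x movements x repetitions), the recording
#' geometry (channels, sampling rate, duration, initial rest period) and the
#' seed. The defaults emulate a lower-limb database: 8 subjects, six foot
#' movements plus rest, 20 repetitions, 4 bipolar channels sampled at 1 kHz
#' for 7 s with 1 s of initial rest.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param movements Character vector of movement-class labels. One of them
#'   may be the rest class (see `rest_label`).
#' @param n_reps Repetitions per subject and movement (>= 1).
#' @param n_channels Number of EMG channels (>= 1).
#' @param fs Sampling rate in Hz.
#' @param duration Recording length in seconds.
#' @param rest_lead Initial relaxation period in seconds (`< duration`);
#'   muscle activation starts after it.
#' @param rest_label Label of the movement class that stays at baseline for
#'   the whole recording, or `NA` if there is none.
#' @param seed Integer seed; the same spec with the same seed yields a
#'   bit-identical database.
#' @return An object of class `database_spec`.
#' @seealso [generate_database()]
#' @export
database_spec <- function(n_subjects = 8,
                          movements = c("AP", "AT", "LP", "LT", "PD", "PI",
                                        "RR"),
                          n_reps = 20,
                          n_channels = 4,
                          fs = 1000,
                          duration = 7,
                          rest_lead = 1,
                          rest_label = "RR",
                          seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_reps <- check_count(n_reps, "n_reps")
  n_channels <- check_count(n_channels, "n_channels")
  fs <- check_positive(fs, "fs")
  duration <- check_positive(duration, "duration")
  if (!is.character(movements) || length(movements) < 1L ||
      anyDuplicated(movements)) {
    stop_param("movements must be distinct class labels")
  }
  if (!is.numeric(rest_lead) || rest_lead < 0 || rest_lead >= duration) {
    stop_param("rest_lead must satisfy 0 <= rest_lead < duration")
  }
  structure(list(n_subjects = n_subjects, movements = movements,
                 n_reps = n_reps, n_channels = n_channels, fs = fs,
                 duration = duration, rest_lead = rest_lead,
                 rest_label = rest_label, seed = as.integer(seed)),
            class = "database_spec")
}

#' @export
print.database_spec <- function(x, ...) {
  cat("Synthetic EMG database spec:",
      x$n_subjects, "subjects x", length(x$movements), "movements x",
      x$n_reps, "reps;", x$n_channels, "channels @", x$fs, "Hz,",
      x$duration, "s (rest lead", x$rest_lead, "s), seed", x$seed, "\n")
  invisible(x)
}

# Fixed class -> channel activation map. Each non-rest class drives a primary
# channel at full gain, its neighbour at 0.4 and the rest at 0.1, so classes
# are separable from channel envelopes alone.
activation_map <- function(movements, n_channels, rest_label) {
  A <- matrix(0.1, nrow = length(movements), ncol = n_channels,
              dimnames = list(movements, NULL))
  active <- setdiff(movements, rest_label)
  for (i in seq_along(active)) {
    prim <- 1L + (i - 1L) %% n_channels
    sec <- 1L + prim %% n_channels
    A[active[i], prim] <- 1
    A[active[i], sec] <- 0.4
  }
  if (!is.na(rest_label) && rest_label %in% movements) {
    A[rest_label, ] <- 0
  }
  A
}

# Trapezoidal activation envelope: 0 during the rest lead, then a ramp up,
# plateau, ramp down ending at the last sample.
trapezoid_envelope <- function(n, fs, rest_lead, ramp = 0.25) {
  env <- numeric(n)
  i0 <- floor(rest_lead * fs) + 1L
  if (i0 > n) return(env)
  len <- n - i0 + 1L
  nr <- min(round(ramp * fs), floor(len / 3))
  env[i0:n] <- 1
  if (nr > 0) {
    up <- seq_len(nr) / nr
    env[i0 - 1L + seq_len(nr)] <- up
    env[n - nr + seq_len(nr)] <- rev(up)
  }
  env
}

new_recording <- function(samples, fs, subject, movement, repetition) {
  structure(list(samples = samples, fs = fs, subject = subject,
                 movement = movement, repetition = repetition),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("EMG recording: subject", x$subject, "movement", x$movement,
      "rep", x$repetition, "-", nrow(x$samples), "samples x",
      ncol(x$samples), "channels @", x$fs, "Hz\n")
  invisible(x)
}

#' Generate a seeded synthetic EMG database
#'
#' Produces `n_subjects * length(movements) * n_reps` recordings. Each
#' channel is zero-mean Gaussian noise band-limited to 10--500 Hz (clipped
#' below Nyquist), amplitude-modulated by a trapezoidal activation envelope
#' during the movement phase. Activation strength per (class, channel)
#' follows a fixed map; a per-subject log-normal gain (sd 0.1 on the log
#' scale) and a smaller per-repetition gain (sd 0.05) add realistic
#' between-subject and between-trial variability. The rest class stays at
#' baseline amplitude throughout; every class emits low-level baseline noise
#' so no channel is ever exactly silent.
#'
#' @param spec A [database_spec()].
#' @return An object of class `emg_database`: a list of `emg_recording`
#'   objects (subject-major, then movement, then repetition order) with the
#'   spec attached as an attribute.
#' @examples
#' db <- generate_database(database_spec(n_subjects = 1, n_reps = 1,
#'                                       duration = 1, rest_lead = 0.2))
#' length(db)
#' @export
generate_database <- function(spec) {
  if (!inherits(spec, "database_spec")) {
    stop_param("spec must be a database_spec object")
  }
  n <- round(spec$fs * spec$duration)
  A <- activation_map(spec$movements, spec$n_channels, spec$rest_label)
  env <- trapezoid_envelope(n, spec$fs, spec$rest_lead)
  bp <- butter_coefficients(10, 500, order = 4, fs = spec$fs, warn = FALSE)
  baseline <- 0.05
  recs <- with_seed(spec$seed, {
    subj_gain <- exp(rnorm(spec$n_subjects, 0, 0.1))
    out <- vector("list",
                  spec$n_subjects * length(spec$movements) * spec$n_reps)
    k <- 0L
    for (s in seq_len(spec$n_subjects)) {
      for (m in spec$movements) {
        for (r in seq_len(spec$n_reps)) {
          rep_gain <- exp(rnorm(1, 0, 0.05))
          samples <- matrix(0, nrow = n, ncol = spec$n_channels)
          for (ch in seq_len(spec$n_channels)) {
            noise <- as.numeric(
              signal::filter(bp, rnorm(n)))
            amp <- baseline + A[m, ch] * env * subj_gain[s] * rep_gain
            samples[, ch] <- noise * amp
          }
          colnames(samples) <- paste0("ch", seq_len(spec$n_channels))
          k <- k + 1L
          out[[k]] <- new_recording(samples, spec$fs, s, m, r)
        }
      }
    }
    out
  })
  structure(recs, class = "emg_database", spec = spec)
}

#' @export
print.emg_database <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("Synthetic EMG database:", length(x), "recordings\n")
  if (!is.null(spec)) print(spec)
  invisible(x)
}

#' Database metadata table
#'
#' @param db An `emg_database` or list of `emg_recording` objects.
#' @return A data frame with one row per recording: subject, movement,
#'   repetition and sampling rate.
#' @export
database_metadata <- function(db) {
  data.frame(
    subject = vapply(db, function(r) r$subject, numeric(1)),
    movement = vapply(db, function(r) as.character(r$movement), character(1)),
    repetition = vapply(db, function(r) r$repetition, numeric(1)),
    fs = vapply(db, function(r) r$fs, numeric(1)),
    stringsAsFactors = FALSE)
}
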