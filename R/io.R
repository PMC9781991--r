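# Delimited-text I/O for recordings, databases and feature matrices.
# Recordings are plain CSV (one column per channel, '.' decimal, UTF-8) with
# the trial metadata carried either in commented header lines ("# key=value",
# single-file form) or in a companion metadata CSV (database form).

#' Write / read a single EMG recording as CSV
#'
#' The file starts with commented metadata lines (`# subject=...`,
#' `# movement=...`, `# repetition=...`, `# fs=...`), followed by a header
#' row naming the channels and one row per sample. Amplitudes are written
#' with 12 significant digits, so a round trip preserves them well within
#' 1e-9.
#'
#' @param rec An `emg_recording`.
#' @param path File path to write to / read from.
#' @return `read_recording()` returns an `emg_recording`;
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "emg_recording")) stop_param("rec must be an emg_recording")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# subject=", rec$subject),
               paste0("# movement=", rec$movement),
               paste0("# repetition=", rec$repetition),
               paste0("# fs=", format(rec$fs, digits = 12))), con)
  ch <- colnames(rec$samples) %||% paste0("ch", seq_len(ncol(rec$samples)))
  writeLines(paste(ch, collapse = ","), con)
  body <- apply(rec$samples, 1L,
                function(row) paste(sprintf("%.12g", row), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) stop_format("empty recording file: ", path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", lines[ml])
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) {
    stop_format("recording file has no data rows: ", path)
  }
  fields <- strsplit(body, ",", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld != nfld[1L])) {
    bad <- which(nfld != nfld[1L])[1L]
    stop_format("unequal column counts in ", path, " at data line ", bad)
  }
  header <- fields[[1L]]
  vals <- suppressWarnings(
    vapply(fields[-1L], function(f) as.numeric(f), numeric(nfld[1L])))
  samples <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = nfld[1L])
  if (anyNA(samples)) {
    bad <- which(apply(is.na(samples), 1L, any))[1L]
    stop_format("non-numeric value in ", path, " at data line ", bad + 1L)
  }
  colnames(samples) <- header
  new_recording(samples,
                fs = as.numeric(meta$fs %||% NA),
                subject = meta$subject %||% NA,
                movement = meta$movement %||% NA,
                repetition = as.numeric(meta$repetition %||% NA))
}

#' Write / read a whole database directory
#'
#' Each recording goes to `rec_NNNN.csv` (header row + samples, no comment
#' lines) and a companion `metadata.csv` lists
#' `file,subject,movement,repetition,fs`.
#'
#' @param db An `emg_database` or list of `emg_recording`s.
#' @param dir Directory (created if needed).
#' @return `read_database()` returns a list of `emg_recording`s with class
#'   `emg_database`; `write_database()` returns `dir` invisibly.
#' @export
write_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("rec_%04d.csv", seq_along(db))
  for (i in seq_along(db)) {
    rec <- db[[i]]
    df <- as.data.frame(rec$samples)
    write.csv(df, file.path(dir, files[i]), row.names = FALSE)
  }
  meta <- cbind(file = files, database_metadata(db))
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_database
#' @export
read_database <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop_format("no metadata.csv in ", dir)
  }
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("file", "subject", "movement", "repetition", "fs")
  if (!all(need %in% names(meta))) {
    stop_format("metadata.csv must have columns ",
                paste(need, collapse = ","))
  }
  recs <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    df <- read.csv(file.path(dir, meta$file[i]))
    recs[[i]] <- new_recording(as.matrix(df), fs = meta$fs[i],
                               subject = meta$subject[i],
                               movement = meta$movement[i],
                               repetition = meta$repetition[i])
  }
  structure(recs, class = "emg_database")
}
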