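# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_param <- function(...) {
  stop(structure(class = c("emg_parameter_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("emg_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop_param(name, " must be a single integer >= ", min)
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_param(name, " must be a single positive number")
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
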