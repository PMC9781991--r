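# Shared fixtures, all built in code.

# A small synthetic database: 2 subjects x (2 movements + rest) x 3 reps,
# 2 channels at 500 Hz, 1 s with 0.2 s rest lead.
tiny_db <- function(seed = 42) {
  generate_database(database_spec(
    n_subjects = 2, movements = c("A", "B", "RR"), n_reps = 3,
    n_channels = 2, fs = 500, duration = 1, rest_lead = 0.2,
    rest_label = "RR", seed = seed))
}

# Gaussian class clouds: k classes at distinct (non-collinear) corners of
# the informative subspace, scaled by `sep`; pure noise on the rest. The
# corners keep every class linearly separable one-vs-rest.
toy_classes <- function(n_per_class = 20, k = 3, informative = 2, noise = 2,
                        sep = 4, seed = 1) {
  x <- NULL
  y <- rep(paste0("c", seq_len(k)), each = n_per_class)
  set.seed(seed)
  for (cl in seq_len(k)) {
    corner <- sep * as.integer(intToBits(cl))[seq_len(informative)]
    block <- cbind(
      sweep(matrix(rnorm(n_per_class * informative), n_per_class), 2,
            corner, "+"),
      matrix(rnorm(n_per_class * noise), n_per_class))
    x <- rbind(x, block)
  }
  colnames(x) <- c(paste0("inf", seq_len(informative)),
                   paste0("nse", seq_len(noise)))
  list(x = x, y = y)
}

# Feature-matrix wrapper around arbitrary values, one channel.
fm_from_matrix <- function(x, y, predictors = colnames(x)) {
  as_feature_matrix(x, channels = 1, predictors = predictors,
                    meta = data.frame(movement = y))
}

# Steady-state amplitude of a (near-)sinusoidal tail segment.
steady_amplitude <- function(x, tail_frac = 0.3) {
  tail_x <- x[seq.int(floor(length(x) * (1 - tail_frac)) + 1L, length(x))]
  sqrt(2) * sqrt(mean(tail_x^2))
}
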