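# Binary simple genetic algorithm minimizing the cross-validated SVM mean
# error over feature masks: roulette-wheel selection, two-point crossover,
# uniform mutation, elitism of one.

#' Genetic-algorithm configuration
#'
#' @param n_genes Mask length (number of feature columns).
#' @param pop_size Population size (>= 2, default 100).
#' @param mutation_rate Per-gene flip probability (default 0.02).
#' @param max_iterations Generation cap (default 100).
#' @param crossover_rate Probability that a selected pair is crossed
#'   (default 1, the simple-GA convention).
#' @param elitism Number of best chromosomes copied unchanged into the next
#'   generation (default 1; guarantees a monotone best-fitness history).
#' @param target_error Optional early-stop threshold on the best CV error
#'   (default `NULL`, disabled).
#' @param seed Integer seed for the whole run (initial population, operator
#'   draws, and the CV fold assignment).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(n_genes, pop_size = 100, mutation_rate = 0.02,
                      max_iterations = 100, crossover_rate = 1,
                      elitism = 1, target_error = NULL, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  pop_size <- check_count(pop_size, "pop_size", min = 2L)
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop_param("mutation_rate must be in [0, 1]")
  }
  max_iterations <- check_count(max_iterations, "max_iterations")
  structure(list(n_genes = n_genes, pop_size = pop_size,
                 mutation_rate = mutation_rate,
                 max_iterations = max_iterations,
                 crossover_rate = crossover_rate,
                 elitism = check_count(elitism, "elitism", min = 0L),
                 target_error = target_error, seed = as.integer(seed),
                 selection = "roulette", crossover = "two-point",
                 mutation = "uniform"),
            class = "ga_config")
}

#' Roulette-wheel parent selection
#'
#' Samples chromosome indices with probability proportional to the given
#' non-negative selection weights (with replacement). `run_ga()` converts
#' errors to weights as `(max_error - error) + 1e-6`, so lower error means
#' higher weight.
#'
#' @param weights Non-negative selection weights, one per chromosome.
#' @param n Number of parents to draw (default 2).
#' @return Integer vector of selected indices.
#' @export
roulette_select <- function(weights, n = 2L) {
  if (any(is.na(weights)) || any(weights < 0)) {
    stop_param("selection weights must be non-negative and evaluated")
  }
  if (length(weights) == 1L) return(rep(1L, n))
  if (sum(weights) <= 0) weights <- rep(1, length(weights))
  sample.int(length(weights), n, replace = TRUE, prob = weights)
}

# Minimization transform: low error -> high weight.
roulette_weights <- function(errors, eps = 1e-6) {
  (max(errors) - errors) + eps
}

#' Two-point crossover
#'
#' Picks cut points `0 <= i < j <= n` uniformly and swaps the gene segment
#' `(i, j]` between the parents; genes outside the cut are preserved.
#'
#' @param p1,p2 Parent gene vectors (equal length >= 2).
#' @return List of two offspring vectors, with the cut points as attribute
#'   `cuts`.
#' @export
two_point_crossover <- function(p1, p2) {
  n <- length(p1)
  if (length(p2) != n) stop_param("parents must have equal gene length")
  if (n < 2L) stop_param("crossover needs at least 2 genes")
  cuts <- sort(sample.int(n + 1L, 2L, replace = FALSE) - 1L)
  o1 <- p1; o2 <- p2
  if (cuts[2L] > cuts[1L]) {
    seg <- (cuts[1L] + 1L):cuts[2L]
    o1[seg] <- p2[seg]
    o2[seg] <- p1[seg]
  }
  structure(list(o1, o2), cuts = cuts)
}

#' Uniform bit-flip mutation
#'
#' Each gene flips independently with probability `rate`.
#'
#' @param genes Binary gene vector.
#' @param rate Per-gene flip probability in `[0, 1]`.
#' @return Mutated gene vector.
#' @export
uniform_mutation <- function(genes, rate) {
  if (rate < 0 || rate > 1) stop_param("rate must be in [0, 1]")
  flip <- runif(length(genes)) < rate
  out <- genes
  out[flip] <- 1L - out[flip]
  out
}

#' Run the genetic algorithm over feature masks
#'
#' Minimizes the stratified k-fold cross-validated mean error of the
#' one-vs-all SVM trained on the masked feature columns. Each generation:
#' the elite chromosome(s) are copied unchanged; the remaining slots are
#' filled by roulette-selected pairs, two-point crossover (with probability
#' `crossover_rate`) and uniform mutation. All-zero chromosomes score error
#' 1 without an SVM fit. Fitness values are cached by gene vector. The run
#' stops at `max_iterations` or as soon as the best error reaches
#' `target_error`.
#'
#' @param x Feature matrix (`feature_matrix` or numeric matrix).
#' @param y Class labels (taken from `x` when it is a `feature_matrix`).
#' @param spec An [svm_spec()] used for the fitness.
#' @param config A [ga_config()]; `config$n_genes` must equal the number of
#'   feature columns.
#' @param k CV fold count for the fitness (default 10).
#' @return A `selection_run` with the best mask, its fitness, and the
#'   best-so-far fitness per generation (non-increasing under elitism).
#' @export
run_ga <- function(x, y = NULL, spec = svm_spec(), config, k = 10) {
  if (!inherits(config, "ga_config")) stop_param("config must be a ga_config")
  d <- resolve_xy(x, y)
  if (config$n_genes != ncol(d$x)) {
    stop_param("config$n_genes (", config$n_genes,
               ") must equal feature columns (", ncol(d$x), ")")
  }
  fit <- make_mask_fitness(d$x, d$y, spec, k, cv_seed = config$seed)
  with_seed(config$seed, {
    pop <- matrix(rbinom(config$pop_size * config$n_genes, 1L, 0.5),
                  nrow = config$pop_size)
    history <- numeric(0)
    best_mask <- NULL
    best_err <- Inf
    for (gen in seq_len(config$max_iterations)) {
      errs <- apply(pop, 1L, function(g) fit(as.logical(g)))
      gen_best <- which.min(errs)
      if (errs[gen_best] < best_err) {
        best_err <- errs[gen_best]
        best_mask <- pop[gen_best, ]
      }
      history <- c(history, best_err)
      if (!is.null(config$target_error) &&
          best_err <= config$target_error) break
      if (gen == config$max_iterations) break
      # next generation: elites first, then offspring of roulette pairs
      ord <- order(errs)
      nxt <- matrix(0L, nrow = config$pop_size, ncol = config$n_genes)
      n_elite <- min(config$elitism, config$pop_size)
      if (n_elite > 0) nxt[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], ]
      w <- roulette_weights(errs)
      slot <- n_elite + 1L
      while (slot <= config$pop_size) {
        par <- roulette_select(w, 2L)
        c1 <- pop[par[1L], ]; c2 <- pop[par[2L], ]
        if (runif(1) < config$crossover_rate) {
          off <- two_point_crossover(c1, c2)
          c1 <- off[[1L]]; c2 <- off[[2L]]
        }
        nxt[slot, ] <- uniform_mutation(c1, config$mutation_rate)
        if (slot + 1L <= config$pop_size) {
          nxt[slot + 1L, ] <- uniform_mutation(c2, config$mutation_rate)
        }
        slot <- slot + 2L
      }
      pop <- nxt
    }
    new_selection_run("ga", as.logical(best_mask), best_err, history,
                      attr(fit, "n_evals")(), config, colnames(d$x))
  })
}
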