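# Binary particle swarm optimization of feature masks. Velocities follow
# the canonical inertia/cognitive/social update; a sigmoid transfer maps
# each velocity component to the probability of setting the corresponding
# bit.

#' Binary-PSO configuration
#'
#' @param n_genes Mask length (number of feature columns).
#' @param n_particles Swarm size (default 10).
#' @param w Inertia weight (default 0.9).
#' @param c1 Cognitive learning factor (default 2).
#' @param c2 Social learning factor (default 2).
#' @param max_iterations Iteration cap (default 100).
#' @param v_clamp Componentwise velocity bound (default 6; the sigmoid is
#'   within 0.0025 of saturation at +/-6).
#' @param target_error Optional early-stop threshold on the global-best CV
#'   error.
#' @param seed Integer seed for the whole run.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(n_genes, n_particles = 10, w = 0.9, c1 = 2, c2 = 2,
                       max_iterations = 100, v_clamp = 6,
                       target_error = NULL, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_particles <- check_count(n_particles, "n_particles")
  if (w < 0 || c1 < 0 || c2 < 0) stop_param("w, c1, c2 must be >= 0")
  max_iterations <- check_count(max_iterations, "max_iterations")
  v_clamp <- check_positive(v_clamp, "v_clamp")
  structure(list(n_genes = n_genes, n_particles = n_particles, w = w,
                 c1 = c1, c2 = c2, max_iterations = max_iterations,
                 v_clamp = v_clamp, target_error = target_error,
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' Sigmoid transfer from velocity to bit probability
#'
#' `S(v) = 1 / (1 + exp(-v))`: strictly increasing, `S(0) = 0.5`,
#' saturating at 0 and 1.
#'
#' @param v Numeric velocity (vectorized).
#' @return Probabilities in (0, 1).
#' @export
bpso_transfer <- function(v) 1 / (1 + exp(-v))

#' One binary-PSO velocity update
#'
#' `v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with fresh uniform
#' `r1`, `r2` vectors drawn per dimension, clamped componentwise to
#' `[-v_clamp, v_clamp]`.
#'
#' @param v Current velocity vector.
#' @param x Current binary position.
#' @param pbest Personal best position.
#' @param gbest Global best position.
#' @param w,c1,c2 Inertia, cognitive and social factors.
#' @param v_clamp Componentwise bound.
#' @return Updated velocity vector.
#' @export
bpso_update_velocity <- function(v, x, pbest, gbest, w = 0.9, c1 = 2,
                                 c2 = 2, v_clamp = 6) {
  n <- length(v)
  r1 <- runif(n)
  r2 <- runif(n)
  vn <- w * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)
  pmin(pmax(vn, -v_clamp), v_clamp)
}

#' One binary-PSO position update
#'
#' Each bit is set to 1 iff `S(v) > r3` for a fresh per-dimension uniform
#' draw `r3`.
#'
#' @param v Velocity vector (already updated).
#' @return Binary position vector.
#' @export
bpso_update_position <- function(v) {
  as.integer(bpso_transfer(v) > runif(length(v)))
}

#' Run binary PSO over feature masks
#'
#' Minimizes the same cached cross-validated fitness as [run_ga()].
#' Positions initialize as Bernoulli(0.5) bits with zero velocities; each
#' iteration updates every particle's velocity and position, re-evaluates
#' fitness, and updates personal and global bests. The global best is only
#' ever replaced by a strictly better mask, so its history is monotone
#' non-increasing. All-zero positions score error 1 without an SVM fit.
#'
#' @param x Feature matrix (`feature_matrix` or numeric matrix).
#' @param y Class labels (taken from `x` when it is a `feature_matrix`).
#' @param spec An [svm_spec()] used for the fitness.
#' @param config A [pso_config()]; `config$n_genes` must equal the number
#'   of feature columns.
#' @param k CV fold count for the fitness (default 10).
#' @return A `selection_run` with the global-best mask, its fitness, and
#'   the gbest fitness per iteration.
#' @export
run_pso <- function(x, y = NULL, spec = svm_spec(), config, k = 10) {
  if (!inherits(config, "pso_config")) stop_param("config must be a pso_config")
  d <- resolve_xy(x, y)
  if (config$n_genes != ncol(d$x)) {
    stop_param("config$n_genes (", config$n_genes,
               ") must equal feature columns (", ncol(d$x), ")")
  }
  fit <- make_mask_fitness(d$x, d$y, spec, k, cv_seed = config$seed)
  with_seed(config$seed, {
    np <- config$n_particles
    X <- matrix(rbinom(np * config$n_genes, 1L, 0.5), nrow = np)
    V <- matrix(0, nrow = np, ncol = config$n_genes)
    perr <- apply(X, 1L, function(g) fit(as.logical(g)))
    pbest <- X
    g_idx <- which.min(perr)
    gbest <- X[g_idx, ]
    gerr <- perr[g_idx]
    history <- numeric(0)
    for (it in seq_len(config$max_iterations)) {
      for (i in seq_len(np)) {
        V[i, ] <- bpso_update_velocity(V[i, ], X[i, ], pbest[i, ], gbest,
                                       config$w, config$c1, config$c2,
                                       config$v_clamp)
        X[i, ] <- bpso_update_position(V[i, ])
        err <- fit(as.logical(X[i, ]))
        if (err < perr[i]) {
          perr[i] <- err
          pbest[i, ] <- X[i, ]
        }
        if (err < gerr) {
          gerr <- err
          gbest <- X[i, ]
        }
      }
      history <- c(history, gerr)
      if (!is.null(config$target_error) && gerr <= config$target_error) break
    }
    new_selection_run("pso", as.logical(gbest), gerr, history,
                      attr(fit, "n_evals")(), config, colnames(d$x))
  })
}
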