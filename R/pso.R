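#' Swarm configuration
#'
#' Defaults follow the reference tuning setup: learning factors
#' `c1 = c2 = 2`, inertia decayed linearly from `q_max = 0.9` to
#' `q_min = 0.4`, and search box `epsilon in (0, 0.2)`, `C in (1, 100)`,
#' `phi in (0.01, 2.0)`. Velocities are clamped per dimension at
#' `v_max = 0.2 * (hi - lo)`.
#'
#' @param n_particles swarm size (default 30).
#' @param n_iters number of iterations (default 100).
#' @param c1,c2 cognitive and social learning factors.
#' @param q_max,q_min inertia bounds (`q_max >= q_min`).
#' @param bounds 2 x d matrix (`rbind(lo, hi)`), one column per searched
#'   dimension, optionally with column names.
#' @param v_max per-dimension velocity cap; default `0.2 * (hi - lo)`.
#' @param seed RNG seed used by [pso_optimize()].
#' @return a `swarm_config` list.
#' @export
swarm_config <- function(n_particles = 30L, n_iters = 100L, c1 = 2, c2 = 2,
                         q_max = 0.9, q_min = 0.4,
                         bounds = default_param_bounds(), v_max = NULL,
                         seed = 1L) {
  stopifnot(q_max >= q_min, is.matrix(bounds), nrow(bounds) == 2L,
            all(bounds[1, ] < bounds[2, ]), n_particles >= 1, n_iters >= 1)
  if (is.null(v_max)) v_max <- 0.2 * (bounds[2, ] - bounds[1, ])
  structure(list(n_particles = as.integer(n_particles),
                 n_iters = as.integer(n_iters), c1 = c1, c2 = c2,
                 q_max = q_max, q_min = q_min, bounds = bounds,
                 v_max = v_max, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Default (epsilon, C, phi) search box
#' @return 2 x 3 matrix of bounds.
#' @export
default_param_bounds <- function() {
  b <- rbind(lo = c(0, 1, 0.01), hi = c(0.2, 100, 2.0))
  colnames(b) <- c("epsilon", "C", "phi")
  b
}

#' Inertia factor at a given iteration
#'
#' Linear decay from `q_max` at the first iteration to `q_min` at the last:
#' `q = q_max - (q_max - q_min) * iter / (n_iters - 1)` with 0-based `iter`.
#' With fewer than two iterations the inertia is constant at `q_max`.
#'
#' @param iter 0-based iteration index.
#' @param config a [swarm_config()].
#' @return inertia weight.
#' @export
inertia <- function(iter, config) {
  stopifnot(iter >= 0, iter < config$n_iters)
  if (config$n_iters < 2L) return(config$q_max)
  config$q_max - (config$q_max - config$q_min) * iter / (config$n_iters - 1)
}

init_swarm <- function(fitness, config) {
  d <- ncol(config$bounds)
  lo <- config$bounds[1, ]
  hi <- config$bounds[2, ]
  pos <- t(replicate(config$n_particles, stats::runif(d, lo, hi)))
  vel <- t(replicate(config$n_particles,
                     stats::runif(d, -config$v_max, config$v_max)))
  fit <- apply(pos, 1L, fitness)
  list(position = pos, velocity = vel, best_position = pos,
       best_fitness = fit)
}

#' One particle-swarm update step
#'
#' Applies the velocity rule
#' `v <- q v + c1 r1 (p_best - x) + c2 r2 (g_best - x)` with `r1, r2`
#' uniform on `[0, 1]` drawn independently per particle and dimension,
#' clamps the velocity to `±v_max`, moves `x <- x + v`, clamps the position
#' to the bounds, re-evaluates fitness and updates personal bests. A
#' particle whose fitness evaluates non-finite is re-initialized uniformly
#' inside the bounds with a warning.
#'
#' @param swarm state list from [init_swarm] or a previous step.
#' @param g_best current global best position (numeric vector).
#' @param iter 0-based iteration index (drives the inertia schedule).
#' @param config a [swarm_config()].
#' @param fitness the objective function, lower is better.
#' @return updated swarm state list.
#' @export
pso_step <- function(swarm, g_best, iter, config, fitness) {
  q <- inertia(iter, config)
  lo <- config$bounds[1, ]
  hi <- config$bounds[2, ]
  np <- nrow(swarm$position)
  d <- ncol(swarm$position)
  for (i in seq_len(np)) {
    r1 <- stats::runif(d)
    r2 <- stats::runif(d)
    v <- q * swarm$velocity[i, ] +
      config$c1 * r1 * (swarm$best_position[i, ] - swarm$position[i, ]) +
      config$c2 * r2 * (g_best - swarm$position[i, ])
    v <- pmin(pmax(v, -config$v_max), config$v_max)
    x <- pmin(pmax(swarm$position[i, ] + v, lo), hi)
    f <- fitness(x)
    if (!is.finite(f)) {
      warning("non-finite fitness; particle re-initialized")
      x <- stats::runif(d, lo, hi)
      v <- numeric(d)
      f <- fitness(x)
    }
    swarm$velocity[i, ] <- v
    swarm$position[i, ] <- x
    if (f < swarm$best_fitness[i]) {
      swarm$best_fitness[i] <- f
      swarm$best_position[i, ] <- x
    }
  }
  swarm
}

#' Particle swarm optimization over a bounded box
#'
#' Runs `n_iters` steps of [pso_step()] from a seeded uniform
#' initialization and returns the global best. The per-iteration best
#' fitness history is non-increasing by construction.
#'
#' @param fitness objective function mapping a parameter vector (length =
#'   `ncol(config$bounds)`) to a scalar, lower is better.
#' @param config a [swarm_config()].
#' @return list with `best_position` (named like the bounds columns),
#'   `best_fitness` and `history` (best fitness after each iteration).
#' @export
pso_optimize <- function(fitness, config = swarm_config()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  swarm <- init_swarm(fitness, config)
  gi <- which.min(swarm$best_fitness)
  g_best <- swarm$best_position[gi, ]
  g_fit <- swarm$best_fitness[gi]
  history <- numeric(config$n_iters)
  for (iter in seq_len(config$n_iters) - 1L) {
    swarm <- pso_step(swarm, g_best, iter, config, fitness)
    gi <- which.min(swarm$best_fitness)
    if (swarm$best_fitness[gi] < g_fit) {
      g_fit <- swarm$best_fitness[gi]
      g_best <- swarm$best_position[gi, ]
    }
    history[iter + 1L] <- g_fit
  }
  names(g_best) <- colnames(config$bounds)
  list(best_position = g_best, best_fitness = g_fit, history = history)
}

#' Cross-validated reconstruction fitness for SVR hyperparameters
#'
#' Builds the objective minimized when tuning `(epsilon, C, phi)`: genes are
#' split into `k_folds` folds (seeded, so the split is fixed across fitness
#' evaluations); for a candidate parameter triple, per-sample SVR
#' coefficients are fit on the training genes of each fold and the fitness
#' is the mean across folds of the RMSE between held-out gene expression
#' and its reconstruction `S_heldout %*% w` (raw regression coefficients —
#' the simplex mapping is a reporting step, not part of the regression, and
#' would spoil the reconstruction's scale). Both matrices are aligned and
#' z-scored once up front.
#'
#' @param X mixture matrix (genes x samples, rownames = gene ids).
#' @param S signature matrix (genes x cell types, rownames = gene ids).
#' @param k_folds number of gene folds (>= 2).
#' @param seed seed fixing the fold assignment.
#' @return a function `params_vec -> fitness` where `params_vec` is
#'   `c(epsilon, C, phi)`.
#' @export
deconv_fitness_factory <- function(X, S, k_folds = 5L, seed = 1L) {
  stopifnot(k_folds >= 2L)
  al <- align_and_normalize(X, S)
  n <- nrow(al$S)
  m <- ncol(al$S)
  if (n < k_folds || floor(n * (1 - 1 / k_folds)) < m) {
    stop("not enough genes for ", k_folds, "-fold tuning")
  }
  fold <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    sample(rep_len(seq_len(k_folds), n))
  })
  function(p) {
    params <- svr_params(epsilon = p[[1]], C = p[[2]], phi = p[[3]])
    errs <- vapply(seq_len(k_folds), function(kf) {
      tr <- fold != kf
      res <- vapply(seq_len(ncol(al$X)), function(j) {
        w <- svr_solve(al$X[tr, j], al$S[tr, , drop = FALSE], params)
        pred <- al$S[!tr, , drop = FALSE] %*% w
        mean((al$X[!tr, j] - pred)^2)
      }, 0)
      sqrt(mean(res))
    }, 0)
    mean(errs)
  }
}

#' Tune SVR hyperparameters by particle swarm
#'
#' Convenience wrapper: builds the cross-validation fitness for `(X, S)` and
#' searches the default `(epsilon, C, phi)` box. The penalty `C` is searched
#' on a log10 scale internally (its plausible range spans orders of
#' magnitude) and reported on the natural scale.
#'
#' @param X,S mixture and signature matrices.
#' @param config a [swarm_config()] on the natural scale; its `C` bounds are
#'   log-transformed internally.
#' @param k_folds,seed passed to [deconv_fitness_factory()].
#' @return list with `params` (an [svr_params()]), `best_fitness`,
#'   `history`.
#' @export
tune_svr <- function(X, S, config = swarm_config(), k_folds = 5L,
                     seed = config$seed) {
  fit_nat <- deconv_fitness_factory(X, S, k_folds = k_folds, seed = seed)
  b <- config$bounds
  ci <- match("C", colnames(b))
  stopifnot(!is.na(ci))
  b_int <- b
  b_int[, ci] <- log10(b[, ci])
  cfg <- swarm_config(n_particles = config$n_particles,
                      n_iters = config$n_iters, c1 = config$c1,
                      c2 = config$c2, q_max = config$q_max,
                      q_min = config$q_min, bounds = b_int,
                      seed = config$seed)
  to_nat <- function(p) { p[ci] <- 10^p[ci]; p }
  res <- pso_optimize(function(p) fit_nat(to_nat(p)), cfg)
  best <- to_nat(res$best_position)
  list(params = svr_params(epsilon = best[["epsilon"]], C = best[["C"]],
                           phi = best[["phi"]]),
       best_fitness = res$best_fitness, history = res$history)
}
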