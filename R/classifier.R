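#' Elastic-net logistic regression configuration
#'
#' The fitted objective is the penalized negative mean log-likelihood
#' `-(1/n) sum_i [ y_i (b0 + x_i' b) - log(1 + exp(b0 + x_i' b)) ]
#'  + mu * ( (1 - alpha) ||b||_2^2 / 2 + alpha ||b||_1 )`,
#' mixing ridge (`alpha = 0`) and lasso (`alpha = 1`). The intercept is
#' never penalized. When `mu = NULL`, it is chosen by `cv_folds`-fold
#' cross-validated deviance over a log-spaced grid.
#'
#' @param mu overall penalty weight (>= 0) or `NULL` for CV selection.
#' @param alpha L1/L2 mixing in `[0, 1]` (default 0.5).
#' @param max_iter,tol proximal-gradient iteration budget and objective
#'   convergence tolerance.
#' @param train_fraction fraction of samples used for training in
#'   [evaluate_three_cases()] (default 0.75).
#' @param cv_folds folds used when `mu` is selected by cross-validation.
#' @param mu_grid penalty grid for CV (log-spaced by default).
#' @param seed RNG seed for splits.
#' @return an `en_config` list.
#' @export
en_config <- function(mu = NULL, alpha = 0.5, max_iter = 20000L, tol = 1e-10,
                      train_fraction = 0.75, cv_folds = 5L,
                      mu_grid = 10^seq(-4, 0, length.out = 9), seed = 1L) {
  stopifnot(is.null(mu) || mu >= 0, alpha >= 0, alpha <= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(mu = mu, alpha = alpha, max_iter = as.integer(max_iter),
                 tol = tol, train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), mu_grid = mu_grid,
                 seed = as.integer(seed)),
            class = "en_config")
}

en_objective <- function(beta0, beta, X, y, mu, alpha) {
  eta <- beta0 + drop(X %*% beta)
  # stable log(1 + exp(eta))
  log1pe <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
  -mean(y * eta - log1pe) +
    mu * ((1 - alpha) * sum(beta^2) / 2 + alpha * sum(abs(beta)))
}

#' Fit an elastic-net-penalized logistic regression
#'
#' Minimizes the objective described in [en_config()] by monotone proximal
#' gradient descent (ISTA): a gradient step on the smooth part (mean
#' negative log-likelihood plus ridge) with a fixed step size from the
#' Lipschitz bound of the logistic Hessian, followed by soft-thresholding
#' of the coefficients at `step * mu * alpha`. Features are standardized
#' internally (zero mean, unit variance; constant features are left at
#' zero) and the returned model carries the scaling so that prediction
#' operates on the original feature scale.
#'
#' @param features numeric matrix, samples x features.
#' @param labels 0/1 vector, one per sample, both classes present.
#' @param config an [en_config()].
#' @return a `tmi_logit` model: `beta0`, `beta` (original scale),
#'   `beta_std` (standardized scale), `center`, `scale`, `mu`, `alpha`,
#'   `converged`, `objective_trace`.
#' @export
fit_logistic_en <- function(features, labels, config = en_config()) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (sum(y == 1) < 2L || sum(y == 0) < 2L) {
    stop("need >= 2 samples per class")
  }
  mu <- config$mu
  if (is.null(mu)) {
    mu <- cv_select_mu(X, y, config)
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  n <- nrow(Z); p <- ncol(Z)
  # Lipschitz constant of the smooth part: 0.25 * ||[1 Z]||_2^2 / n + ridge
  A <- cbind(1, Z)
  L <- 0.25 * max(eigen(crossprod(A) / n, symmetric = TRUE,
                        only.values = TRUE)$values) + mu * (1 - config$alpha)
  step <- 1 / L
  b0 <- 0
  b <- numeric(p)
  trace <- en_objective(b0, b, Z, y, mu, config$alpha)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    eta <- b0 + drop(Z %*% b)
    pr <- 1 / (1 + exp(-eta))
    g <- pr - y
    grad0 <- mean(g)
    grad <- drop(crossprod(Z, g)) / n + mu * (1 - config$alpha) * b
    b0 <- b0 - step * grad0
    b_raw <- b - step * grad
    thr <- step * mu * config$alpha
    b <- sign(b_raw) * pmax(abs(b_raw) - thr, 0)
    obj <- en_objective(b0, b, Z, y, mu, config$alpha)
    trace <- c(trace, obj)
    if (abs(trace[it] - obj) < config$tol) {
      converged <- TRUE
      break
    }
  }
  beta <- b / scl
  beta0 <- b0 - sum(beta * ctr)
  structure(list(beta0 = beta0, beta = stats::setNames(beta, colnames(X)),
                 beta_std = b, center = ctr, scale = scl, mu = mu,
                 alpha = config$alpha, converged = converged,
                 objective_trace = trace),
            class = "tmi_logit")
}

cv_select_mu <- function(X, y, config) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  n <- nrow(X)
  fold <- sample(rep_len(seq_len(config$cv_folds), n))
  dev <- vapply(config$mu_grid, function(m) {
    cfg <- config
    cfg$mu <- m
    cfg$max_iter <- min(cfg$max_iter, 5000L)
    per_fold <- vapply(seq_len(config$cv_folds), function(kf) {
      tr <- fold != kf
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 1L) {
        return(NA_real_)
      }
      fit <- fit_logistic_en(X[tr, , drop = FALSE], y[tr], cfg)
      pr <- predict(fit, X[!tr, , drop = FALSE])$probability
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      -mean(y[!tr] * log(pr) + (1 - y[!tr]) * log(1 - pr))
    }, 0)
    mean(per_fold, na.rm = TRUE)
  }, 0)
  config$mu_grid[which.min(dev)]
}

#' Predict from a fitted elastic-net logistic model
#'
#' @param object a `tmi_logit` model.
#' @param features samples x features matrix with the same feature count
#'   (and order) as at fit time.
#' @param ... unused.
#' @return list with `probability` (`1 / (1 + exp(-(b0 + x'b)))`) and
#'   `label` (1 when probability >= 0.5).
#' @export
predict.tmi_logit <- function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != length(object$beta)) {
    stop("feature count mismatch: model has ", length(object$beta),
         ", input has ", ncol(X))
  }
  eta <- object$beta0 + drop(X %*% object$beta)
  p <- 1 / (1 + exp(-eta))
  list(probability = p, label = as.integer(p >= 0.5))
}

stratified_split <- function(y, train_fraction) {
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  n1 <- max(1L, round(length(idx1) * train_fraction))
  n0 <- max(1L, round(length(idx0) * train_fraction))
  n1 <- min(n1, length(idx1) - 1L)
  n0 <- min(n0, length(idx0) - 1L)
  train <- c(sample(idx1, n1), sample(idx0, n0))
  sort(train)
}

#' Compare bacteria-only, immune-cell-only and joint classifiers
#'
#' For each of the three feature cases — bacterial abundances alone, immune
#' cell fractions alone, and their column-wise union — fits the elastic-net
#' logistic classifier on a stratified 75/25 train/test split and reports
#' held-out accuracy. The split/fit/score cycle is repeated across
#' `repeats` seeded splits and summarized as mean and standard deviation,
#' since a single split is dominated by sampling noise at cohort scale.
#'
#' @param bacteria samples x bacterial-feature matrix.
#' @param cells samples x cell-fraction matrix (same sample order).
#' @param labels 0/1 vector (0 = normal, 1 = tumor).
#' @param config an [en_config()]; `config$seed` seeds the split sequence.
#' @param repeats number of repeated splits (default 50).
#' @return list per case (`bacteria`, `cells`, `joint`) with
#'   `accuracy_mean`, `accuracy_sd`, `accuracies`.
#' @export
evaluate_three_cases <- function(bacteria, cells, labels,
                                 config = en_config(), repeats = 50L) {
  bacteria <- as.matrix(bacteria)
  cells <- as.matrix(cells)
  y <- as.numeric(labels)
  stopifnot(nrow(bacteria) == length(y), nrow(cells) == length(y))
  cases <- list(bacteria = bacteria, cells = cells,
                joint = cbind(bacteria, cells))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  # when mu is unset, select it once per case on the full cohort (CV inside
  # every repeat would be needlessly slow and noisier)
  mu_case <- lapply(cases, function(X) {
    if (is.null(config$mu)) cv_select_mu(X, y, config) else config$mu
  })
  acc <- lapply(cases, function(x) numeric(repeats))
  for (r in seq_len(repeats)) {
    set.seed(config$seed + r - 1L)
    tr <- stratified_split(y, config$train_fraction)
    te <- setdiff(seq_along(y), tr)
    if (length(unique(y[te])) < 2L) {
      warning("class absent from test split; re-splitting")
      tr <- stratified_split(y, config$train_fraction)
      te <- setdiff(seq_along(y), tr)
    }
    for (case in names(cases)) {
      X <- cases[[case]]
      cfg <- config
      cfg$mu <- mu_case[[case]]
      fit <- fit_logistic_en(X[tr, , drop = FALSE], y[tr], cfg)
      pred <- predict(fit, X[te, , drop = FALSE])
      acc[[case]][r] <- mean(pred$label == y[te])
    }
  }
  lapply(acc, function(a) {
    list(accuracy_mean = mean(a), accuracy_sd = stats::sd(a), accuracies = a)
  })
}
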