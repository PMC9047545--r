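#' Default SVR hyperparameters
#'
#' The converged reference values used when swarm tuning is skipped:
#' penalty `C = 3`, tube half-width `epsilon = 1.203564e-5`, and kernel
#' coefficient `phi = 0.04545455`. `phi` is accepted for API symmetry with
#' the tuner but is inert under the fixed linear kernel `k(x, y) = x . y`.
#'
#' @param epsilon epsilon-insensitive tube half-width, >= 0.
#' @param C penalty factor, > 0.
#' @param phi kernel coefficient, > 0 (no effect with a linear kernel).
#' @return an `svr_params` list.
#' @export
svr_params <- function(epsilon = 1.203564e-5, C = 3, phi = 0.04545455) {
  stopifnot(epsilon >= 0, C > 0, phi > 0)
  structure(list(epsilon = epsilon, C = C, phi = phi), class = "svr_params")
}

#' Restrict mixture and signature to shared genes and z-score both
#'
#' Rows of the mixture `X` (genes x samples) and signature `S` (genes x cell
#' types) are restricted to their shared gene ids, in the signature's order,
#' then each matrix is globally z-scored (subtract its overall mean, divide
#' by its overall standard deviation) — the usual preprocessing before
#' support-vector deconvolution. Scaling each matrix by its own global
#' moments makes the downstream fractions invariant to overall library
#' scale.
#'
#' @param X numeric matrix, genes x samples, with gene ids as rownames.
#' @param S numeric matrix, genes x cell types, with gene ids as rownames.
#' @param normalize z-score the matrices (default TRUE).
#' @return list with aligned (and normalized) `X` and `S`.
#' @export
align_and_normalize <- function(X, S, normalize = TRUE) {
  stopifnot(is.matrix(X), is.matrix(S),
            !is.null(rownames(X)), !is.null(rownames(S)))
  shared <- intersect(rownames(S), rownames(X))
  if (length(shared) < 2L) {
    stop("fewer than 2 shared genes between mixture and signature; ",
         "example mixture ids: ",
         paste(utils::head(rownames(X), 3L), collapse = ", "),
         "; signature ids: ",
         paste(utils::head(rownames(S), 3L), collapse = ", "))
  }
  X <- X[shared, , drop = FALSE]
  S <- S[shared, , drop = FALSE]
  if (normalize) {
    sx <- stats::sd(X)
    ss <- stats::sd(S)
    # constant matrices (e.g. an all-zero mixture) are centered only
    X <- (X - mean(X)) / (if (sx > 0) sx else 1)
    S <- (S - mean(S)) / (if (ss > 0) ss else 1)
  }
  list(X = X, S = S)
}

#' Fit linear epsilon-SVR coefficients for one sample
#'
#' Solves the (bias-free) linear epsilon-insensitive support vector
#' regression `x ~ S w`: minimize
#' `0.5 * ||w||^2 + C * sum_i max(0, |x_i - s_i . w| - epsilon)`
#' over the cell-type weight vector `w`, where rows `s_i` of the signature
#' are the training points. Fit by cyclic dual coordinate descent on
#' `beta_i = alpha_i - alpha_i*` (one closed-form soft-threshold-and-clip
#' update per gene), which is deterministic and needs no random restarts.
#' The `phi` entry of `params` is ignored (linear kernel).
#'
#' @param x numeric vector, one sample's (normalized) expression over the
#'   shared genes.
#' @param S numeric matrix, (normalized) signature over the same genes.
#' @param params an [svr_params()].
#' @param max_passes maximum sweeps over the genes.
#' @param tol convergence on the largest change of any entry of `w` across
#'   one sweep. (The dual variables themselves can keep drifting along the
#'   null space of the rank-deficient gram matrix while `w` — the only
#'   quantity used downstream — is already stationary, so convergence is
#'   measured on `w`.)
#' @return numeric vector `w` of raw regression coefficients (length =
#'   number of cell types), with attribute `passes`.
#' @export
svr_solve <- function(x, S, params = svr_params(), max_passes = 1000L,
                      tol = 1e-9) {
  stopifnot(length(x) == nrow(S))
  n <- nrow(S)
  m <- ncol(S)
  eps <- params$epsilon
  C <- params$C
  qii <- rowSums(S^2)
  active <- which(qii > 0)
  beta <- numeric(n)
  w <- numeric(m)
  passes <- 0L
  delta_w <- Inf
  repeat {
    passes <- passes + 1L
    w_prev <- w
    for (i in active) {
      si <- S[i, ]
      g <- sum(w * si) - x[i]            # gradient of the smooth dual part
      z <- beta[i] - g / qii[i]
      b_new <- sign(z) * max(abs(z) - eps / qii[i], 0)
      b_new <- min(max(b_new, -C), C)
      d <- b_new - beta[i]
      if (d != 0) {
        beta[i] <- b_new
        w <- w + d * si
      }
    }
    delta_w <- max(abs(w - w_prev))
    if (delta_w < tol || passes >= max_passes) break
  }
  if (passes >= max_passes && delta_w >= sqrt(tol)) {
    stop("SVR solver did not converge (C=", C, ", epsilon=", eps, ")")
  }
  attr(w, "passes") <- passes
  w
}

#' Map raw SVR coefficients to simplex cell fractions
#'
#' Negative coefficients are clamped to zero and the remainder renormalized
#' to sum to one. If no coefficient is positive the fractions fall back to
#' uniform `1/m` with a warning (degenerate input, e.g. an all-zero sample).
#'
#' @param w numeric coefficient vector.
#' @return numeric fraction vector on the probability simplex.
#' @export
coefficients_to_fractions <- function(w) {
  v <- pmax(w, 0)
  s <- sum(v)
  if (s <= 0) {
    warning("all coefficients non-positive; returning uniform fractions")
    return(stats::setNames(rep(1 / length(w), length(w)), names(w)))
  }
  v / s
}

#' Deconvolve bulk expression into immune cell-type fractions
#'
#' Solves `X = S f` column by column: genes are aligned and both matrices
#' globally z-scored, then each sample column is fit by linear epsilon-SVR
#' ([svr_solve()]) and the raw coefficients mapped onto the probability
#' simplex ([coefficients_to_fractions()]).
#'
#' @param X numeric mixture matrix, genes x samples (rownames = gene ids).
#' @param S numeric signature matrix, genes x cell types (rownames = gene
#'   ids, colnames = cell types).
#' @param params an [svr_params()]; defaults to the reference values.
#' @param normalize passed to [align_and_normalize()].
#' @return a `cell_fractions` object: list with `fractions` (samples x cell
#'   types, rows on the simplex), `raw_coefficients` (same shape) and
#'   `params`.
#' @export
deconvolve <- function(X, S, params = svr_params(), normalize = TRUE) {
  al <- align_and_normalize(X, S, normalize = normalize)
  L <- ncol(al$X)
  m <- ncol(al$S)
  raw <- matrix(NA_real_, L, m, dimnames = list(colnames(X), colnames(S)))
  for (j in seq_len(L)) {
    raw[j, ] <- svr_solve(al$X[, j], al$S, params)
  }
  frac <- t(apply(raw, 1L, coefficients_to_fractions))
  dimnames(frac) <- dimnames(raw)
  structure(list(fractions = frac, raw_coefficients = raw, params = params),
            class = "cell_fractions")
}

#' @export
print.cell_fractions <- function(x, ...) {
  cat("Cell fractions:", nrow(x$fractions), "samples x",
      ncol(x$fractions), "cell types (epsilon=", x$params$epsilon,
      ", C=", x$params$C, ")\n", sep = "")
  print(utils::head(round(x$fractions, 4)))
  invisible(x)
}
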