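#' Mann-Whitney U test with mid-rank ties
#'
#' Pools the two samples, assigns mid-ranks to ties, and computes the rank
#' sums `T_A`, `T_B` and the statistics
#' `U_A = N_A N_B + N_A (N_A + 1) / 2 - T_A` (and symmetrically `U_B`); the
#' reported `U` is the smaller of the two and `U_A + U_B = N_A N_B` always.
#' The p-value is exact — by enumeration of the null distribution of `U` —
#' when both samples have fewer than 20 observations and there are no ties
#' (or when `mode = "exact"` is forced and enumeration is feasible);
#' otherwise a normal approximation with tie-corrected variance and a 0.5
#' continuity correction is used.
#'
#' @param A,B numeric samples (each non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternative on the location of `A` relative to `B`).
#' @return a `two_sample_result` list: `U_A`, `U_B`, `U`, `T_A`, `T_B`,
#'   `p_value`, `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(A, B, mode = c("auto", "exact", "normal"),
                           alternative = c("two.sided", "less", "greater")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  A <- as.numeric(A); B <- as.numeric(B)
  if (length(A) == 0L || length(B) == 0L) stop("empty sample")
  na <- length(A); nb <- length(B)
  pooled <- c(A, B)
  r <- rank(pooled)                       # mid-ranks for ties
  T_A <- sum(r[seq_len(na)])
  T_B <- sum(r[na + seq_len(nb)])
  U_A <- na * nb + na * (na + 1) / 2 - T_A
  U_B <- na * nb + nb * (nb + 1) / 2 - T_B
  U <- min(U_A, U_B)
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- switch(mode,
    auto = na < 20L && nb < 20L && !ties,
    exact = TRUE,
    normal = FALSE)
  if (use_exact && !ties) {
    p <- mw_exact_p(U_A, na, nb, alternative)
    method <- "exact"
  } else if (use_exact) {
    if (choose(na + nb, na) > 2e5) {
      stop("exact enumeration with ties infeasible at this sample size")
    }
    p <- mw_exact_p_ties(pooled, na, U_A, alternative)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    N <- na + nb
    tt <- table(pooled)
    tie_term <- sum(tt^3 - tt) / (N * (N - 1))
    sig2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sig2 <= 0) {
      p <- 1
    } else {
      sig <- sqrt(sig2)
      # continuity-corrected z for U_A
      p <- switch(alternative,
        two.sided = min(1, 2 * stats::pnorm(
          (abs(U_A - mu) - 0.5) / sig, lower.tail = FALSE)),
        # A shifted left => small T_A => large U_A
        less = stats::pnorm((U_A - mu - 0.5) / sig, lower.tail = FALSE),
        greater = stats::pnorm((U_A - mu + 0.5) / sig))
    }
    method <- "normal_approx"
  }
  structure(list(U_A = U_A, U_B = U_B, U = U, T_A = T_A, T_B = T_B,
                 N_A = na, N_B = nb, p_value = p, method = method,
                 alternative = alternative),
            class = "two_sample_result")
}

mw_exact_p <- function(U_A, na, nb, alternative) {
  # exact null pmf of U for untied data (Mann-Whitney count recursion as
  # provided by stats::dwilcox)
  u_all <- 0:(na * nb)
  pmf <- stats::dwilcox(u_all, na, nb)
  p_le <- sum(pmf[u_all <= U_A])
  p_ge <- sum(pmf[u_all >= U_A])
  switch(alternative,
    two.sided = min(1, 2 * min(p_le, p_ge)),
    less = p_ge,       # A below B => T_A small => U_A large
    greater = p_le)
}

# Exact p with ties: enumerate all C(N, na) assignments of the pooled
# (tied) values to group A and tabulate U_A.
mw_exact_p_ties <- function(pooled, na, U_A_obs, alternative) {
  r <- rank(pooled)
  N <- length(pooled)
  idx <- utils::combn(N, na)
  nb <- N - na
  u_a <- apply(idx, 2L, function(ii) {
    na * nb + na * (na + 1) / 2 - sum(r[ii])
  })
  tol <- 1e-9
  p_le <- mean(u_a <= U_A_obs + tol)
  p_ge <- mean(u_a >= U_A_obs - tol)
  switch(alternative,
    two.sided = min(1, 2 * min(p_le, p_ge)),
    less = p_ge,
    greater = p_le)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up procedure: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1 and mapped back to
#' the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Per-feature differential abundance between two groups
#'
#' Runs a Mann-Whitney U test per feature (row) between the two sample
#' groups, adjusts across features with Benjamini-Hochberg, and annotates
#' each feature with a direction arrow (up when the group-2 mean exceeds the
#' group-1 mean) and a percent difference defined as
#' `|mean_2 - mean_1| / min(mean_1, mean_2) * 100` — dividing by the
#' smaller group mean, which is why differences above 100% occur. Constant
#' features (identical value in every sample of both groups) get `p = 1`
#' and are flagged.
#'
#' @param group1 numeric matrix, features x samples (e.g. normal tissue).
#' @param group2 numeric matrix, same features x samples (e.g. tumor).
#' @param alpha significance level applied to the FDR (annotation only).
#' @param mode passed to [mann_whitney_u()].
#' @return data.frame with columns `feature`, `mean_1`, `mean_2`, `U`, `p`,
#'   `q`, `direction` (`"up"`/`"down"`), `pct_diff`, `significant`,
#'   `constant`.
#' @export
differential_table <- function(group1, group2, alpha = 0.05,
                               mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(group1), is.matrix(group2),
            nrow(group1) == nrow(group2),
            ncol(group1) >= 2L, ncol(group2) >= 2L)
  feats <- rownames(group1)
  if (is.null(feats)) feats <- paste0("feature_", seq_len(nrow(group1)))
  res <- lapply(seq_len(nrow(group1)), function(i) {
    a <- group1[i, ]; b <- group2[i, ]
    constant <- length(unique(c(a, b))) == 1L
    if (constant) {
      list(U = length(a) * length(b) / 2, p = 1, constant = TRUE)
    } else {
      t <- mann_whitney_u(a, b, mode = mode)
      list(U = t$U, p = t$p_value, constant = FALSE)
    }
  })
  m1 <- rowMeans(group1)
  m2 <- rowMeans(group2)
  p <- vapply(res, `[[`, 0, "p")
  denom <- pmin(m1, m2)
  pct <- ifelse(denom > 0, abs(m2 - m1) / denom * 100, Inf)
  pct[abs(m2 - m1) == 0] <- 0
  out <- data.frame(feature = feats, mean_1 = m1, mean_2 = m2,
                    U = vapply(res, `[[`, 0, "U"), p = p, q = bh_fdr(p),
                    direction = ifelse(m2 > m1, "up", "down"),
                    pct_diff = pct,
                    constant = vapply(res, `[[`, NA, "constant"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$q < alpha
  out
}

#' Benchmark metrics: RMSE, Pearson and Spearman correlation
#'
#' @param truth,estimate numeric vectors of equal length (>= 2).
#' @return list with `rmse`, `pearson_r`, `spearman_rs`; correlations are
#'   `NaN` with a warning when either vector is constant.
#' @export
benchmark_metrics <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate), length(truth) >= 2L)
  rmse <- sqrt(mean((estimate - truth)^2))
  if (stats::sd(truth) == 0 || stats::sd(estimate) == 0) {
    warning("constant vector: correlation undefined")
    return(list(rmse = rmse, pearson_r = NaN, spearman_rs = NaN))
  }
  list(rmse = rmse,
       pearson_r = stats::cor(truth, estimate, method = "pearson"),
       spearman_rs = stats::cor(truth, estimate, method = "spearman"))
}
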