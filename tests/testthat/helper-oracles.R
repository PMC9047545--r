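# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, textbook formulas, or
# naive dense implementations.

# Lawson-Hanson active-set non-negative least squares: min ||A x - b||, x >= 0
oracle_nnls <- function(A, b, tol = 1e-10) {
  m <- ncol(A)
  passive <- rep(FALSE, m)
  x <- numeric(m)
  repeat {
    wgrad <- drop(crossprod(A, b - A %*% x))
    if (all(passive) || max(wgrad[!passive]) <= tol) break
    j <- which(!passive)[which.max(wgrad[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(m)
      s[passive] <- qr.solve(A[, passive, drop = FALSE], b)
      if (all(s[passive] > tol)) {
        x <- s
        break
      }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
  }
  x
}

# Mann-Whitney oracle: U statistics from first-principles pairwise counts,
# and the exact two-sided p by enumerating every assignment of the pooled
# values to group A (feasible for small N). The two-sided p doubles the
# smaller tail of U_A, as in the package.
oracle_mw <- function(A, B) {
  na <- length(A); nb <- length(B)
  # large T_A (A high in the pooled ranking) gives small U_A, so U_A counts
  # the (a, b) pairs with a < b, plus half of the tied pairs
  lt <- sum(outer(A, B, "<")); eq <- sum(outer(A, B, "=="))
  U_A <- lt + eq / 2
  U_B <- na * nb - U_A
  pooled <- c(A, B)
  r <- rank(pooled)
  idx <- utils::combn(length(pooled), na)
  u_star <- apply(idx, 2L, function(ii) {
    na * nb + na * (na + 1) / 2 - sum(r[ii])
  })
  tol <- 1e-9
  p_two <- min(1, 2 * min(mean(u_star <= U_A + tol),
                          mean(u_star >= U_A - tol)))
  list(U_A = U_A, U_B = U_B, U = min(U_A, U_B), p_two = p_two)
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, 0)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Direct EM iteration on a dense read x genome likelihood matrix; returns
# the read-mixture weights pi (not length-corrected).
oracle_em <- function(lik, n_iter = 5000) {
  k <- ncol(lik)
  pi <- rep(1 / k, k)
  for (it in seq_len(n_iter)) {
    num <- sweep(lik, 2L, pi, "*")
    resp <- num / rowSums(num)
    pi <- colMeans(resp)
  }
  pi
}

# Dense grid search over a 3-D box
oracle_grid_best <- function(fitness, bounds, n = 11L) {
  grids <- lapply(seq_len(ncol(bounds)), function(j) {
    seq(bounds[1, j], bounds[2, j], length.out = n)
  })
  pts <- as.matrix(expand.grid(grids))
  min(apply(pts, 1L, fitness))
}

# Unpenalized logistic MLE via IRLS (independent of both glm internals'
# formula interface and the package's proximal solver)
oracle_logit_mle <- function(X, y, n_iter = 100) {
  A <- cbind(1, X)
  b <- numeric(ncol(A))
  for (it in seq_len(n_iter)) {
    eta <- drop(A %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    b <- b + solve(crossprod(A, W * A), crossprod(A, y - p))
  }
  drop(b)
}

# shared tiny fixtures -------------------------------------------------------

make_sam_fixture <- function(path) {
  # 12 records exercising every flag combination relevant to extraction
  recs <- list(
    #        qname  flag                       seq        qual
    c("r01", 69),    # paired, read unmapped, mate mapped, first  -> single
    c("r02", 133),   # paired, read unmapped, mate mapped, second -> single
    c("r03", 77),    # both unmapped, first   -> pair (with r03/141)
    c("r03", 141),   # both unmapped, second
    c("r04", 77),    # both unmapped, first, mate lost below -> orphan
    c("r05", 4),     # unpaired unmapped (bit 8 unset)        -> single
    c("r06", 260),   # unmapped secondary (4+256)             -> excluded
    c("r07", 0),     # mapped primary                         -> excluded
    c("r08", 16),    # mapped reverse                         -> excluded
    c("r09", 337),   # paired, mapped, secondary (1+16+64+256)-> excluded
    c("r10", 73),    # paired, mate unmapped only (1+8+64)    -> excluded
    c("r11", 333)    # 1+4+8+64+256: both unmapped secondary  -> excluded
  )
  lines <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000")
  for (r in recs) {
    flag <- as.integer(r[[2]])
    unmapped <- bitwAnd(flag, 4L) == 4L
    # htslib force-flags CIGAR-less "mapped" records as unmapped, so give
    # mapped records a real CIGAR/position
    lines <- c(lines, paste(
      r[[1]], flag,
      if (unmapped) "*" else "chr1", if (unmapped) "0" else "1",
      if (unmapped) "0" else "60", if (unmapped) "*" else "10M",
      "*", "0", "0", "ACGTACGTAC", "IIIIIIIIII", sep = "\t"))
  }
  writeLines(lines, path)
  path
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T", "N")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
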