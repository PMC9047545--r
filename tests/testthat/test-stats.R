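test_that("Mann-Whitney statistics follow the printed formulas", {
  t <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t$T_A, 6)
  expect_equal(t$U_A, 9)
  expect_equal(t$U_B, 0)
  expect_equal(t$U, 0)
  expect_equal(t$p_value, 0.1)
  expect_equal(t$method, "exact")

  # fully tied: mid-ranks force U_A = U_B = N_A N_B / 2
  tt <- mann_whitney_u(c(1, 1), c(1, 1))
  expect_equal(tt$U_A, 2)
  expect_equal(tt$U_B, 2)

  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("U_A + U_B = N_A N_B on 1000 random inputs", {
  set.seed(13)
  for (i in 1:1000) {
    na <- sample(1:15, 1)
    nb <- sample(1:15, 1)
    A <- sample(1:10, na, replace = TRUE)   # ties likely
    B <- sample(1:10, nb, replace = TRUE)
    t <- mann_whitney_u(A, B)
    expect_equal(t$U_A + t$U_B, na * nb)
    expect_equal(t$U, min(t$U_A, t$U_B))
    expect_gte(t$p_value, 0)
    expect_lte(t$p_value, 1)
  }
})

test_that("exact p matches full enumeration for N_A, N_B <= 7", {
  set.seed(17)
  for (i in 1:60) {
    na <- sample(2:7, 1)
    nb <- sample(2:7, 1)
    tied <- i %% 2 == 0
    pool <- if (tied) sample(1:4, na + nb, replace = TRUE)
            else sample(1:1000, na + nb)
    A <- pool[seq_len(na)]
    B <- pool[na + seq_len(nb)]
    orc <- oracle_mw(A, B)
    t <- mann_whitney_u(A, B, mode = "exact")
    expect_equal(t$U_A, orc$U_A)
    expect_equal(t$U_B, orc$U_B)
    expect_equal(t$p_value, orc$p_two, tolerance = 1e-12)
  }
})

test_that("normal approximation approaches the exact p at N = 15", {
  set.seed(19)
  for (i in 1:10) {
    A <- stats::rnorm(15)
    B <- stats::rnorm(15, mean = 0.5)
    pe <- mann_whitney_u(A, B, mode = "exact")$p_value
    pn <- mann_whitney_u(A, B, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("one-sided alternatives point in the right direction", {
  A <- c(1, 2, 3, 4)
  B <- c(10, 11, 12, 13)
  less <- mann_whitney_u(A, B, alternative = "less")$p_value
  greater <- mann_whitney_u(A, B, alternative = "greater")$p_value
  expect_lt(less, 0.05)
  expect_gt(greater, 0.9)
})

test_that("BH-FDR matches the step-up oracle on random vectors", {
  expect_equal(bh_fdr(c(0.005, 0.05)), c(0.01, 0.05))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(23)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- stats::runif(m)^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))   # monotone after sorting by p
  }
})

test_that("BH rejections never decrease when a p-value shrinks", {
  set.seed(29)
  for (i in 1:50) {
    p <- stats::runif(10)
    j <- sample(10, 1)
    p2 <- p
    p2[j] <- p[j] * stats::runif(1)
    r1 <- sum(bh_fdr(p) < 0.05)
    r2 <- sum(bh_fdr(p2) < 0.05)
    expect_gte(r2, r1)
  }
})

test_that("differential_table finds planted shifts and annotates them", {
  spec <- synth_spec(seed = 31, planted_bacteria = c("2" = 2),
                     planted_cells = stats::setNames(numeric(0),
                                                     character(0)))
  cohort <- make_cohort(spec)
  normal <- t(cohort$bacteria[cohort$labels == 0L, ])
  tumor <- t(cohort$bacteria[cohort$labels == 1L, ])
  tab <- differential_table(normal, tumor)
  planted <- tab[tab$feature == "bact_2", ]
  expect_lt(planted$q, 0.05)
  expect_equal(planted$direction, "up")
  expect_gt(planted$pct_diff, 0)

  # permuting sample order within groups leaves the table unchanged
  set.seed(1)
  tab2 <- differential_table(normal[, sample(ncol(normal))],
                             tumor[, sample(ncol(tumor))])
  expect_equal(tab2, tab)

  # constant feature is flagged with p = 1
  const <- rbind(f1 = rep(1, 8))
  tabc <- differential_table(rbind(const[, 1:4, drop = FALSE]),
                             rbind(const[, 5:8, drop = FALSE]))
  expect_equal(tabc$p, 1)
  expect_true(tabc$constant)
})

test_that("identical groups keep the false positive rate near alpha", {
  set.seed(37)
  hits <- 0L
  tests <- 0L
  for (rep in 1:200) {
    g1 <- matrix(stats::rnorm(5 * 10), 5)
    g2 <- matrix(stats::rnorm(5 * 10), 5)
    tab <- differential_table(g1, g2, mode = "normal")
    hits <- hits + sum(tab$p < 0.05)   # raw p: per-test level
    tests <- tests + nrow(tab)
  }
  expect_lt(abs(hits / tests - 0.05), 0.02)
  # and with BH, family-wise discoveries under the null are rare
  set.seed(38)
  fams <- vapply(1:200, function(i) {
    g1 <- matrix(stats::rnorm(5 * 10), 5)
    g2 <- matrix(stats::rnorm(5 * 10), 5)
    sum(differential_table(g1, g2, mode = "normal")$q < 0.05)
  }, 0)
  expect_lt(mean(fams > 0), 0.1)
})

test_that("percent difference divides by the smaller group mean", {
  g1 <- rbind(f = c(1, 1, 1.2, 0.8))        # mean 1
  g2 <- rbind(f = c(3, 3.2, 2.8, 3))        # mean 3
  tab <- differential_table(g1, g2)
  expect_equal(tab$pct_diff, 200, tolerance = 1e-9)  # |3-1|/1 * 100 > 100%
  expect_equal(tab$direction, "up")
})

test_that("benchmark metrics match hand computation", {
  m <- benchmark_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(rmse = 0, pearson_r = 1, spearman_rs = 1))

  m2 <- benchmark_metrics(c(1, 2, 3), c(2, 2, 2.000001))
  expect_equal(m2$rmse, sqrt(mean(c(1, 0, 1.000001 - 2)^2)),
               tolerance = 1e-6)

  m3 <- benchmark_metrics(c(1, 2, 3), c(1, 4, 9))
  expect_equal(m3$spearman_rs, 1)
  expect_lt(m3$pearson_r, 1)

  expect_warning(m4 <- benchmark_metrics(c(1, 2, 3), c(2, 2, 2)),
                 "constant")
  expect_true(is.nan(m4$pearson_r))
  expect_equal(m4$rmse, sqrt(2 / 3))
})
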