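test_that("exact tied-group null matches full permutation enumeration", {
  # all-distinct references, n = 4..8: DP distribution vs all n! orderings
  for (n in c(4, 6, 8)) {
    ref <- seq_len(n)
    S <- vapply(permutations_of(seq_len(n)), kendall_s, 0, ref = ref)
    enum <- table(S) / factorial(n)
    d <- rhythmscan:::.jt_null(rep(1L, n))
    M <- length(d) - 1L
    dp <- setNames(d, 2 * (0:M) - M)
    expect_equal(max(abs(enum - dp[names(enum)])), 0, tolerance = 1e-12)
  }
  # tied reference groups, as produced by replicates sharing a time point
  for (sizes in list(c(2, 2, 2), c(3, 2, 1), c(2, 2, 1))) {
    ref <- rep(seq_along(sizes), times = sizes)
    n <- length(ref)
    S <- vapply(permutations_of(seq_len(n)), kendall_s, 0, ref = ref)
    enum <- table(S) / factorial(n)
    d <- rhythmscan:::.jt_null(sizes)
    M <- length(d) - 1L
    dp <- setNames(d, 2 * (0:M) - M)
    expect_equal(max(abs(enum - dp[names(enum)])), 0, tolerance = 1e-12)
  }
})

test_that("perfect concordance attains the enumerated extreme-tail p", {
  # 4 distinct values, 4-level reference: S = 6 and one-sided p = 1/24
  d <- rhythmscan:::.jt_null(rep(1L, 4))
  expect_equal(d[length(d)], 1 / 24, tolerance = 1e-12)
  pf <- rhythmscan:::.jt_two_sided(d)
  expect_equal(pf(6), 2 / 24, tolerance = 1e-12)
  # antisymmetry: a reversed series has the same two-sided p
  x <- c(0.3, 1.1, 2.7, 5.2, 4.1, 3.3, 2.0, 0.9)
  times <- seq(0, 21, 3)
  cfg <- np_config()
  expect_equal(jtk_test(x, times, cfg)$p, jtk_test(-x, times, cfg)$p,
               tolerance = 1e-12)
  expect_equal(jtk_test(x, times, cfg)$tau, -jtk_test(-x, times, cfg)$tau,
               tolerance = 1e-12)
})

test_that("the rank test locates a noise-free period on the grid", {
  y <- cosine_series(1, 24, 0, 0:23)
  r <- jtk_test(y, 0:23)
  expect_equal(r$best_period, 24)
  expect_equal(r$best_lag, 0)
  # tau-b is slightly below 1 because the symmetric cosine reference has tied
  # pairs (t and 24-t) that the floating-point data values break
  expect_gt(r$tau, 0.97)
  expect_lt(r$p, 0.01)
  # all-tied data cannot be concordant with anything
  expect_equal(jtk_test(rep(2, 24), 0:23)$p, 1)
  expect_error(jtk_test(y[1:4], 0:3), "6 samples")
})

test_that("rank-test p-values under Gaussian noise are conservative", {
  set.seed(77)
  X <- matrix(rnorm(500 * 24), 500, 24,
              dimnames = list(sprintf("g%d", 1:500), NULL))
  times <- rep(seq(0, 22, 2), each = 2)
  r <- rhythmscan:::.jtk_engine(X, times, np_config())
  expect_lte(mean(r$p < 0.05), 0.07)   # ECDF at 0.05 not above the diagonal
  expect_gt(mean(r$p), 0.4)
})

test_that("periodogram peaks at the true frequency and matches regression power", {
  y <- cosine_series(1, 24, 3, 0:23)
  r <- lomb_scargle_test(y, 0:23)
  expect_equal(r$best_period, 24, tolerance = 0.6)  # grid resolution
  expect_lt(r$p, 0.01)
  # identity: LS power == sinusoid least-squares explained SS / (2 * variance)
  set.seed(88)
  for (i in 1:5) {
    t <- 0:23
    x <- rnorm(24)
    eng <- rhythmscan:::.ls_engine(matrix(x, 1), t, np_config())
    for (k in c(1, which.max(eng$P[, 1]), length(eng$freqs))) {
      w <- 2 * pi * eng$freqs[k]
      tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
      cc <- cos(w * (t - tau)); ss <- sin(w * (t - tau))
      xc <- x - mean(x)
      fit <- lm(xc ~ cc + ss - 1)
      expect_equal(eng$P[k, 1], sum(fitted(fit)^2) / (2 * var(x)),
                   tolerance = 1e-6)
    }
  }
  # shift invariance and the zero-variance contract
  expect_equal(lomb_scargle_test(y + 100, 0:23)$peak_power, r$peak_power,
               tolerance = 1e-9)
  expect_equal(lomb_scargle_test(rep(3, 24), 0:23)$p, 1)
})

test_that("periodogram false-alarm rate is controlled on white noise", {
  set.seed(99)
  X <- matrix(rnorm(200 * 24), 200, 24,
              dimnames = list(sprintf("g%d", 1:200), NULL))
  r <- rhythmscan:::run_ls_matrix(X, rep(seq(0, 22, 2), each = 2))
  expect_lte(mean(r$p < 0.05), 0.10)
})

test_that("meta integration combines p-values and consensus estimates", {
  jt <- data.frame(gene = c("a", "b", "c"), p = c(1, 0.05, 0.01),
                   q = NA, best_period = c(24, 24, 22), best_lag = c(0, 2, 1),
                   tau = c(0, 0.5, 0.7), stringsAsFactors = FALSE)
  ls <- data.frame(gene = c("a", "b", "c"), p = c(1, 0.05, 0.2),
                   q = NA, best_period = c(24, 26, 22), peak_power = 1:3,
                   phase = c(0, 2, 1), stringsAsFactors = FALSE)
  m <- meta_combine(jt, ls)
  expect_equal(m$p_meta[1], 1)
  oracle <- integrate(function(x) dchisq(x, 4), -2 * 2 * log(0.05), Inf,
                      rel.tol = 1e-12)$value
  expect_equal(m$p_meta[2], oracle, tolerance = 1e-8)
  expect_equal(m$period[2], 25)
  expect_equal(m$period[3], 22)     # identical periods pass through
  expect_equal(m$phase[3], 1, tolerance = 1e-9)
  expect_error(meta_combine(jt, ls[c(2, 1, 3), ]), "same genes")
})
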