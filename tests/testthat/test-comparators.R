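test_that("fisher_g_pvalue closed form: boundaries and exact values", {
  expect_equal(fisher_g_pvalue(1, 7), 0)
  expect_equal(fisher_g_pvalue(0.5, 2), 1) # g = 1/N
  expect_equal(fisher_g_pvalue(0.5, 5), 5 * 0.5^4) # 0.3125
  expect_error(fisher_g_pvalue(0.05, 5), "outside", class = "ar_validation_error")
  expect_error(fisher_g_pvalue(1.5, 5), "outside", class = "ar_validation_error")
  expect_error(fisher_g_pvalue(0.5, 1), "n_ordinates", class = "ar_validation_error")
})

test_that("fisher_g_pvalue is strictly decreasing in g and in [0, 1]", {
  for (N in c(10, 50, 719)) {
    gs <- seq(1 / N + 1e-6, 1, length.out = 40)
    ps <- vapply(gs, fisher_g_pvalue, 0, n_ordinates = N)
    expect_true(all(diff(ps) < 1e-15))
    expect_true(all(ps >= 0 & ps <= 1))
  }
})

test_that("fisher_g_pvalue agrees with Monte Carlo at moderate settings", {
  # 2e4 draws here keeps the unit suite quick; the acceptance suite runs
  # the full 1e5-draw version.
  set.seed(61)
  M <- 2e4
  for (N in c(10, 50)) {
    E <- matrix(stats::rexp(N * M), N, M)
    G <- apply(E, 2, function(e) max(e) / sum(e))
    for (g in c(0.2, 0.3)) {
      p <- fisher_g_pvalue(g, N)
      se <- sqrt(max(p * (1 - p), 1 / M) / M)
      expect_lt(abs(mean(G > g) - p), 4 * se)
    }
  }
})

test_that("sequential_fisher: spike, flat spectrum, stopping rule", {
  ord <- c(1000, rep(1, 99))
  steps <- sequential_fisher(ord, alpha = 0.05, correction_p = 100)
  expect_equal(steps$significant, c(TRUE, FALSE))
  expect_equal(steps$n_remaining, c(100L, 99L))
  expect_equal(steps$rank, 1:2)
  # step 2 tests the remaining near-flat ordinates
  expect_equal(steps$g_statistic[2], 1 / 99)

  flat <- sequential_fisher(rep(2.5, 40), alpha = 0.05, correction_p = 1)
  expect_equal(nrow(flat), 1L)
  expect_false(flat$significant[1])
  expect_equal(flat$g_statistic[1], 1 / 40)
  expect_equal(flat$p_value[1], 1)

  expect_error(sequential_fisher(c(1, 0, 2)), "positive",
               class = "ar_validation_error")
})

test_that("adding a spike never removes previously significant steps", {
  set.seed(62)
  base <- stats::rexp(200) + 0.01
  base[1] <- 500 # one clear periodicity
  s1 <- sequential_fisher(base, alpha = 0.05, correction_p = 200)
  spiked <- base; spiked[2] <- 400
  s2 <- sequential_fisher(spiked, alpha = 0.05, correction_p = 200)
  sig1 <- s1$period_minutes[s1$significant]
  sig2 <- s2$period_minutes[s2$significant]
  expect_true(all(sig1 %in% sig2))
  expect_gte(length(sig2), length(sig1))
})

test_that("pool_ordinates sums squared magnitudes over subjects", {
  X1 <- matrix(c(1, 2, 3), 1)
  expect_equal(pool_ordinates(X1), c(1, 4, 9))
  expect_equal(pool_ordinates(rbind(X1, X1)), 2 * c(1, 4, 9))

  set.seed(63)
  X <- matrix(runif(60), 6, 10)
  oracle <- numeric(10)
  for (j in 1:10) for (i in 1:6) oracle[j] <- oracle[j] + X[i, j]^2
  expect_equal(pool_ordinates(X), oracle, tolerance = 1e-12)
})

test_that("autocorrelation: r0, bounds, periodic peak, errors", {
  s <- cosine_series(7, baseline = 10, amps = 5, periods = 1440)
  pr <- autocorrelation(s, 2880)
  expect_equal(pr$r[1], 1)
  expect_true(all(abs(pr$r) <= 1 + 1e-12))
  # one-day rhythm: the out-of-lobe peak sits near one day (biased-ACF
  # envelope displaces it a few epochs early; see package docs)
  peak <- find_local_maxima(pr, 120)[1]
  expect_lt(abs(peak - 1440), 20)

  expect_error(autocorrelation(make_series(rep(3, 1440)), 100),
               "constant", class = "ar_validation_error")
  expect_error(autocorrelation(s, 20000), "max_lag",
               class = "ar_validation_error")
})

test_that("white-noise ACF stays inside the Monte Carlo null band", {
  # |r_k| <= 4/sqrt(n) for >= 99% of lags, across seeded replicates
  # (40 replicates here; the bound is ~4 sd so violations are rare)
  n <- 10080
  frac_ok <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    x <- make_series(abs(stats::rnorm(n, 50, 10)))
    pr <- autocorrelation(x, 200)
    mean(abs(pr$r[-1]) <= 4 / sqrt(n))
  }, 0)
  expect_true(all(frac_ok >= 0.99))
})

test_that("find_local_maxima: plateaus, decay, mixtures vs exhaustive scan", {
  s <- cosine_series(7, baseline = 10, amps = 5, periods = 1440)
  pr <- autocorrelation(s, 4400)
  peaks <- find_local_maxima(pr, 120)
  # multiples of one day (within the envelope displacement)
  expect_true(any(abs(peaks - 1440) <= 20))
  expect_true(any(abs(peaks - 2880) <= 30))

  # monotone decaying profile has no local maxima
  decay <- structure(list(lags_epochs = 0:100, r = exp(-(0:100) / 30),
                          epoch_seconds = 60L, n = 1000L),
                     class = "acf_profile")
  expect_length(find_local_maxima(decay, 5), 0L)

  # two-cosine mixture: peaks near both planted periods; verify against an
  # exhaustive neighborhood-scan oracle
  m <- cosine_series(7, baseline = 30, amps = c(4, 8), periods = c(1440, 480))
  pm <- autocorrelation(m, 2000)
  w <- 100L
  got <- sort(find_local_maxima(pm, w))
  r <- pm$r
  oracle <- integer(0)
  for (k in w:2000) {
    lo <- max(0L, k - w); hi <- min(2000L, k + w)
    ok <- TRUE
    for (mm in lo:hi) if (r[mm + 1] > r[k + 1]) { ok <- FALSE; break }
    if (ok) oracle <- c(oracle, k)
  }
  expect_equal(got, sort(setdiff(oracle, 0L)))
  expect_true(any(abs(got - 1440) <= 20))
  expect_true(any(abs(got - 480) <= 20))
})
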