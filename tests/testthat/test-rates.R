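test_that("slippage solver is exact where the root is analytic", {
  # N*p = e makes log(N*p) = 1, so 0.6*G = e at G = e/0.6
  expect_equal(estimate_slippage_rate(exp(1) / 0.6, 1e7), exp(1) / 1e7,
               tolerance = 1e-10)
  # plugging the estimate back reproduces 0.6*G
  p <- estimate_slippage_rate(50, 1e7)
  expect_equal(1e7 * p * log(1e7 * p), 0.6 * 50, tolerance = 1e-8)
})

test_that("solver agrees with the independent grid+bisection oracle", {
  for (N in c(1e5, 1e6, 1e7)) {
    for (G in c(1:20, seq(25, 200, by = 5))) {
      expect_equal(estimate_slippage_rate(G, N), oracle_slippage(G, N),
                   tolerance = 1e-8)
    }
  }
})

test_that("forward-inverse round trips hold across the rate range", {
  set.seed(11)
  N <- 1e7
  p0 <- 10^runif(100, -8, -3)
  p0 <- p0[N * p0 > 1]  # relation only defined for N*p > 1
  for (p in p0) {
    G0 <- N * p * log(N * p) / 0.6
    expect_equal(estimate_slippage_rate(G0, N), p, tolerance = 1e-10)
  }
  # explicit round trip at the published control rate
  p <- 3.8e-7
  G0 <- N * p * log(N * p) / 0.6
  expect_equal(estimate_slippage_rate(G0, N), p, tolerance = 1e-10)
})

test_that("estimate is strictly increasing in the colony count", {
  p <- vapply(1:500, estimate_slippage_rate, numeric(1), n_expanded = 1e7)
  expect_true(all(diff(p) > 0))
})

test_that("log base is a configurable sensitivity knob", {
  p_ln <- estimate_slippage_rate(50, 1e7)
  p_10 <- estimate_slippage_rate(50, 1e7, log_base = "log10")
  expect_gt(p_10, p_ln)  # log10(x) < ln(x) for x > 1, so x must be larger
  x <- 1e7 * p_10
  expect_equal(x * log10(x), 30, tolerance = 1e-8)
})

test_that("zero colony counts signal below-detection, not a zero rate", {
  err <- tryCatch(estimate_slippage_rate(0, 1e7), condition = identity)
  expect_s3_class(err, "mmrscreen_below_detection")
  expect_equal(err$detection_limit, estimate_slippage_rate(1, 1e7))
  expect_error(estimate_slippage_rate(5, 1), "n_expanded")
})

test_that("summarize_fluctuation aggregates replicates", {
  eq <- fluctuation_experiment("v", replicates = c(40, 40, 40, 40))
  s <- summarize_fluctuation(eq)
  expect_equal(s$p_sd, 0)
  expect_equal(s$p_mean, estimate_slippage_rate(40, 1e7))
  expect_false(s$below_detection)

  zero <- summarize_fluctuation(fluctuation_experiment("v", c(0, 0, 0, 0)))
  expect_true(zero$below_detection)
  expect_true(all(is.na(zero$p_per_replicate)))
  expect_true(is.na(zero$p_mean))
  expect_equal(zero$detection_limit, estimate_slippage_rate(1, 1e7))

  # mixed: finite replicates summarized, below_detection still flagged
  mix <- summarize_fluctuation(fluctuation_experiment("v", c(0, 40, 40, 40)))
  expect_true(mix$below_detection)
  expect_equal(mix$p_mean, estimate_slippage_rate(40, 1e7))

  expect_error(fluctuation_experiment("v", numeric(0)), "non-empty")
})

test_that("fold_change reproduces the published display convention", {
  expect_equal(fold_change(5.3e-5, 3.8e-7, display = TRUE), 140)
  expect_equal(fold_change(5.1e-4, 3.8e-7, display = TRUE), 1340)
  # raw ratios retained without display rounding
  expect_equal(fold_change(5.3e-5, 3.8e-7), 5.3e-5 / 3.8e-7)
  for (p in 10^seq(-8, -3)) expect_equal(fold_change(p, p), 1)
  expect_error(fold_change(1e-5, 0), "positive")
})

test_that("mutation_frequency divides counts by plated cells", {
  exp <- mutagenesis_experiment("v", 4, c(30, 0), cells_plated = 1.5e6)
  f <- mutation_frequency(exp)
  expect_equal(f$freq_per_replicate, c(2e-5, 0))
  expect_equal(f$freq_mean, 1e-5)
  exp$cells_plated <- 0
  expect_error(mutation_frequency(exp), "positive")
})

test_that("mutation_frequency recovers a simulated Poisson rate", {
  set.seed(21)
  f_true <- 1e-5; cells <- 1.5e6; n <- 200
  counts <- rpois(n, f_true * cells)
  f <- mutation_frequency(mutagenesis_experiment("v", 4, counts, cells))
  se <- sqrt(f_true / cells / n)  # Poisson SE of the mean frequency
  expect_lt(abs(f$freq_mean - f_true), 3 * se)
})
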