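sim_truth <- data.frame(variant_id = c("PATH", "POLY"),
                        abrogates_mmr = c(TRUE, FALSE))

test_that("simulators are bit-reproducible under a fixed seed", {
  p <- screen_sim_params(rng_seed = 42)
  expect_identical(simulate_screen(sim_truth, p), simulate_screen(sim_truth, p))
  expect_false(identical(simulate_screen(sim_truth, p),
                         simulate_screen(sim_truth, screen_sim_params(rng_seed = 43))))

  fp <- fluct_sim_params(2e-4, rng_seed = 9)
  expect_identical(simulate_fluctuation_assay(fp)$replicates,
                   simulate_fluctuation_assay(fp)$replicates)

  m1 <- simulate_mnng_assay(1e-6, 1e-5, rng_seed = 4)
  m2 <- simulate_mnng_assay(1e-6, 1e-5, rng_seed = 4)
  expect_identical(m1$dose4$resistant_colonies, m2$dose4$resistant_colonies)
})

test_that("degenerate screen regimes behave as stated", {
  off <- screen_sim_params(targeting_efficiency = 0, loh_survivor_rate = 0,
                           background_survivor_rate = 0, rng_seed = 1)
  warns <- capture_warnings(res <- simulate_screen(sim_truth, off))
  expect_length(warns, 2)  # one empty-panel warning per variant
  expect_match(warns, "no 6TG survivors", all = TRUE)
  expect_equal(nrow(res), 0)

  pure <- screen_sim_params(loh_survivor_rate = 0, background_survivor_rate = 0,
                            rng_seed = 1)
  res <- simulate_screen(data.frame(variant_id = "PATH", abrogates_mmr = TRUE),
                         pure)
  expect_true(all(res$sequence_call == "planned_mutation"))
  expect_equal(nrow(res), 18)
})

test_that("picked-colony composition matches the calibrated regime", {
  # mean non-LOH picked fraction over 500 simulated panels per class;
  # calibration targets are 0.40 (abrogating) and 0.06 (neutral)
  f <- vapply(1:500, function(s) {
    co <- simulate_screen(sim_truth, screen_sim_params(rng_seed = s))
    cc <- classify_and_call(co)
    c(1 - cc$f_loh[cc$variant_id == "PATH"],
      1 - cc$f_loh[cc$variant_id == "POLY"])
  }, numeric(2))
  expect_lt(abs(mean(f[1, ]) - 0.40), 0.03)
  expect_lt(abs(mean(f[2, ]) - 0.06), 0.015)
})

test_that("screen category counts follow their binomial expectations", {
  params <- screen_sim_params(rng_seed = 123)
  n_rep <- 500
  counts <- vapply(1:n_rep, function(s) {
    co <- simulate_screen(data.frame(variant_id = "PATH", abrogates_mmr = TRUE),
                          screen_sim_params(rng_seed = 1e6 + s))
    cc <- classify_and_call(co)
    c(cc$n_confirmed, cc$n_loh, cc$n_background)
  }, numeric(3))
  n <- params$n_cells_selected
  e_mut <- n * params$targeting_efficiency
  e_loh <- n * params$loh_survivor_rate
  e_bg <- n * params$background_survivor_rate
  probs <- c(e_mut, e_loh, e_bg) / (e_mut + e_loh + e_bg)
  for (k in 1:3) {
    exp_k <- 18 * probs[k]
    se_k <- sqrt(18 * probs[k] * (1 - probs[k]) / n_rep)
    expect_lt(abs(mean(counts[k, ]) - exp_k), 4 * se_k)
  }
})

test_that("fluctuation simulator matches its closed-form expectation", {
  # main simulator at full plating: expected mutant colonies are
  # p * n_final * log2(n_final / n_start)
  p <- 1e-4; G <- 14
  fp <- fluct_sim_params(p, n_start = 1, n_final = 2^G,
                         cells_per_plate = 2^G, n_plates = 1,
                         n_replicates = 500, rng_seed = 31)
  sim <- simulate_fluctuation_assay(fp)
  expected <- p * 2^G * G
  reps <- sim$replicates
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 3 * se)

  # independent per-cell enumeration at the same size agrees with both
  set.seed(77)
  enum <- vapply(1:500, function(i) oracle_enumerate_mutants(p, 1, G), numeric(1))
  se2 <- sqrt(sd(enum)^2 / 500 + se^2)
  expect_lt(abs(mean(enum) - mean(reps)), 4 * se2)
})

test_that("fluctuation counts carry the jackpot signature and edge cases", {
  expect_equal(simulate_fluctuation_assay(
    fluct_sim_params(0, rng_seed = 2))$replicates, rep(0L, 4))

  # replicate variance exceeds the mean (over-dispersion from jackpots)
  over <- vapply(1:200, function(s) {
    r <- simulate_fluctuation_assay(
      fluct_sim_params(1e-5, n_final = 2^20, n_replicates = 8,
                       cells_per_plate = 2^20, n_plates = 1,
                       rng_seed = s))$replicates
    var(r) > mean(r)
  }, logical(1))
  expect_gt(mean(over), 0.8)

  expect_error(simulate_fluctuation_assay(fluct_sim_params(0.5, n_final = 2^10,
                                                           cells_per_plate = 2^10,
                                                           n_plates = 1,
                                                           rng_seed = 1)),
               class = "mmrscreen_saturation")
  expect_error(fluct_sim_params(1e-4, n_start = 3, n_final = 1e7),
               "power-of-two")
})

test_that("MNNG simulator draws Poisson counts at the stated means", {
  z <- simulate_mnng_assay(0, 1e-5, rng_seed = 8)
  expect_true(all(z$dose0$resistant_colonies == 0))

  many <- simulate_mnng_assay(1e-6, 1e-5, cells_plated = 1.5e6,
                              n_replicates = 1000, rng_seed = 13)
  se <- sqrt(15 / 1000)  # Poisson mean 15, SE of the mean over 1000 draws
  expect_lt(abs(mean(many$dose4$resistant_colonies) - 15), 3 * se)

  # round trip with the analysis layer: recover the induced frequency
  f <- mutation_frequency(many$dose4)
  se_f <- sqrt(1e-5 / 1.5e6 / 1000)
  expect_lt(abs(f$freq_mean - 1e-5), 3 * se_f)

  expect_error(simulate_mnng_assay(0.5, 1e-5), "\\[0, 1e-2\\]")
})

test_that("a simulated proof-of-principle study evaluates cleanly", {
  truth9 <- data.frame(
    variant_id = c(sprintf("PATH%d", 1:4), sprintf("POLY%d", 1:5)),
    abrogates_mmr = rep(c(TRUE, FALSE), c(4, 5)))
  clean <- vapply(1:100, function(s) {
    co <- simulate_screen(truth9, screen_sim_params(rng_seed = 2000 + s))
    cc <- classify_and_call(co, truth9$variant_id)
    truth <- data.frame(variant_id = truth9$variant_id,
                        prior_label = ifelse(truth9$abrogates_mmr,
                                             "pathogenic", "non_pathogenic"))
    rep_ <- screen_performance(cc, truth)
    rep_$n_detected == 4 && rep_$n_false_positive == 0
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})
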