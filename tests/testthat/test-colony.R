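test_that("classify_colony maps genotyping read-outs to the three categories", {
  expect_equal(classify_colony("wt_allele_lost", "not_tested"), "loh")
  expect_equal(classify_colony("both_alleles_present", "planned_mutation"),
               "confirmed_mutant")
  expect_equal(classify_colony("both_alleles_present", "no_mutation"),
               "background")
  # vectorized
  expect_equal(
    classify_colony(c("wt_allele_lost", "both_alleles_present"),
                    c("not_tested", "planned_mutation")),
    c("loh", "confirmed_mutant"))
})

test_that("classify_colony rejects inconsistent and unknown inputs", {
  expect_error(classify_colony("both_alleles_present", "not_tested"),
               "not sequenced")
  expect_error(classify_colony("wt_allele_lost", "planned_mutation"),
               "excluded before sequencing")
  expect_error(classify_colony("maybe", "not_tested"), "unknown allele_pcr")
  expect_error(classify_colony("wt_allele_lost", "dunno"),
               "unknown sequence_call")
})

test_that("colony_fractions computes category fractions summing to one", {
  f <- colony_fractions(make_panel("v", n_loh = 17, n_bg = 1))
  expect_equal(f$f_loh, 17 / 18)
  expect_equal(f$f_background, 1 / 18)
  expect_equal(f$f_confirmed, 0)

  f <- colony_fractions(make_panel("v", n_mut = 18))
  expect_equal(f$f_confirmed, 1)
  expect_equal(f$f_loh + f$f_background, 0)

  expect_error(colony_fractions(make_panel("v")),
               class = "mmrscreen_empty_panel")
})

test_that("classification partitions panels and fractions sum to 1 exactly", {
  set.seed(7)
  for (i in 1:25) {
    counts <- as.vector(rmultinom(1, sample(1:40, 1), c(0.6, 0.1, 0.3)))
    panel <- make_panel("v", n_loh = counts[1], n_bg = counts[2],
                        n_mut = counts[3])
    if (nrow(panel) == 0) next
    cats <- classify_colony(panel$allele_pcr, panel$sequence_call)
    expect_length(cats, nrow(panel))  # every colony gets exactly one category
    f <- colony_fractions(panel)
    expect_equal(f$f_loh + f$f_background + f$f_confirmed, 1)
  }
})

test_that("aggregate_rounds sums panels and records orientations", {
  single <- make_panel("v", n_loh = 17, n_bg = 1)
  agg <- aggregate_rounds(single)
  expect_equal(agg[c("n_confirmed", "n_background", "n_loh", "n_total")],
               list(n_confirmed = 0L, n_background = 1L, n_loh = 17L,
                    n_total = 18L))
  expect_equal(agg$rounds_used, "antisense")

  both <- rbind(make_panel("v", "antisense", n_loh = 18),
                make_panel("v", "sense", n_loh = 12, n_bg = 1, n_mut = 5))
  agg <- aggregate_rounds(both)
  expect_equal(agg$n_confirmed, 5L)
  expect_equal(agg$n_total, 36L)
  expect_equal(agg$rounds_used, c("antisense", "sense"))

  # one confirmed in each round crosses the two-colony threshold jointly
  two <- rbind(make_panel("v", "antisense", n_loh = 17, n_mut = 1),
               make_panel("v", "sense", n_loh = 17, n_mut = 1))
  expect_equal(aggregate_rounds(two)$n_confirmed, 2L)
})

test_that("aggregate_rounds enforces its preconditions", {
  mixed <- rbind(make_panel("a", n_loh = 1), make_panel("b", n_loh = 1))
  expect_error(aggregate_rounds(mixed), "single variant")
  expect_error(aggregate_rounds(make_panel("v", "sense", n_loh = 18)),
               "sense is a retry")
})

test_that("call_variant applies the two-independent-colony rule", {
  call_n <- function(n_conf, n_bg = 0, n_loh = 0)
    call_variant(list(variant_id = "v", n_confirmed = n_conf,
                      n_background = n_bg, n_loh = n_loh,
                      n_total = n_conf + n_bg + n_loh,
                      rounds_used = "antisense"))$call
  expect_equal(call_n(2, n_bg = 3, n_loh = 13), "mmr_abrogating")
  expect_equal(call_n(0, n_bg = 1, n_loh = 17), "not_detected")
  expect_equal(call_n(1, n_loh = 17), "inconclusive")
  expect_error(call_n(-1), "non-negative")
})

test_that("call_variant is monotone in confirmed colonies", {
  # adding a confirmed colony never demotes an mmr_abrogating call
  for (n_conf in 0:6) {
    for (extra in 1:3) {
      a <- call_variant(list(variant_id = "v", n_confirmed = n_conf,
                             n_background = 2, n_loh = 10,
                             n_total = 12 + n_conf, rounds_used = "antisense"))
      b <- call_variant(list(variant_id = "v", n_confirmed = n_conf + extra,
                             n_background = 2, n_loh = 10,
                             n_total = 12 + n_conf + extra,
                             rounds_used = "antisense"))
      if (a$call == "mmr_abrogating") expect_equal(b$call, "mmr_abrogating")
    }
  }
})

test_that("classify_and_call drives the per-variant pipeline", {
  colonies <- rbind(make_panel("hit", n_loh = 11, n_bg = 1, n_mut = 6),
                    make_panel("poly", n_loh = 17, n_bg = 1))
  calls <- classify_and_call(colonies)
  expect_equal(calls$call[calls$variant_id == "hit"], "mmr_abrogating")
  expect_equal(calls$call[calls$variant_id == "poly"], "not_detected")
  expect_equal(calls$f_confirmed[calls$variant_id == "hit"], 6 / 18)

  # a requested variant with no colonies is reported not_detected, with a warning
  expect_warning(calls <- classify_and_call(colonies, c("hit", "poly", "ghost")),
                 "ghost")
  expect_equal(calls$call[calls$variant_id == "ghost"], "not_detected")
  expect_equal(calls$n_total[calls$variant_id == "ghost"], 0L)

  # duplicate colony row within a (variant, round) panel is an error
  dup <- rbind(colonies, colonies[1, ])
  expect_error(classify_and_call(dup), "duplicate")
})
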