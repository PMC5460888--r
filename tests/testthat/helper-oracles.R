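# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Fixed-grid + bisection root of 0.6*G = x*log(x) (x = N*p), written
# without reference to estimate_slippage_rate: scan a coarse grid for the
# sign change, then bisect.
oracle_slippage <- function(G, N) {
  target <- 0.6 * G
  f <- function(x) x * log(x) - target
  grid <- exp(seq(log(1 + 1e-9), log(1e12), length.out = 4096))
  i <- which(f(grid) > 0)[1]
  lo <- grid[i - 1]; hi <- grid[i]
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / N
}

# Direct per-cell enumeration of the doubling-growth mutation process:
# every generation each wild-type cell divides and each daughter mutates
# independently with probability p; mutants breed true. Tractable only for
# small n_final.
oracle_enumerate_mutants <- function(p, n_start, generations) {
  wt <- n_start
  mut <- 0
  for (g in seq_len(generations)) {
    wt <- 2 * wt
    mut <- 2 * mut
    new_mut <- rbinom(1, wt, p)
    wt <- wt - new_mut
    mut <- mut + new_mut
  }
  mut
}

# Brute-force confusion-matrix evaluation: counts over explicit vectors of
# truth labels and detected flags, with the zero-failure bound applied by
# direct case analysis.
oracle_performance <- function(truth_pathogenic, detected) {
  pos <- which(truth_pathogenic)
  neg <- which(!truth_pathogenic)
  n_det <- sum(detected[pos])
  n_fp <- sum(detected[neg])
  sens_pt <- 100 * n_det / length(pos)
  spec_pt <- 100 * (length(neg) - n_fp) / length(neg)
  list(
    sensitivity_point = sens_pt,
    specificity_point = spec_pt,
    sensitivity_bound = if (n_det == length(pos))
      100 * (length(pos) - 1) / length(pos) else sens_pt,
    specificity_bound = if (n_fp == 0)
      100 * (length(neg) - 1) / length(neg) else spec_pt)
}

# Build a colony data frame from category counts (possibly empty).
make_panel <- function(variant_id, round = "antisense", n_loh = 0, n_bg = 0,
                       n_mut = 0) {
  cat_ <- c(rep("loh", n_loh), rep("bg", n_bg), rep("mut", n_mut))
  if (length(cat_) == 0)
    return(data.frame(variant_id = character(), round = character(),
                      colony_id = character(), allele_pcr = character(),
                      sequence_call = character(), stringsAsFactors = FALSE))
  data.frame(
    variant_id = variant_id, round = round,
    colony_id = sprintf("%s_%s_%02d", variant_id, round, seq_along(cat_)),
    allele_pcr = ifelse(cat_ == "loh", "wt_allele_lost", "both_alleles_present"),
    sequence_call = ifelse(cat_ == "loh", "not_tested",
                    ifelse(cat_ == "mut", "planned_mutation", "no_mutation")),
    stringsAsFactors = FALSE)
}

fixture_path <- function(name) system.file("extdata", name, package = "mmrscreen")
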