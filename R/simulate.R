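# Stochastic simulators of the screen and of the reporter fluctuation
# assay. These generate synthetic datasets with the statistical structure
# the analysis layer assumes, so every pipeline stage can be exercised and
# round-tripped without bench data.

#' Survivor rates reproducing the observed picked-colony composition
#'
#' Closed-form calibration of the per-cell LOH and background survivor
#' rates: with targeting efficiency e, LOH rate l and background rate b,
#' the expected non-LOH fraction among picked colonies is
#' `(e + b) / (e + b + l)` for an MMR-abrogating variant (targeted cells
#' survive selection) and `b / (b + l)` for a neutral one. Solving both for
#' the observed fractions (defaults 0.40 and 0.06) gives
#' `l = (1 - f_path) * e / (f_path - (1 - f_path) * q)` with
#' `q = f_poly / (1 - f_poly)`, and `b = l * q`.
#'
#' @param f_path target mean non-LOH picked fraction for MMR-abrogating
#'   variants (default 0.40).
#' @param f_poly target mean non-LOH picked fraction for neutral variants
#'   (default 0.06).
#' @param targeting_efficiency per-cell probability of oligo-directed base
#'   substitution (default 1e-3).
#' @return list with `loh_survivor_rate` and `background_survivor_rate`.
#' @export
calibrate_survivor_rates <- function(f_path = 0.40, f_poly = 0.06,
                                     targeting_efficiency = 1e-3) {
  q <- f_poly / (1 - f_poly)
  denom <- f_path - (1 - f_path) * q
  if (denom <= 0) .stop("infeasible calibration targets")
  l <- (1 - f_path) * targeting_efficiency / denom
  list(loh_survivor_rate = l, background_survivor_rate = l * q)
}

#' Parameters for the screen simulator
#'
#' Defaults restate the screen's stated regime: ~1 per 1000 exposed cells
#' acquires the planned substitution, 1.5e6 cells enter 6TG selection, and
#' the 18 largest resistant colonies are picked. The LOH and background
#' survivor rates are not printed anywhere; their defaults come from
#' [calibrate_survivor_rates()] (stored in `inst/extdata/sim_defaults.json`)
#' so that mean picked-colony compositions match the observed ~40%
#' (MMR-abrogating) and ~6% (neutral) non-LOH fractions.
#'
#' @param targeting_efficiency probability a selected cell carries the
#'   planned substitution.
#' @param n_cells_selected cells subjected to 6TG selection.
#' @param loh_survivor_rate,background_survivor_rate per-cell survival
#'   probabilities for the two confounding routes; `NULL` loads the
#'   calibrated defaults.
#' @param n_colonies_picked colonies genotyped per panel.
#' @param rng_seed integer seed.
#' @return list of class `screen_sim_params`.
#' @export
screen_sim_params <- function(targeting_efficiency = 1e-3,
                              n_cells_selected = 1.5e6,
                              loh_survivor_rate = NULL,
                              background_survivor_rate = NULL,
                              n_colonies_picked = 18L,
                              rng_seed = 1L) {
  if (is.null(loh_survivor_rate) || is.null(background_survivor_rate)) {
    cfg <- default_sim_config()
    if (is.null(loh_survivor_rate)) loh_survivor_rate <- cfg$loh_survivor_rate
    if (is.null(background_survivor_rate))
      background_survivor_rate <- cfg$background_survivor_rate
  }
  pr <- c(targeting_efficiency, loh_survivor_rate, background_survivor_rate)
  if (any(pr < 0) || any(pr > 1)) .stop("rates must lie in [0, 1]")
  structure(list(targeting_efficiency = targeting_efficiency,
                 n_cells_selected = n_cells_selected,
                 loh_survivor_rate = loh_survivor_rate,
                 background_survivor_rate = background_survivor_rate,
                 n_colonies_picked = as.integer(n_colonies_picked),
                 rng_seed = as.integer(rng_seed)),
            class = "screen_sim_params")
}

#' Calibrated simulator defaults bundled with the package
#'
#' @return named list read from `inst/extdata/sim_defaults.json`.
#' @export
default_sim_config <- function() {
  path <- system.file("extdata", "sim_defaults.json", package = "mmrscreen")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Simulate one screening round for a set of variants
#'
#' Per variant: binomial draws over `n_cells_selected` cells give the
#' targeted, LOH-survivor and background-survivor counts; targeted cells
#' survive 6TG selection iff the variant abrogates MMR; `n_colonies_picked`
#' colonies are then drawn without replacement from the surviving pool
#' (picking is uniform over survivors; colony size is not modelled) and
#' emitted as genotyping rows consistent with their latent category.
#'
#' @param variants data frame with columns `variant_id` and
#'   `abrogates_mmr` (logical ground truth of the simulated variant's MMR
#'   effect).
#' @param params a [screen_sim_params()] object.
#' @param round screening round label (default `"antisense"`).
#' @return colony table (columns `variant_id`, `round`, `colony_id`,
#'   `allele_pcr`, `sequence_call`) shaped exactly like [read_colonies()]
#'   output; variants with zero survivors contribute no rows and raise a
#'   warning. The truth is attached as attribute `"truth"`.
#' @export
simulate_screen <- function(variants, params = screen_sim_params(),
                            round = "antisense") {
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "abrogates_mmr") %in% names(variants)))
  set.seed(params$rng_seed)
  n <- params$n_cells_selected
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    n_targeted <- rbinom(1, n, params$targeting_efficiency)
    n_loh <- rbinom(1, n, params$loh_survivor_rate)
    n_bg <- rbinom(1, n, params$background_survivor_rate)
    n_mut <- if (variants$abrogates_mmr[i]) n_targeted else 0L
    pool <- c(rep("confirmed_mutant", n_mut), rep("loh", n_loh),
              rep("background", n_bg))
    if (length(pool) == 0) {
      warning(sprintf("variant %s: no 6TG survivors; empty panel",
                      variants$variant_id[i]))
      next
    }
    picked <- sample(pool, min(params$n_colonies_picked, length(pool)))
    out[[i]] <- data.frame(
      variant_id = variants$variant_id[i],
      round = round,
      colony_id = sprintf("%s_%s_c%02d", variants$variant_id[i], round,
                          seq_along(picked)),
      allele_pcr = ifelse(picked == "loh", "wt_allele_lost", "both_alleles_present"),
      sequence_call = ifelse(picked == "loh", "not_tested",
                      ifelse(picked == "confirmed_mutant", "planned_mutation",
                             "no_mutation")),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(variant_id = character(), round = character(),
                      colony_id = character(), allele_pcr = character(),
                      sequence_call = character(), stringsAsFactors = FALSE)
  attr(res, "truth") <- variants
  res
}

#' Parameters for the fluctuation-assay simulator
#'
#' The growth model is synchronous doubling: the culture starts from
#' `n_start` cells and doubles for `log2(n_final / n_start)` generations,
#' so `n_final` must be a power-of-two multiple of `n_start`. The default
#' expansion (`n_start = 1`, `n_final = 2^23 = 8388608`) is the closest
#' power of two to the assay's nominal 1e7-cell expansion.
#'
#' @param p_true slippage rate per cell division.
#' @param n_start,n_final expansion end points.
#' @param cells_per_plate,n_plates plating geometry; the default plates
#'   (nearly) the whole expanded culture.
#' @param plating_efficiency probability a plated mutant cell forms a
#'   colony (default 1: idealized plating, matching the estimator's
#'   assumption that colony totals count mutant cells).
#' @param n_replicates independent replicate cultures (default 4).
#' @param rng_seed integer seed.
#' @return list of class `fluct_sim_params`.
#' @export
fluct_sim_params <- function(p_true, n_start = 1, n_final = 2^23,
                             cells_per_plate = 1e5,
                             n_plates = floor(n_final / cells_per_plate),
                             plating_efficiency = 1,
                             n_replicates = 4L, rng_seed = 1L) {
  if (n_start < 1 || n_final < n_start) .stop("need n_final >= n_start >= 1")
  g <- log2(n_final / n_start)
  if (abs(g - round(g)) > 1e-9)
    .stop("n_final must be a power-of-two multiple of n_start (doubling growth model)")
  if (cells_per_plate * n_plates > n_final)
    .stop("cannot plate more cells than the expansion produced")
  if (p_true < 0 || plating_efficiency < 0 || plating_efficiency > 1)
    .stop("invalid rate parameter")
  structure(list(p_true = p_true, n_start = n_start, n_final = n_final,
                 generations = as.integer(round(g)),
                 cells_per_plate = cells_per_plate, n_plates = n_plates,
                 plating_efficiency = plating_efficiency,
                 n_replicates = as.integer(n_replicates),
                 rng_seed = as.integer(rng_seed)),
            class = "fluct_sim_params")
}

#' Simulate a replicated fluctuation assay
#'
#' Event/clone-size formulation of the Luria-Delbrueck process: in
#' generation `g` (population `n_start * 2^g`) the number of new mutation
#' events is Poisson with mean `p_true * n_start * 2^g`; each event founds
#' a mutant clone that doubles through the remaining generations to size
#' `2^(G - g)`. The expected final mutant-cell count is therefore
#' `p_true * n_final * log2(n_final / n_start)`, while early "jackpot"
#' events give the characteristic heavy right tail. Plated colony counts
#' are binomial over the plated fraction of the culture and the plating
#' efficiency.
#'
#' @param params a [fluct_sim_params()] object.
#' @return a [fluctuation_experiment()] whose `replicates` are the
#'   simulated Geneticin-resistant colony totals (one per replicate
#'   culture) and whose `n_expanded` is `n_final`; the per-replicate
#'   mutant-cell counts are attached as attribute `"mutant_cells"`.
#' @export
simulate_fluctuation_assay <- function(params) {
  stopifnot(inherits(params, "fluct_sim_params"))
  set.seed(params$rng_seed)
  G <- params$generations
  plated_fraction <- params$cells_per_plate * params$n_plates / params$n_final
  counts <- integer(params$n_replicates)
  mutants <- numeric(params$n_replicates)
  for (r in seq_len(params$n_replicates)) {
    m <- 0
    for (g in seq_len(G)) {
      events <- rpois(1, params$p_true * params$n_start * 2^g)
      m <- m + events * 2^(G - g)
    }
    if (m > params$n_final)
      .stop("mutant cells exceed the population: p_true too large (saturation)",
            class = "mmrscreen_saturation")
    mutants[r] <- m
    plated <- rbinom(1, m, plated_fraction)
    counts[r] <- rbinom(1, plated, params$plating_efficiency)
  }
  exp <- fluctuation_experiment(
    variant_id = sprintf("sim_p%g", params$p_true),
    replicates = counts, n_expanded = params$n_final,
    cells_per_plate = params$cells_per_plate, n_plates = params$n_plates)
  attr(exp, "mutant_cells") <- mutants
  exp
}

#' Simulate the MNNG mutagenesis assay
#'
#' Colony counts are Poisson with mean `frequency * cells_plated` for the
#' untreated (dose 0) and MNNG-treated (dose 4 uM) arms.
#'
#' @param spontaneous_freq,induced_freq Hprt mutant frequencies per plated
#'   cell for the two arms (must lie in \[0, 1e-2\]).
#' @param cells_plated cells transferred to 6TG selection (default 1.5e6).
#' @param n_replicates replicates per arm (default 2, the assay's design).
#' @param rng_seed integer seed.
#' @param variant_id label for the simulated cell line.
#' @return list with components `dose0` and `dose4`, each a
#'   [mutagenesis_experiment()].
#' @export
simulate_mnng_assay <- function(spontaneous_freq, induced_freq,
                                cells_plated = 1.5e6, n_replicates = 2L,
                                rng_seed = 1L, variant_id = "sim") {
  if (any(c(spontaneous_freq, induced_freq) < 0) ||
      any(c(spontaneous_freq, induced_freq) > 1e-2))
    .stop("frequencies must lie in [0, 1e-2]")
  set.seed(rng_seed)
  draw <- function(freq) rpois(n_replicates, freq * cells_plated)
  list(dose0 = mutagenesis_experiment(variant_id, 0, draw(spontaneous_freq),
                                      cells_plated),
       dose4 = mutagenesis_experiment(variant_id, 4, draw(induced_freq),
                                      cells_plated))
}
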