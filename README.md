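# mmrscreen

Analysis toolkit for a cell-based functional screen that classifies *MSH6*
missense variants of uncertain significance (VUS) by their effect on DNA
mismatch repair (MMR). Suspected Lynch-syndrome families carry many such
variants; whether a given one inactivates MMR decides who needs intensive
cancer surveillance. The screen introduces each candidate variant into the
single active *Msh6* allele of *Msh6*^+/-
mouse embryonic stem cells by oligonucleotide-directed mutagenesis
(~10⁻³ per cell), selects MMR-deficient survivors with 6-thioguanine (6TG),
excludes loss-of-heterozygosity (LOH) survivors by allele-specific PCR, and
sequences the retained colonies for the planned mutation.

The package implements the complete analysis layer for whoever runs or
audits such a screen:

* **Colony classification & calling** — `classify_colony()`,
  `aggregate_rounds()` (antisense round plus optional sense retry),
  `call_variant()` with the two-independent-colonies pathogenicity rule,
  and `colony_fractions()` for the LOH / background / confirmed split.
* **Performance** — `screen_performance()` with zero-failure lower bounds:
  with all *n* labelled cases handled correctly, the reported bound is
  100·(n−1)/n % (error rate "< 1/n").
* **Rates** — `estimate_slippage_rate()` solves the fluctuation-assay
  relation `0.6·G = N·p·log(N·p)` for the per-division slippage rate *p* of
  a (G)₁₀-*neo* frameshift reporter; `fold_change()`,
  `mutation_frequency()` (MNNG-induced *Hprt* mutants),
  `welch_one_tailed()` and `significance_stars()`.
* **Protein levels** — `relative_protein_level()`, loading-normalized
  percent of the MMR-proficient control lane.
* **Simulation** — seeded generators for the whole screen
  (`simulate_screen()`), Luria–Delbrück fluctuation counts
  (`simulate_fluctuation_assay()`), Poisson MNNG counts
  (`simulate_mnng_assay()`), plus targeting-oligo design (`design_lmo()`).
* **Pipeline / CLI** — `run_classify()`, `run_evaluate()`, `run_rates()`,
  `run_mnng()`, `run_simulate()`, `run_report()`, and a command-line
  wrapper (`mmrscreen_cli()`; executable script in `inst/cli/mmrscreen.R`).

See `vignettes/mmrscreen-methods.Rmd` for the models, calibration and
design decisions.

## Worked example

Running the bundled fixture study (9 proof-of-principle variants plus 26
screened VUS, transcribed from the published panels):

```r
library(mmrscreen)
vp <- system.file("extdata", "variants.tsv", package = "mmrscreen")
cp <- system.file("extdata", "colonies.tsv", package = "mmrscreen")
calls <- classify_and_call(read_colonies(cp), read_variants(vp)$variant_id)
head(calls[calls$call == "mmr_abrogating", 1:6], 4)
#>  variant_id           call n_confirmed n_loh n_background rounds_used
#>       V397E mmr_abrogating           6    11            1   antisense
#>       L448P mmr_abrogating           7    11            0   antisense
#>      R1332Q mmr_abrogating           7    11            0   antisense
#>      G1139S mmr_abrogating           7    11            0   antisense
screen_performance(calls, read_variants(vp))
#> <performance_report>
#>   sensitivity: 7/7 detected, point 100.0%, zero-failure bound >85.7%
#>   specificity: 0/10 false positive, point 100.0%, zero-failure bound >90.0%
#>   excluded (uncertain label): R511G, F706S, E1193K, ...
```

All 7 truth-pathogenic variants carry the planned mutation in ≥2
independent colonies (call `mmr_abrogating`), and none of the 10
truth-non-pathogenic variants does — hence sensitivity >85.7% and
specificity >90.0% under the zero-failure convention.

A slippage rate from quadruplicate Geneticin counts:

```r
fl <- read_fluctuation(system.file("extdata", "fluctuation.tsv", package = "mmrscreen"))
summarize_fluctuation(fl$V397E)
#> <slippage_rate_estimate> V397E: p = 0.0001918 +/- 1.5e-05 (4 replicates)
fold_change(summarize_fluctuation(fl$V397E)$p_mean, 3.8e-7, display = TRUE)
#> [1] 500
```

i.e. this MMR-deficient line slips ~500× faster than the MMR-proficient
control rate of 3.8×10⁻⁷ per division.

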