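---
title: "Methods: models and design choices in mmrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in mmrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmrscreen)
```

## The assay this package analyses

Lynch syndrome is caused by inactivating germline variants in DNA mismatch
repair (MMR) genes; missense variants of uncertain significance (VUS) in
*MSH6* are common and hard to classify clinically. The functional screen
analysed here introduces a candidate variant into the single active *Msh6*
allele of *Msh6*^+/-^ mouse embryonic stem cells by oligonucleotide-directed
mutagenesis (efficiency ~10^-3^ per exposed cell), then selects with a mild
dose of 6-thioguanine (6TG), which kills MMR-proficient cells. Surviving
colonies are genotyped in two steps: an allele-specific PCR removes colonies
that became MMR deficient through loss of heterozygosity (LOH) of the
wild-type allele, and the retained colonies are sequenced for the planned
mutation. `mmrscreen` implements the full analysis layer of this screen plus
a stochastic simulator of it.

## Colony classification and the two-colony call

Each picked colony maps deterministically onto one of three categories
(`classify_colony()`): `loh` (wild-type allele lost), `confirmed_mutant`
(both alleles retained, planned mutation present) or `background` (both
alleles retained, no mutation). A colony that retained both alleles but has
no sequencing result is treated as a hard error rather than silently counted
as background: the screen's workflow sequences every retained colony, so a
missing call means data loss.

Because base substitution happens in roughly 1 per 1000 cells, finding the
planned mutation independently in **two** colonies is considered indicative
of MMR abrogation (`call_variant()`). Counts are summed across the antisense
round and, where run, the sense-orientation retry (`aggregate_rounds()`; the
sense round is only valid as a retry after an antisense round). Exactly one
confirmed colony is a case the published study never encountered; we report
it as `inconclusive` rather than forcing it into either class, and
performance evaluation treats it conservatively (not detected, not called
pathogenic). An all-LOH panel is reported as `not_detected` with its counts;
the pipeline does not decide whether to retry in sense orientation — that
remains an experimenter's call.

## Performance bounds

With small, error-free truth sets, point estimates of 100% overstate
certainty. `screen_performance()` therefore reports, alongside the point
estimates, a zero-failure lower bound of `100 * (n - 1) / n` percent when
all `n` labelled cases were handled correctly: with 7 pathogenic variants
all detected the sensitivity is reported as >85.7%, and with 10
non-pathogenic variants none called the specificity as >90.0%. This
convention (error rate "< 1/n") reproduces both published bounds; an exact
binomial interval would be the textbook alternative but is not what the
assay's report format uses. When failures exist the bound field simply
equals the point estimate. Percents are displayed with one decimal.

The truth partition bundled in `inst/extdata/variants.tsv` labels 7
variants pathogenic (three class-5 controls, the previously proven G1139S,
and the three class-4 VUS) and 10 non-pathogenic (five proof-of-principle
polymorphisms, four class-2 VUS, and G566R, proven MMR-proficient a
posteriori in a purified mutant line). All other VUS are `uncertain` and
excluded from evaluation. Which four VUS carry class 2 is not itemized in
the source study's text; the fixture assigns the class to four
screen-negative variants, which is the only property the bound depends on.

## Slippage-rate estimation

Microsatellite instability is read out with a (G)~10~-*neo* frameshift
reporter: uncorrected polymerase slippage restores the *neo* reading frame
and confers Geneticin resistance. After expanding a culture to `N` cells
(nominally 10^7^) and plating under Geneticin, the total resistant-colony
count `G` relates to the slippage rate `p` (events per cell division)
through

$$0.6 \, G \;=\; N p \,\log(N p),$$

a median-style fluctuation-analysis relation. `estimate_slippage_rate()`
solves it for the unique root with `Np > 1` by bisection on `x = Np`
(monotone there, since `d/dx [x log x] = log x + 1 > 0`), to relative
tolerance 10^-12^. Numerical choices:

* **Log base.** The relation is printed without a base. Natural log is the
  default because the `x log x` form and its 0.6 constant come from
  Luria–Delbrück-style estimation; `log_base = "log10"` is available as a
  sensitivity knob. The 0.6 constant itself is taken as given.
* **Zero counts.** `G = 0` is outside the estimator's domain. Rather than
  imputing a rate of zero, the estimator signals a below-detection
  condition carrying the detection limit (the estimate at `G = 1`), and
  `summarize_fluctuation()` propagates a `below_detection` flag.
* **Replicates.** The quadruplicate design is read as one estimate per
  replicate culture, summarized by mean and SD; each replicate's
  `geneticin_total` is its colony count summed over that replicate's
  plates (the alternative per-plate reading is not used and the TSV format
  records per-replicate totals).

Fold changes versus the MMR-proficient control line use the raw ratio; for
display, ratios at or above 100 are rounded to the nearest 10, which is the
unique simple rule reproducing the published "140-fold" (139.5) and
"1340-fold" (1342) endpoints. Raw ratios are always retained.

Rate and frequency comparisons use a hand-implemented one-tailed unpaired
t-test with Welch's correction (`welch_one_tailed()`), direction fixed as
variant > control as in every published comparison; the test suite checks
it against `stats::t.test()` and verifies null p-value uniformity. Star
annotations use strict thresholds 0.05/0.01/0.001/0.0001. No
multiple-testing correction is applied, matching the assay's convention.

## MNNG mutagenesis

MMR-deficient cells tolerate methylation damage and accumulate mutations.
The assay exposes cells to 0 or 4 µM MNNG, plates 1.5×10^6^ cells under
high-dose 6TG and counts *Hprt*-mutant colonies; `mutation_frequency()` is
the per-plated-cell frequency, reported per replicate and as a mean, with
spontaneous and induced arms side by side.

## What the simulator emulates — and what it does not

`simulate_screen()` draws, per variant, binomial counts of targeted cells,
LOH survivors and background survivors among the 1.5×10^6^ selected cells;
targeted cells survive 6TG iff the simulated variant abrogates MMR, and 18
colonies are picked uniformly without replacement from the survivor pool.
The LOH and background per-cell survival rates are nowhere printed; they
are calibrated in closed form (`calibrate_survivor_rates()`, values stored
in `inst/extdata/sim_defaults.json`, not in code) so that the expected
non-LOH fraction among picked colonies is 0.40 for MMR-abrogating variants
and 0.06 for neutral ones — the two aggregates the published figures
report. A single global LOH rate is used; per-variant variation is
unknowable from the aggregates.

`simulate_fluctuation_assay()` uses a synchronous-doubling Luria–Delbrück
model: in generation `g` mutation events are Poisson with mean
`p × n_start × 2^g`, and each event founds a clone that doubles to size
`2^(G-g)`. This makes the expected final mutant count exactly
`p × n_final × log2(n_final/n_start)`, giving a closed form for oracle
tests, while early events produce the characteristic jackpot skew. Because
the growth model doubles, `n_final` must be a power-of-two multiple of
`n_start`; the default expansion is `2^23 ≈ 8.4×10^6`, the closest power of
two to the nominal 10^7. A direct per-cell enumeration simulator (test
helper, capped at small populations) validates the event formulation.
Plating is idealized (efficiency 1, nearly the whole culture plated),
matching the estimator's assumption that colony totals count mutant cells.

Deliberate divergences from the bench protocol: colony *size* is not
modelled (the protocol picks the 18 largest colonies; picking here is
uniform over survivors), survival is a per-cell Bernoulli contract with no
transfection or LNA-chemistry biology, growth is synchronous, and 6TG
dose–response curves are out of scope. A green simulation test therefore
establishes that the analysis layer recovers the parameters of *this*
stated generative world — not that it would be robust to, say,
size-biased picking or asynchronous growth.

`design_lmo()` builds the mutant oligo window centered on the first changed
base of the codon substitution, shifting the window just enough to fit when
the substitution lies near a sequence end, and reports the substitution in
1-based reference coordinates; the antisense oligo is the reverse
complement. Default length is 35 nt and configurable; LNA chemistry is not
represented.

## Interfaces and determinism

TSV with mandatory headers is the canonical dialect ('.' decimal mark,
rates serialized in scientific notation with 4 significant digits, percents
with one decimal). Every writer round-trips through its reader, and the
whole simulate → classify → evaluate chain is byte-identical under a fixed
seed — both properties are asserted in the test suite. Stage boundaries log
record counts so silent data loss is visible.

## Known limitations

* The per-colony fixture rows are reconstructions consistent with
  published per-panel aggregates; only the aggregates themselves are
  authoritative (see `inst/extdata/README.md`).
* The zero-failure bound convention `(n-1)/n` is inferred from the
  published numbers, not stated by them.
* No maximum-likelihood (Ma–Sandri–Sarkar) fluctuation estimator is
  provided; the published closed-form relation is the contract, and the
  simulator exists to validate it at realistic parameter values (recovery
  within a factor of two, which is the realistic accuracy of this class of
  estimator at quadruplicate scale).
* Splice-site and intronic variants can evade the mouse-cell screen for
  species reasons the analysis layer cannot see; labels, not sequences,
  are its inputs.
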