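# Bundled fixtures

Regenerate with `Rscript tools/make_fixtures.R` from the repository root.

- `variants.tsv` — the 9 proof-of-principle variants plus the 26 screened
  VUS with InSiGHT classes and a priori / a posteriori truth labels
  (`prior_label`). Four proof-of-principle polymorphisms are not named in
  the source study's text and carry placeholder ids `POLY-A..POLY-D`; three
  pathogenic controls are identified by their mouse amino-acid names.
- `colonies.tsv` — per-colony genotyping rows (18 picked colonies per
  panel; sense rows are orientation retries). Panel-level aggregates
  (non-LOH fractions ~40% for MMR-abrogating and ~6% for neutral variants,
  confirmed-colony counts including the 2-of-5 and 2-of-4 panels, the
  single unconfirmed non-LOH colony among the pathogenic proof-of-principle
  panels) transcribe the published figures; the per-colony breakdown within
  those aggregates is a deterministic reconstruction, since only aggregates
  were published. Nucleotide-change strings for undetected variants are
  unpublished and left NA.
- `fluctuation.tsv` — small fluctuation-assay fixture: a MMR-proficient
  control near 3.8e-7, a pathogenic line near 1.9e-4, an analytic unit row
  (`UNIT`, geneticin_total = e/0.6, deliberately non-integer) and an
  all-zero below-detection row.
- `mnng.tsv` — duplicate MNNG assay counts for a control and a deficient
  line at 0 and 4 uM.
- `sim_defaults.json` — calibrated simulator defaults (see
  `calibrate_survivor_rates()`).
- `cds_synthetic.fa` — synthetic toy coding sequence for oligo-design
  examples; not a real gene.
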