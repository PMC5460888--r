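# Regenerates the plain-text fixtures under inst/extdata/.
# Panel compositions follow the printed per-variant aggregates (non-LOH
# fractions, confirmed-colony counts); per-colony rows are a deterministic
# reconstruction consistent with those aggregates (see inst/extdata/README.md).
# Run from the repository root: Rscript tools/make_fixtures.R

outdir <- "inst/extdata"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

# --- simulator defaults (closed-form calibration; see calibrate_survivor_rates)
f_path <- 0.40; f_poly <- 0.06; eff <- 1e-3
q <- f_poly / (1 - f_poly)
l <- (1 - f_path) * eff / (f_path - (1 - f_path) * q)
cfg <- list(targeting_efficiency = eff,
            n_cells_selected = 1.5e6,
            loh_survivor_rate = l,
            background_survivor_rate = l * q,
            n_colonies_picked = 18,
            calibration_targets = list(nonloh_fraction_abrogating = f_path,
                                       nonloh_fraction_neutral = f_poly))
jsonlite::write_json(cfg, file.path(outdir, "sim_defaults.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

# --- variant truth/annotation table ----------------------------------------
v <- function(id, hum, mus, nt, cls, lab)
  data.frame(variant_id = id, human_aa_change = hum, mouse_aa_change = mus,
             nucleotide_change = nt, insight_class = cls, prior_label = lab,
             stringsAsFactors = FALSE)
variants <- rbind(
  # proof of principle: 5 known non-pathogenic (4 class-1 + L1087R) ...
  v("POLY-A", "POLY-A", NA, NA, "1", "non_pathogenic"),
  v("POLY-B", "POLY-B", NA, NA, "1", "non_pathogenic"),
  v("POLY-C", "POLY-C", NA, NA, "1", "non_pathogenic"),
  v("POLY-D", "POLY-D", NA, NA, "1", "non_pathogenic"),
  v("L1087R", "L1087R", "L1085R", NA, "3", "non_pathogenic"),
  # ... and 4 known pathogenic (3 class-5 + G1139S, class 3 but proven)
  v("V397E",  NA, "V397E",  NA, "5", "pathogenic"),
  v("L448P",  NA, "L448P",  NA, "5", "pathogenic"),
  v("R1332Q", NA, "R1332Q", NA, "5", "pathogenic"),
  v("G1139S", "G1139S", "G1137S", NA, "3", "pathogenic"),
  # 26 VUS: 8 detected ...
  v("R511G",  "R511G",  "R510G",  "c.1531A>G", "3",  "uncertain"),
  v("A587P",  "A587P",  "A586P",  "c.1759G>C", "4",  "pathogenic"),
  v("G686D",  "G686D",  "G683D",  "c.2057G>A", "4",  "pathogenic"),
  v("F706S",  "F706S",  "F703S",  "c.2117T>C", NA,   "uncertain"),
  v("L1063R", "L1063R", "L1060R", "c.3188T>G", "4",  "pathogenic"),
  v("E1193K", "E1193K", "E1191K", "c.3577G>A", "3",  "uncertain"),
  v("T1219D", "T1219D", "T1217D", "c.3655_3656delACinsGA", NA, "uncertain"),
  v("T1219I", "T1219I", "T1217I", "c.3656C>T", "3",  "uncertain"),
  # ... and 18 not detected (clinical cohort + literature/InSiGHT)
  v("A25S",        "A25S",   NA, NA, NA,  "uncertain"),
  v("E221D",       "E221D",  NA, NA, NA,  "uncertain"),
  v("G670R",       "G670R",  NA, NA, NA,  "uncertain"),
  v("R922Q",       "R922Q",  NA, NA, NA,  "uncertain"),
  v("c.3438+6T>C", NA,       NA, "c.3438+6T>C", NA, "uncertain"),
  v("R128L",  "R128L",  NA, NA, "3", "uncertain"),
  v("R468H",  "R468H",  NA, NA, "2", "non_pathogenic"),
  v("V509A",  "V509A",  NA, NA, "2", "non_pathogenic"),
  v("Y556F",  "Y556F",  NA, NA, "3", "uncertain"),
  v("P623A",  "P623A",  NA, NA, "2", "non_pathogenic"),
  v("S666P",  "S666P",  NA, NA, "3", "uncertain"),
  v("E983Q",  "E983Q",  NA, NA, "3", "uncertain"),
  v("R1095C", "R1095C", NA, NA, "3", "uncertain"),
  v("T1255M", "T1255M", NA, NA, "3", "uncertain"),
  v("R1304K", "R1304K", NA, NA, "2", "non_pathogenic"),
  v("S285I",  "S285I",  NA, NA, "3", "uncertain"),
  # G566R: screen-negative; a posteriori proven MMR-proficient (G565R line)
  v("G566R",  "G566R",  "G565R", NA, "3", "non_pathogenic"),
  v("T1142M", "T1142M", NA, NA, "3", "uncertain"))
stopifnot(nrow(variants) == 35, sum(variants$prior_label == "pathogenic") == 7,
          sum(variants$prior_label == "non_pathogenic") == 10)

write.table(variants, file.path(outdir, "variants.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "NA")

# --- colony panels ----------------------------------------------------------
# panel(variant, round, n_loh, n_bg, n_mut): always 18 picked colonies.
panel <- function(variant, round, n_loh, n_bg, n_mut) {
  stopifnot(n_loh + n_bg + n_mut == 18)
  cat_ <- c(rep("loh", n_loh), rep("wt", n_bg), rep("mut", n_mut))
  data.frame(variant_id = variant, round = round,
             colony_id = sprintf("%s_%s_c%02d", variant, substr(round, 1, 1),
                                 seq_along(cat_)),
             allele_pcr = ifelse(cat_ == "loh", "wt_lost", "both"),
             sequence_call = ifelse(cat_ == "loh", "nt",
                             ifelse(cat_ == "mut", "mut", "wt")),
             stringsAsFactors = FALSE)
}
p <- list(
  # proof-of-principle polymorphisms: ~6% non-LOH, none confirmed;
  # two of them needed a sense-orientation retry
  panel("POLY-A", "antisense", 17, 1, 0),
  panel("POLY-B", "antisense", 18, 0, 0),
  panel("POLY-B", "sense",     17, 1, 0),
  panel("POLY-C", "antisense", 17, 1, 0),
  panel("POLY-D", "antisense", 17, 1, 0),
  panel("L1087R", "antisense", 18, 0, 0),
  panel("L1087R", "sense",     17, 1, 0),
  # proof-of-principle pathogenic: ~40% non-LOH, all but one colony confirmed
  panel("V397E",  "antisense", 11, 1, 6),
  panel("L448P",  "antisense", 11, 0, 7),
  panel("R1332Q", "antisense", 11, 0, 7),
  panel("G1139S", "antisense", 11, 0, 7),
  # detected VUS; R511G 2/5 and F706S 2/4 non-LOH confirmed as printed
  panel("R511G",  "antisense", 13, 3, 2),
  panel("A587P",  "antisense", 11, 0, 7),
  panel("G686D",  "antisense", 11, 0, 7),
  panel("F706S",  "antisense", 14, 2, 2),
  panel("L1063R", "antisense", 11, 1, 6),
  panel("E1193K", "antisense", 11, 0, 7),
  panel("T1219D", "antisense", 10, 1, 7),
  panel("T1219I", "antisense", 12, 0, 6))
# 18 screen-negative VUS: mostly 17 LOH + 1 background; six retried in
# sense orientation after an all-LOH antisense round
retried <- c("A25S", "E221D", "S285I", "G566R", "T1142M", "c.3438+6T>C")
negatives <- c("A25S", "E221D", "G670R", "R922Q", "c.3438+6T>C", "R128L",
               "R468H", "V509A", "Y556F", "P623A", "S666P", "E983Q",
               "R1095C", "T1255M", "R1304K", "S285I", "G566R", "T1142M")
for (id in negatives) {
  if (id %in% retried) {
    p <- c(p, list(panel(id, "antisense", 18, 0, 0),
                   panel(id, "sense", 17, 1, 0)))
  } else {
    p <- c(p, list(panel(id, "antisense", 17, 1, 0)))
  }
}
colonies <- do.call(rbind, p)
write.table(colonies, file.path(outdir, "colonies.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "NA")

# --- fluctuation assay fixture ---------------------------------------------
# CTRL replicates sit near the MMR-proficient rate (p ~ 3.8e-7 at N = 1e7);
# V397E near the pathogenic average (~1.9e-4); UNIT is the analytic row
# G = e/0.6 (=> N*p = e exactly); ZERO exercises the below-detection path.
flr <- function(id, rep, G, N = 1e7)
  data.frame(variant_id = id, replicate = rep, n_expanded = N,
             cells_per_plate = 1e5, n_plates = 100, geneticin_total = G,
             stringsAsFactors = FALSE)
fluct <- rbind(
  flr("CTRL", 1:4, c(7, 9, 8, 10)),
  flr("V397E", 1:4, c(23000, 25500, 21800, 26400)),
  flr("UNIT", 1, exp(1) / 0.6),
  flr("ZERO", 1:4, c(0, 0, 0, 0)))
write.table(fluct, file.path(outdir, "fluctuation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "NA")

# --- MNNG assay fixture -----------------------------------------------------
mnr <- function(id, dose, rep, colonies)
  data.frame(variant_id = id, dose_uM = dose, replicate = rep,
             cells_plated = 1.5e6, resistant_colonies = colonies,
             stringsAsFactors = FALSE)
mnng <- rbind(mnr("CTRL", 0, 1:2, c(1, 2)),  mnr("CTRL", 4, 1:2, c(2, 3)),
              mnr("V397E", 0, 1:2, c(28, 35)), mnr("V397E", 4, 1:2, c(310, 285)))
write.table(mnng, file.path(outdir, "mnng.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "NA")

# --- synthetic toy CDS for oligo design ------------------------------------
set.seed(42)
codons <- apply(matrix(sample(c("A", "C", "G", "T"), 3 * 60, replace = TRUE),
                       ncol = 3), 1, paste, collapse = "")
cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
writeLines(c(">synthetic_cds_60codons synthetic toy coding sequence", cds),
           file.path(outdir, "cds_synthetic.fa"))

cat("fixtures written to", outdir, "\n")
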