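# Table readers and writers. TSV is the canonical dialect: header
# mandatory, tab separated, '.' decimal mark, UTF-8. Every writer's output
# round-trips through its reader.

.read_tsv <- function(path, required) {
  if (!file.exists(path)) .stop("input file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), comment.char = "#",
                   fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    .stop("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  df
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read the variant annotation / truth table
#'
#' Expected columns: `variant_id`, `human_aa_change`, `mouse_aa_change`,
#' `nucleotide_change`, `insight_class` (1-5 or NA) and `prior_label`
#' (`pathogenic` / `non_pathogenic` / `uncertain`; the a priori or a
#' posteriori truth used only for performance evaluation).
#'
#' @param path TSV file.
#' @return data frame with validated enums and unique `variant_id`.
#' @export
read_variants <- function(path) {
  df <- .read_tsv(path, c("variant_id", "human_aa_change", "mouse_aa_change",
                          "nucleotide_change", "insight_class", "prior_label"))
  if (anyDuplicated(df$variant_id))
    .stop("%s: duplicate variant_id: %s", path,
          df$variant_id[duplicated(df$variant_id)][1])
  df$insight_class <- as.character(df$insight_class)
  bad <- !is.na(df$insight_class) & !df$insight_class %in% .insight_classes
  if (any(bad))
    .stop("%s: invalid insight_class for %s", path,
          paste(df$variant_id[bad], collapse = ", "))
  bad <- !df$prior_label %in% .prior_labels
  if (any(bad))
    .stop("%s: invalid prior_label for %s", path,
          paste(df$variant_id[bad], collapse = ", "))
  df
}

#' Read the per-colony genotyping table
#'
#' Expected columns: `variant_id`, `round` (`antisense`/`sense`),
#' `colony_id`, `allele_pcr` (`both` or `wt_lost`) and `sequence_call`
#' (`mut`, `wt` or `nt`). The compact enum codes are expanded to the
#' canonical values used throughout the package.
#'
#' @param path TSV file.
#' @return data frame with columns `variant_id`, `round`, `colony_id`,
#'   `allele_pcr`, `sequence_call` (canonical values).
#' @export
read_colonies <- function(path) {
  df <- .read_tsv(path, c("variant_id", "round", "colony_id", "allele_pcr",
                          "sequence_call"))
  pcr_map <- c(both = "both_alleles_present", wt_lost = "wt_allele_lost",
               both_alleles_present = "both_alleles_present",
               wt_allele_lost = "wt_allele_lost")
  seq_map <- c(mut = "planned_mutation", wt = "no_mutation", nt = "not_tested",
               planned_mutation = "planned_mutation",
               no_mutation = "no_mutation", not_tested = "not_tested")
  .map_enum <- function(x, map, col) {
    bad <- !x %in% names(map)
    if (any(bad))
      .stop("%s: invalid %s value '%s' (row %d)", path, col,
            x[bad][1], which(bad)[1])
    unname(map[x])
  }
  df$allele_pcr <- .map_enum(df$allele_pcr, pcr_map, "allele_pcr")
  df$sequence_call <- .map_enum(df$sequence_call, seq_map, "sequence_call")
  bad <- !df$round %in% .round_levels
  if (any(bad))
    .stop("%s: invalid round value '%s' (row %d)", path,
          df$round[bad][1], which(bad)[1])
  df
}

#' Write a colony table using the compact TSV enum codes
#' @param colonies canonical colony data frame.
#' @param path output TSV.
#' @export
write_colonies <- function(colonies, path) {
  out <- colonies[, c("variant_id", "round", "colony_id", "allele_pcr",
                      "sequence_call")]
  out$allele_pcr <- c(both_alleles_present = "both",
                      wt_allele_lost = "wt_lost")[out$allele_pcr]
  out$sequence_call <- c(planned_mutation = "mut", no_mutation = "wt",
                         not_tested = "nt")[out$sequence_call]
  .write_tsv(out, path)
}

#' Read fluctuation-assay count tables
#'
#' Expected columns: `variant_id`, `replicate`, `n_expanded`,
#' `cells_per_plate`, `n_plates`, `geneticin_total` (one row per replicate
#' culture; `geneticin_total` is the colony total of that replicate,
#' summed over its plates).
#'
#' @param path TSV file.
#' @return named list of [fluctuation_experiment()] objects, one per
#'   variant.
#' @export
read_fluctuation <- function(path) {
  df <- .read_tsv(path, c("variant_id", "replicate", "n_expanded",
                          "cells_per_plate", "n_plates", "geneticin_total"))
  if (any(!is.finite(df$geneticin_total)) || any(df$geneticin_total < 0))
    .stop("%s: geneticin_total must be non-negative", path)
  lapply(split(df, df$variant_id), function(d) {
    if (length(unique(d$n_expanded)) != 1)
      .stop("%s: variant %s has inconsistent n_expanded across replicates",
            path, d$variant_id[1])
    fluctuation_experiment(d$variant_id[1], d$geneticin_total,
                           n_expanded = d$n_expanded[1],
                           cells_per_plate = d$cells_per_plate[1],
                           n_plates = d$n_plates[1])
  })
}

#' Read MNNG mutagenesis count tables
#'
#' Expected columns: `variant_id`, `dose_uM`, `replicate`, `cells_plated`,
#' `resistant_colonies`.
#'
#' @param path TSV file.
#' @return list of [mutagenesis_experiment()] objects, one per
#'   (variant, dose) arm, named `"<variant_id>@<dose>"`.
#' @export
read_mnng <- function(path) {
  df <- .read_tsv(path, c("variant_id", "dose_uM", "replicate",
                          "cells_plated", "resistant_colonies"))
  key <- paste0(df$variant_id, "@", df$dose_uM)
  lapply(split(df, key), function(d)
    mutagenesis_experiment(d$variant_id[1], d$dose_uM[1],
                           d$resistant_colonies,
                           cells_plated = d$cells_plated[1]))
}

#' Write per-variant screen calls
#' @param calls data frame from [classify_and_call()].
#' @param path output TSV.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  for (f in c("f_loh", "f_background", "f_confirmed"))
    if (f %in% names(out)) out[[f]] <- round(out[[f]], 4)
  .write_tsv(out, path)
}

#' Serialize a performance report to JSON
#'
#' Percent fields are rounded to one decimal for display.
#'
#' @param report a `performance_report`.
#' @param path output JSON file.
#' @export
write_performance <- function(report, path) {
  x <- unclass(report)
  pct <- grep("sensitivity|specificity", names(x))
  x[pct] <- lapply(x[pct], round, digits = 1)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a slippage-rate table
#'
#' One row per variant with per-replicate estimates (scientific notation,
#' 4 significant digits), mean, sd, fold change versus a named reference
#' line, and the star annotation of the one-tailed Welch comparison
#' against that reference.
#'
#' @param estimates list of `slippage_rate_estimate` objects.
#' @param path output TSV.
#' @param reference_id optional variant_id of the MMR-proficient reference
#'   line; enables `fold_vs_reference` (display-rounded) and `stars`.
#' @return the data frame written, invisibly.
#' @export
write_rates <- function(estimates, path, reference_id = NULL) {
  fmt <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "e", digits = 3))
  ref <- NULL
  if (!is.null(reference_id)) {
    ref <- estimates[[reference_id]]
    if (is.null(ref))
      .stop("reference id '%s' not present in the rates input", reference_id)
  }
  rows <- lapply(estimates, function(e) {
    row <- data.frame(
      variant_id = e$variant_id,
      n_replicates = length(e$p_per_replicate),
      p_replicates = paste(fmt(e$p_per_replicate), collapse = ","),
      p_mean = fmt(e$p_mean), p_sd = fmt(e$p_sd),
      below_detection = e$below_detection,
      detection_limit = fmt(e$detection_limit),
      stringsAsFactors = FALSE)
    if (!is.null(ref)) {
      row$fold_vs_reference <- if (is.na(e$p_mean)) NA_real_ else
        fold_change(e$p_mean, ref$p_mean, display = TRUE)
      row$stars <- if (e$variant_id == ref$variant_id ||
                       sum(is.finite(e$p_per_replicate)) < 2) "NA" else
        significance_stars(
          welch_one_tailed(e$p_per_replicate[is.finite(e$p_per_replicate)],
                           ref$p_per_replicate[is.finite(ref$p_per_replicate)]
                           )$p_one_tailed)
    }
    row
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  .write_tsv(out, path)
  invisible(out)
}

#' Write MNNG mutant-frequency table
#'
#' @param freqs list of results from [mutation_frequency()].
#' @param path output TSV.
#' @return the data frame written, invisibly.
#' @export
write_mnng_freq <- function(freqs, path) {
  fmt <- function(x) formatC(x, format = "e", digits = 3)
  out <- do.call(rbind, c(lapply(freqs, function(f)
    data.frame(variant_id = f$variant_id, dose_uM = f$dose_uM,
               freq_replicates = paste(fmt(f$freq_per_replicate), collapse = ","),
               freq_mean = fmt(f$freq_mean), stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
  .write_tsv(out, path)
  invisible(out)
}
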