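# Pipeline orchestration: thin drivers gluing readers, the analysis
# operations and the writers, with stage-boundary logging so silent data
# loss is impossible.

#' Pipeline configuration
#'
#' @param variants,colonies,fluctuation,mnng,reference_fasta input paths
#'   (only those needed by the stages being run are required).
#' @param reference_id variant_id of the MMR-proficient reference line for
#'   fold changes and Welch comparisons.
#' @param log_base logarithm base for the slippage-rate relation.
#' @param rng_seed integer seed for simulation stages.
#' @param outdir output directory (created if missing).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(variants = NULL, colonies = NULL,
                            fluctuation = NULL, mnng = NULL,
                            reference_fasta = NULL, reference_id = NULL,
                            log_base = "ln", rng_seed = 1L,
                            outdir = ".") {
  structure(list(variants = variants, colonies = colonies,
                 fluctuation = fluctuation, mnng = mnng,
                 reference_fasta = reference_fasta,
                 reference_id = reference_id, log_base = log_base,
                 rng_seed = as.integer(rng_seed), outdir = outdir),
            class = "pipeline_config")
}

.ensure_outdir <- function(config) {
  if (!dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)
  config$outdir
}

.log <- function(fmt, ...) message(sprintf(paste0("[mmrscreen] ", fmt), ...))

#' Run colony classification and variant calling
#'
#' Reads the variant and colony tables, classifies every picked colony,
#' applies the two-colony call rule per variant and writes `calls.tsv`.
#'
#' @param config a [pipeline_config()] with `variants` and `colonies` set.
#' @return the calls data frame, invisibly.
#' @export
run_classify <- function(config) {
  variants <- read_variants(config$variants)
  colonies <- read_colonies(config$colonies)
  .log("read %d variants, %d colony rows", nrow(variants), nrow(colonies))
  calls <- classify_and_call(colonies, variant_ids = variants$variant_id)
  .log("calls: %s", paste(sprintf("%s=%d", names(table(calls$call)),
                                  table(calls$call)), collapse = ", "))
  out <- file.path(.ensure_outdir(config), "calls.tsv")
  write_calls(calls, out)
  .log("wrote %s", out)
  invisible(calls)
}

#' Evaluate screen performance and write performance.json
#'
#' @param config a [pipeline_config()] with `variants` and `colonies` set
#'   (calls are recomputed via [run_classify()]'s logic).
#' @return the `performance_report`, invisibly.
#' @export
run_evaluate <- function(config) {
  variants <- read_variants(config$variants)
  if (all(variants$prior_label == "uncertain"))
    .stop("no labelled variants: performance evaluation impossible")
  colonies <- read_colonies(config$colonies)
  calls <- classify_and_call(colonies, variant_ids = variants$variant_id)
  report <- screen_performance(calls, variants)
  .log("sensitivity %d/%d, specificity %d FP/%d; %d uncertain excluded",
       report$n_detected, report$n_pathogenic_truth,
       report$n_false_positive, report$n_nonpathogenic_truth,
       length(report$excluded_uncertain))
  out <- file.path(.ensure_outdir(config), "performance.json")
  write_performance(report, out)
  .log("wrote %s", out)
  invisible(report)
}

#' Estimate slippage rates for every fluctuation experiment
#'
#' @param config a [pipeline_config()] with `fluctuation` set; if
#'   `reference_id` is set, fold changes and Welch stars versus that line
#'   are included.
#' @return the rates data frame written to `rates.tsv`, invisibly.
#' @export
run_rates <- function(config) {
  exps <- read_fluctuation(config$fluctuation)
  .log("estimating slippage rates for %d variants", length(exps))
  estimates <- lapply(exps, summarize_fluctuation, log_base = config$log_base)
  out <- file.path(.ensure_outdir(config), "rates.tsv")
  res <- write_rates(estimates, out, reference_id = config$reference_id)
  .log("wrote %s", out)
  invisible(res)
}

#' Compute MNNG-induced mutant frequencies
#'
#' @param config a [pipeline_config()] with `mnng` set.
#' @return the frequency table written to `mnng_freq.tsv`, invisibly.
#' @export
run_mnng <- function(config) {
  exps <- read_mnng(config$mnng)
  .log("computing mutant frequencies for %d assay arms", length(exps))
  freqs <- lapply(exps, mutation_frequency)
  out <- file.path(.ensure_outdir(config), "mnng_freq.tsv")
  res <- write_mnng_freq(freqs, out)
  .log("wrote %s", out)
  invisible(res)
}

#' Simulate a full screen dataset
#'
#' Generates a synthetic study (screen colonies plus variant truth table)
#' in the exact TSV dialects the analysis stages consume, plus a
#' `truth.json` sidecar, deterministically under the configured seed.
#'
#' @param config a [pipeline_config()]; `rng_seed` drives all draws.
#' @param n_abrogating,n_neutral simulated variant counts (defaults 4 and
#'   5, mirroring the proof-of-principle design).
#' @return invisible list with the file paths written.
#' @export
run_simulate <- function(config, n_abrogating = 4L, n_neutral = 5L) {
  outdir <- .ensure_outdir(config)
  truth <- data.frame(
    variant_id = c(sprintf("SIM_PATH_%02d", seq_len(n_abrogating)),
                   sprintf("SIM_POLY_%02d", seq_len(n_neutral))),
    abrogates_mmr = rep(c(TRUE, FALSE), c(n_abrogating, n_neutral)),
    stringsAsFactors = FALSE)
  params <- screen_sim_params(rng_seed = config$rng_seed)
  colonies <- simulate_screen(truth, params)
  .log("simulated %d colonies for %d variants", nrow(colonies), nrow(truth))

  variants <- data.frame(
    variant_id = truth$variant_id,
    human_aa_change = NA_character_, mouse_aa_change = NA_character_,
    nucleotide_change = NA_character_, insight_class = NA_character_,
    prior_label = ifelse(truth$abrogates_mmr, "pathogenic", "non_pathogenic"),
    stringsAsFactors = FALSE)

  paths <- list(colonies = file.path(outdir, "colonies.tsv"),
                variants = file.path(outdir, "variants.tsv"),
                truth = file.path(outdir, "truth.json"))
  write_colonies(colonies, paths$colonies)
  .write_tsv(variants, paths$variants)
  jsonlite::write_json(truth, paths$truth, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  .log("wrote %s, %s, %s", paths$colonies, paths$variants, paths$truth)
  invisible(paths)
}

#' Render a Markdown summary report
#'
#' Emits a single Markdown file with the per-variant colony fractions and
#' calls, slippage rates with star annotations (when a fluctuation input
#' is configured), and the performance report.
#'
#' @param config a [pipeline_config()].
#' @return path of the report, invisibly.
#' @export
run_report <- function(config) {
  outdir <- .ensure_outdir(config)
  lines <- c("# Screen summary", "")
  md_table <- function(df) {
    esc <- function(x) gsub("\\|", "\\\\|", as.character(x))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(esc(r), collapse = " | "), " |"))
    c(header, sep, rows, "")
  }
  if (!is.null(config$colonies) && !is.null(config$variants)) {
    calls <- run_classify(config)
    lines <- c(lines, "## Variant calls and colony fractions", "",
               md_table(calls))
    variants <- read_variants(config$variants)
    if (any(variants$prior_label != "uncertain")) {
      rep_ <- run_evaluate(config)
      perf <- data.frame(
        metric = c("sensitivity", "specificity"),
        detected_or_clean = c(sprintf("%d/%d", rep_$n_detected, rep_$n_pathogenic_truth),
                              sprintf("%d/%d", rep_$n_nonpathogenic_truth - rep_$n_false_positive,
                                      rep_$n_nonpathogenic_truth)),
        point_pct = round(c(rep_$sensitivity_point, rep_$specificity_point), 1),
        zero_failure_bound_pct = round(c(rep_$sensitivity_zero_failure_bound,
                                         rep_$specificity_zero_failure_bound), 1))
      lines <- c(lines, "## Screen performance", "", md_table(perf))
    }
  }
  if (!is.null(config$fluctuation))
    lines <- c(lines, "## Slippage rates", "", md_table(run_rates(config)))
  if (!is.null(config$mnng))
    lines <- c(lines, "## MNNG-induced mutant frequencies", "",
               md_table(run_mnng(config)))
  out <- file.path(outdir, "report.md")
  writeLines(lines, out)
  .log("wrote %s", out)
  invisible(out)
}
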