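# Colony genotype classification and per-variant pathogenicity calls.
#
# The screen introduces a candidate MSH6 variant into Msh6+/- mouse ES cells
# by oligo targeting, selects MMR-deficient survivors with 6-thioguanine,
# and genotypes the picked colonies: an allele-specific PCR separates
# loss-of-heterozygosity (LOH) survivors from colonies that kept both Msh6
# alleles, and the retained colonies are sequenced for the planned mutation.

#' Classify a genotyped 6TG-resistant colony
#'
#' Maps the two per-colony genotyping read-outs onto the three survivor
#' categories of the screen:
#' \itemize{
#'   \item `loh` — the allele-specific PCR shows the wild-type *Msh6* allele
#'     was lost (loss of heterozygosity); the colony is MMR deficient for a
#'     reason unrelated to the tested variant and is excluded before
#'     sequencing.
#'   \item `confirmed_mutant` — both alleles retained and sequencing found
#'     the planned mutation.
#'   \item `background` — both alleles retained but no mutation found; the
#'     cell survived selection for unknown reasons.
#' }
#'
#' A colony that retained both alleles but was never sequenced is a hard
#' error: the screen's workflow sequences every retained colony, so a
#' missing call indicates data loss, not background.
#'
#' @param allele_pcr character vector, `"both_alleles_present"` or
#'   `"wt_allele_lost"`.
#' @param sequence_call character vector, `"planned_mutation"`,
#'   `"no_mutation"` or `"not_tested"`.
#' @return character vector with values `"loh"`, `"background"` or
#'   `"confirmed_mutant"`.
#' @examples
#' classify_colony("wt_allele_lost", "not_tested")
#' classify_colony("both_alleles_present", "planned_mutation")
#' @export
classify_colony <- function(allele_pcr, sequence_call) {
  if (length(allele_pcr) != length(sequence_call))
    .stop("allele_pcr and sequence_call must have equal length")
  bad <- !allele_pcr %in% .allele_pcr_levels
  if (any(bad))
    .stop("unknown allele_pcr value(s): %s",
          paste(unique(allele_pcr[bad]), collapse = ", "))
  bad <- !sequence_call %in% .sequence_call_levels
  if (any(bad))
    .stop("unknown sequence_call value(s): %s",
          paste(unique(sequence_call[bad]), collapse = ", "))

  loh <- allele_pcr == "wt_allele_lost"
  if (any(loh & sequence_call != "not_tested"))
    .stop("LOH colonies are excluded before sequencing; found wt_allele_lost with a sequence call")
  if (any(!loh & sequence_call == "not_tested"))
    .stop("colony retained both alleles but was not sequenced (sequencing missing for a non-LOH colony)")

  ifelse(loh, "loh",
         ifelse(sequence_call == "planned_mutation", "confirmed_mutant", "background"))
}

#' Fractions of picked colonies per survivor category
#'
#' @param colonies data frame with columns `allele_pcr` and `sequence_call`,
#'   one row per picked colony of a single panel.
#' @return list with components `f_loh`, `f_background`, `f_confirmed`
#'   (summing to 1) and `n_picked`.
#' @export
colony_fractions <- function(colonies) {
  n <- nrow(colonies)
  if (is.null(n) || n == 0L)
    .stop("cannot compute colony fractions of an empty panel",
          class = "mmrscreen_empty_panel")
  cat_ <- classify_colony(colonies$allele_pcr, colonies$sequence_call)
  counts <- table(factor(cat_, levels = .colony_categories))
  list(f_loh        = unname(counts[["loh"]]) / n,
       f_background = unname(counts[["background"]]) / n,
       f_confirmed  = unname(counts[["confirmed_mutant"]]) / n,
       n_picked     = n)
}

#' Merge screening rounds for one variant
#'
#' Each variant is first screened with an antisense-oriented targeting
#' oligonucleotide; if no mutation-carrying colonies appear the screen is
#' repeated with the sense orientation. Counts are summed over the rounds
#' actually run.
#'
#' @param colonies data frame with columns `variant_id`, `round`,
#'   `allele_pcr`, `sequence_call`; all rows must belong to one variant, and
#'   at most one panel (set of rows) per round is allowed.
#' @return list with `variant_id`, `n_confirmed`, `n_background`, `n_loh`,
#'   `n_total` and `rounds_used`.
#' @export
aggregate_rounds <- function(colonies) {
  ids <- unique(colonies$variant_id)
  if (length(ids) != 1L)
    .stop("aggregate_rounds expects colonies of a single variant, got: %s",
          paste(ids, collapse = ", "))
  rounds <- unique(colonies$round)
  if (any(!rounds %in% .round_levels))
    .stop("unknown round value(s): %s",
          paste(setdiff(rounds, .round_levels), collapse = ", "))
  if ("sense" %in% rounds && !"antisense" %in% rounds)
    .stop("variant %s has a sense panel without the antisense round (sense is a retry)", ids)

  cat_ <- classify_colony(colonies$allele_pcr, colonies$sequence_call)
  counts <- table(factor(cat_, levels = .colony_categories))
  list(variant_id   = ids,
       n_confirmed  = unname(counts[["confirmed_mutant"]]),
       n_background = unname(counts[["background"]]),
       n_loh        = unname(counts[["loh"]]),
       n_total      = nrow(colonies),
       rounds_used  = intersect(.round_levels, rounds))
}

#' Call a variant from merged colony counts
#'
#' The pathogenicity convention of the screen: given the low (~1e-3)
#' per-cell efficiency of oligo-directed base substitution, recovering the
#' planned mutation in two independent 6TG-resistant colonies is considered
#' indicative of MMR abrogation. Zero confirmed colonies is a clean
#' negative; exactly one is reported as `inconclusive` (the convention
#' covers >= 2; a singleton is surfaced distinctly rather than forced into
#' either class).
#'
#' @param counts list as returned by [aggregate_rounds()].
#' @return object of class `screen_call`: list with `variant_id`, `call`
#'   (`"mmr_abrogating"`, `"not_detected"` or `"inconclusive"`),
#'   `n_confirmed`, `n_loh`, `n_background`, `n_total`, `rounds_used`.
#' @export
call_variant <- function(counts) {
  n <- c(counts$n_confirmed, counts$n_loh, counts$n_background)
  if (any(!is.finite(n)) || any(n < 0))
    .stop("colony counts must be non-negative")
  call <- if (counts$n_confirmed >= 2L) "mmr_abrogating"
          else if (counts$n_confirmed == 0L) "not_detected"
          else "inconclusive"
  structure(list(variant_id   = counts$variant_id,
                 call         = call,
                 n_confirmed  = counts$n_confirmed,
                 n_loh        = counts$n_loh,
                 n_background = counts$n_background,
                 n_total      = counts$n_total,
                 rounds_used  = counts$rounds_used),
            class = "screen_call")
}

#' @export
print.screen_call <- function(x, ...) {
  cat(sprintf("<screen_call> %s: %s (%d confirmed / %d background / %d LOH of %d; rounds: %s)\n",
              x$variant_id, x$call, x$n_confirmed, x$n_background, x$n_loh,
              x$n_total, paste(x$rounds_used, collapse = "+")))
  invisible(x)
}

#' Classify all colonies and call every variant
#'
#' Convenience driver: splits a colony table by variant, enforces the
#' one-panel-per-round invariant, aggregates rounds and applies
#' [call_variant()].
#'
#' @param colonies colony table (see [read_colonies()]); a `colony_id`
#'   column, if present, must be unique within each (variant, round) panel.
#' @param variant_ids optional character vector of variants that must appear
#'   in the output; variants with no colonies are reported `not_detected`
#'   with zero counts (and a warning).
#' @return data frame, one row per variant: `variant_id`, `call`,
#'   `n_confirmed`, `n_loh`, `n_background`, `n_total`, `rounds_used`
#'   (collapsed with `+`), `f_loh`, `f_background`, `f_confirmed`.
#' @export
classify_and_call <- function(colonies, variant_ids = NULL) {
  if (!is.null(colonies$colony_id)) {
    key <- paste(colonies$variant_id, colonies$round, colonies$colony_id)
    if (anyDuplicated(key))
      .stop("duplicate colony row(s): %s", key[duplicated(key)][1])
  }
  empty <- data.frame(variant_id = character(), call = character(),
                      n_confirmed = integer(), n_loh = integer(),
                      n_background = integer(), n_total = integer(),
                      rounds_used = character(), stringsAsFactors = FALSE)
  calls <- lapply(split(colonies, colonies$variant_id), function(df) {
    agg <- aggregate_rounds(df)
    sc <- call_variant(agg)
    data.frame(variant_id = sc$variant_id, call = sc$call,
               n_confirmed = sc$n_confirmed, n_loh = sc$n_loh,
               n_background = sc$n_background, n_total = sc$n_total,
               rounds_used = paste(sc$rounds_used, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(calls) == 0) empty else
    do.call(rbind, c(calls, list(make.row.names = FALSE)))
  if (!is.null(variant_ids)) {
    missing <- setdiff(variant_ids, out$variant_id)
    if (length(missing) > 0) {
      warning(sprintf("no colonies for variant(s) %s; reported as not_detected",
                      paste(missing, collapse = ", ")))
      out <- rbind(out, data.frame(variant_id = missing, call = "not_detected",
                                   n_confirmed = 0L, n_loh = 0L,
                                   n_background = 0L, n_total = 0L,
                                   rounds_used = "", stringsAsFactors = FALSE))
    }
    out <- out[match(variant_ids, out$variant_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out$f_loh <- ifelse(out$n_total > 0, out$n_loh / out$n_total, NA_real_)
  out$f_background <- ifelse(out$n_total > 0, out$n_background / out$n_total, NA_real_)
  out$f_confirmed <- ifelse(out$n_total > 0, out$n_confirmed / out$n_total, NA_real_)
  out
}
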