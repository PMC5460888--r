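# Slippage-rate estimation from (G)10-neo reporter fluctuation assays.
#
# A culture is expanded to N cells and plated under Geneticin; frameshift
# slippage at the (G)10 repeat restores the neo reading frame, so the total
# count of resistant colonies G reflects the per-division slippage rate p
# through the median-style fluctuation relation
#
#     0.6 * G = N * p * log(N * p)
#
# which is solved for the unique p with N*p > 1. The relation is only
# defined for G > 0; a zero-count replicate is reported as below the
# detection limit (the estimate at G = 1), never imputed as rate zero.

#' Solve the fluctuation relation for the slippage rate
#'
#' Finds the unique `p` with `N*p > 1` satisfying
#' `0.6 * geneticin_total = N * p * log(N * p)` by bisection on
#' `x = N*p` (the left side is strictly increasing there since its
#' derivative `log(x) + 1 > 0` for `x > 1`), to relative tolerance 1e-12.
#'
#' @param geneticin_total total Geneticin-resistant colony count of one
#'   replicate (must be > 0; a zero count raises a condition of class
#'   `mmrscreen_below_detection` carrying the detection limit, the estimate
#'   at a count of 1).
#' @param n_expanded number of cells the culture was expanded to (N).
#' @param log_base `"ln"` (default) or `"log10"`. The published relation
#'   prints an unqualified log; the natural log is the default because the
#'   `x log x` form and its 0.6 constant stem from Luria-Delbrueck-style
#'   mutation-rate estimation, but the base is exposed as a sensitivity knob.
#' @return slippage rate `p` (mutations per cell division), a scalar.
#' @examples
#' # N*p = e makes log(N*p) = 1, so G = e/0.6 gives p = e/N analytically:
#' estimate_slippage_rate(exp(1) / 0.6, 1e7)
#' @export
estimate_slippage_rate <- function(geneticin_total, n_expanded,
                                   log_base = c("ln", "log10")) {
  log_base <- match.arg(log_base)
  if (length(geneticin_total) != 1L || length(n_expanded) != 1L)
    .stop("estimate_slippage_rate is scalar; use summarize_fluctuation for replicates")
  if (!is.finite(n_expanded) || n_expanded < 2)
    .stop("n_expanded must be >= 2")
  if (!is.finite(geneticin_total) || geneticin_total < 0)
    .stop("geneticin_total must be a non-negative count")
  if (geneticin_total == 0) {
    lim <- estimate_slippage_rate(1, n_expanded, log_base)
    stop(errorCondition(
      "no Geneticin-resistant colonies: slippage rate below detection limit",
      detection_limit = lim,
      class = c("mmrscreen_below_detection", "error", "condition")))
  }
  logf <- if (log_base == "ln") log else log10
  target <- 0.6 * geneticin_total
  f <- function(x) x * logf(x) - target

  lo <- 1 + 1e-12
  hi <- 2
  while (f(hi) < 0) hi <- hi * 2      # f is increasing; bracket the root
  while ((hi - lo) > 1e-12 * hi) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / n_expanded
}

#' Summarize a replicated fluctuation experiment
#'
#' Applies [estimate_slippage_rate()] to each replicate's colony total and
#' summarizes by mean and standard deviation over the finite estimates,
#' matching the quadruplicate design of the assay. Zero-count replicates
#' set `below_detection` and contribute only a detection limit.
#'
#' @param exp a `fluctuation_experiment` (see [fluctuation_experiment()]).
#' @param log_base passed to [estimate_slippage_rate()].
#' @return object of class `slippage_rate_estimate`: list with
#'   `variant_id`, `p_per_replicate` (NA where below detection), `p_mean`,
#'   `p_sd`, `below_detection`, `detection_limit`.
#' @export
summarize_fluctuation <- function(exp, log_base = c("ln", "log10")) {
  log_base <- match.arg(log_base)
  reps <- exp$replicates
  p <- rep(NA_real_, length(reps))
  limit <- NA_real_
  for (i in seq_along(reps)) {
    p[i] <- tryCatch(estimate_slippage_rate(reps[i], exp$n_expanded, log_base),
                     mmrscreen_below_detection = function(c) {
                       limit <<- c$detection_limit
                       NA_real_
                     })
  }
  finite <- p[is.finite(p)]
  structure(list(
    variant_id = exp$variant_id,
    p_per_replicate = p,
    p_mean = if (length(finite) > 0) mean(finite) else NA_real_,
    p_sd = if (length(finite) > 1) sd(finite) else if (length(finite) == 1) 0 else NA_real_,
    below_detection = anyNA(p),
    detection_limit = limit
  ), class = "slippage_rate_estimate")
}

#' @export
print.slippage_rate_estimate <- function(x, ...) {
  cat(sprintf("<slippage_rate_estimate> %s: p = %s +/- %s (%d replicates%s)\n",
              x$variant_id, format(x$p_mean, digits = 4),
              format(x$p_sd, digits = 4), length(x$p_per_replicate),
              if (x$below_detection)
                sprintf("; below detection, limit %s", format(x$detection_limit, digits = 4))
              else ""))
  invisible(x)
}

#' Constructor for a fluctuation experiment
#'
#' @param variant_id cell-line / variant identifier.
#' @param replicates vector of Geneticin-resistant colony totals, one per
#'   independently expanded replicate culture.
#' @param n_expanded cells per replicate at plating (N; default 1e7).
#' @param cells_per_plate,n_plates plating geometry (recorded, not used by
#'   the estimator, which works from the replicate total).
#' @return object of class `fluctuation_experiment`.
#' @export
fluctuation_experiment <- function(variant_id, replicates, n_expanded = 1e7,
                                   cells_per_plate = 1e5, n_plates = NA_integer_) {
  if (length(replicates) == 0) .stop("replicates must be non-empty")
  if (any(!is.finite(replicates)) || any(replicates < 0))
    .stop("replicate colony counts must be non-negative")
  if (!is.na(n_plates) && n_expanded < cells_per_plate * n_plates)
    .stop("cannot plate more cells than the culture was expanded to")
  structure(list(variant_id = variant_id, replicates = as.numeric(replicates),
                 n_expanded = n_expanded, cells_per_plate = cells_per_plate,
                 n_plates = n_plates),
            class = "fluctuation_experiment")
}

#' Fold change of a slippage rate over a reference rate
#'
#' @param p_variant,p_reference rates; `p_reference` must be > 0.
#' @param display if `TRUE`, round to the nearest 10 when the ratio is
#'   >= 100 (the convention used to report, e.g., 139.5x as "140-fold");
#'   raw ratios are returned otherwise.
#' @return dimensionless fold change.
#' @export
fold_change <- function(p_variant, p_reference, display = FALSE) {
  if (any(!is.finite(p_reference)) || any(p_reference <= 0))
    .stop("reference rate must be positive")
  fc <- p_variant / p_reference
  if (display) fc <- ifelse(fc >= 100, round(fc / 10) * 10, fc)
  fc
}

#' Constructor for an MNNG mutagenesis experiment arm
#'
#' One arm (a single MNNG dose) of the methylation-damage mutagenesis
#' assay: cells are exposed to 0 or 4 uM MNNG, and Hprt-mutant cells are
#' counted as colonies surviving long-term high-dose 6TG.
#'
#' @param variant_id cell-line identifier.
#' @param dose_uM MNNG dose in micromolar (design doses 0 and 4).
#' @param resistant_colonies vector of resistant-colony counts, one per
#'   replicate.
#' @param cells_plated cells transferred to selection (default 1.5e6).
#' @return object of class `mutagenesis_experiment`.
#' @export
mutagenesis_experiment <- function(variant_id, dose_uM, resistant_colonies,
                                   cells_plated = 1.5e6) {
  if (any(resistant_colonies < 0)) .stop("colony counts must be non-negative")
  if (!dose_uM %in% c(0, 4))
    warning("dose outside the 0/4 uM design: ", dose_uM)
  structure(list(variant_id = variant_id, dose_uM = dose_uM,
                 resistant_colonies = as.numeric(resistant_colonies),
                 cells_plated = cells_plated),
            class = "mutagenesis_experiment")
}

#' MNNG-induced mutant frequency per plated cell
#'
#' @param exp a `mutagenesis_experiment`.
#' @return list with `variant_id`, `dose_uM`, `freq_per_replicate`
#'   (resistant colonies / cells plated) and `freq_mean`.
#' @export
mutation_frequency <- function(exp) {
  if (exp$cells_plated <= 0) .stop("cells_plated must be positive")
  f <- exp$resistant_colonies / exp$cells_plated
  list(variant_id = exp$variant_id, dose_uM = exp$dose_uM,
       freq_per_replicate = f, freq_mean = mean(f))
}
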