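# Screen performance against prior truth labels.
#
# Variants with an a priori / a posteriori truth label (pathogenic or
# non_pathogenic) form the evaluation set; class-3/uncertain variants are
# excluded. Because the labelled sets are small and the screen made no
# errors on them, performance is reported as a zero-failure lower bound
# (n-1)/n rather than a point estimate alone: with n labelled cases all
# handled correctly, the error rate is "< 1/n".

#' Evaluate screen calls against truth labels
#'
#' Sensitivity counts a truth-pathogenic variant as detected iff its call
#' is `mmr_abrogating`; `inconclusive` counts as not detected (conservative
#' toward the screen). Specificity counts a truth-non-pathogenic variant as
#' a false positive iff it was called `mmr_abrogating`.
#'
#' When all n positives are detected (resp. all n negatives clean), the
#' reported bound is `100 * (n - 1) / n`; when failures exist the bound
#' field equals the point estimate.
#'
#' @param calls data frame with columns `variant_id` and `call`
#'   (e.g. from [classify_and_call()]).
#' @param truth data frame with columns `variant_id` and `prior_label`
#'   (`"pathogenic"`, `"non_pathogenic"` or `"uncertain"`).
#' @return object of class `performance_report`: list with counts,
#'   point estimates and zero-failure bounds (percents), plus
#'   `excluded_uncertain` (variant ids left out of the evaluation).
#' @export
screen_performance <- function(calls, truth) {
  bad <- !truth$prior_label %in% .prior_labels
  if (any(bad))
    .stop("unknown prior_label value(s): %s",
          paste(unique(truth$prior_label[bad]), collapse = ", "))
  labelled <- truth[truth$prior_label != "uncertain", , drop = FALSE]
  miss <- setdiff(labelled$variant_id, calls$variant_id)
  if (length(miss) > 0)
    .stop("no screen call for labelled variant(s): %s", paste(miss, collapse = ", "))
  call_of <- setNames(calls$call, calls$variant_id)

  pos <- labelled$variant_id[labelled$prior_label == "pathogenic"]
  neg <- labelled$variant_id[labelled$prior_label == "non_pathogenic"]
  if (length(pos) == 0)
    .stop("empty truth partition: no pathogenic-labelled variants",
          class = "mmrscreen_empty_partition")
  if (length(neg) == 0)
    .stop("empty truth partition: no non_pathogenic-labelled variants",
          class = "mmrscreen_empty_partition")

  n_detected <- sum(call_of[pos] == "mmr_abrogating")
  n_fp <- sum(call_of[neg] == "mmr_abrogating")

  sens_point <- 100 * n_detected / length(pos)
  spec_point <- 100 * (length(neg) - n_fp) / length(neg)
  zf_bound <- function(n) 100 * (n - 1) / n
  sens_bound <- if (n_detected == length(pos)) zf_bound(length(pos)) else sens_point
  spec_bound <- if (n_fp == 0) zf_bound(length(neg)) else spec_point

  structure(list(
    n_pathogenic_truth = length(pos),
    n_detected = n_detected,
    n_nonpathogenic_truth = length(neg),
    n_false_positive = n_fp,
    sensitivity_point = sens_point,
    specificity_point = spec_point,
    sensitivity_zero_failure_bound = sens_bound,
    specificity_zero_failure_bound = spec_bound,
    excluded_uncertain = setdiff(truth$variant_id, labelled$variant_id)
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report>\n  sensitivity: %d/%d detected, point %.1f%%, zero-failure bound >%.1f%%\n",
              x$n_detected, x$n_pathogenic_truth,
              x$sensitivity_point, x$sensitivity_zero_failure_bound))
  cat(sprintf("  specificity: %d/%d false positive, point %.1f%%, zero-failure bound >%.1f%%\n",
              x$n_false_positive, x$n_nonpathogenic_truth,
              x$specificity_point, x$specificity_zero_failure_bound))
  if (length(x$excluded_uncertain) > 0)
    cat(sprintf("  excluded (uncertain label): %s\n",
                paste(x$excluded_uncertain, collapse = ", ")))
  invisible(x)
}
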