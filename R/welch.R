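# One-tailed unpaired t-test with Welch's correction, as used for all
# rate and frequency comparisons (variant vs MMR-proficient control).

#' One-tailed Welch t-test
#'
#' Unpaired two-sample t statistic without the equal-variance assumption,
#' with Welch-Satterthwaite degrees of freedom, and a one-tailed p-value in
#' the fixed direction "sample a greater than sample b" (every comparison
#' in the assay tests whether a variant's rate exceeds the control's).
#'
#' `t = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` and
#' `df = (s_a^2/n_a + s_b^2/n_b)^2 / ((s_a^2/n_a)^2/(n_a-1) + (s_b^2/n_b)^2/(n_b-1))`.
#'
#' @param sample_a,sample_b numeric vectors, each with at least 2 finite
#'   values; at least one sample must have positive variance.
#' @param direction only `"a_greater"` is supported.
#' @return object of class `welch_result`: list with `t_statistic`,
#'   `degrees_freedom` (non-integer allowed), `p_one_tailed`.
#' @export
welch_one_tailed <- function(sample_a, sample_b, direction = "a_greater") {
  direction <- match.arg(direction, "a_greater")
  a <- sample_a[is.finite(sample_a)]
  b <- sample_b[is.finite(sample_b)]
  if (length(a) < 2 || length(b) < 2)
    .stop("each sample needs at least 2 finite values")
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  if (va + vb == 0)
    .stop("both samples have zero variance; t statistic undefined")
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  structure(list(t_statistic = t_stat,
                 degrees_freedom = df,
                 p_one_tailed = pt(t_stat, df, lower.tail = FALSE)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t = %.4f, df = %.3f, one-tailed p = %.4g %s\n",
              x$t_statistic, x$degrees_freedom, x$p_one_tailed,
              significance_stars(x$p_one_tailed)))
  invisible(x)
}

#' Star annotation for a p-value
#'
#' Strict thresholds: `*` p<0.05, `**` p<0.01, `***` p<0.001,
#' `****` p<0.0001; `ns` otherwise (p = 0.05 exactly is `ns`).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return character vector of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    .stop("p-values must lie in [0, 1]")
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 5e-2, "*", "ns"))))
}
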