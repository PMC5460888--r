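# Western-blot quantification relative to the Msh6+/- control lane.

#' Protein quantification for one Western lane
#'
#' @param msh6_signal,msh2_signal,loading_signal non-negative infrared
#'   fluorescence signals (arbitrary units); `loading_signal` is the
#'   gamma-tubulin loading control and must be positive.
#' @return object of class `protein_quant`.
#' @export
protein_quant <- function(msh6_signal, msh2_signal = NA_real_, loading_signal) {
  if (!is.finite(loading_signal) || loading_signal <= 0)
    .stop("loading_signal must be positive for a quantified lane")
  if (msh6_signal < 0 || (!is.na(msh2_signal) && msh2_signal < 0))
    .stop("signals must be non-negative")
  structure(list(msh6_signal = msh6_signal, msh2_signal = msh2_signal,
                 loading_signal = loading_signal),
            class = "protein_quant")
}

#' Loading-normalized protein level relative to a control lane
#'
#' Returns `100 * (variant signal / variant loading) / (control signal /
#' control loading)`, i.e. the variant's MSH6 (or MSH2) level as a percent
#' of the MMR-proficient control after gamma-tubulin normalization. The
#' result is invariant under rescaling both signals of a lane by a common
#' positive factor.
#'
#' @param variant,control `protein_quant` lanes.
#' @param protein `"msh6"` (default) or `"msh2"`.
#' @return percent (numeric scalar).
#' @export
relative_protein_level <- function(variant, control, protein = c("msh6", "msh2")) {
  protein <- match.arg(protein)
  field <- paste0(protein, "_signal")
  v <- variant[[field]]; ctl <- control[[field]]
  if (is.na(v) || is.na(ctl))
    .stop("%s signal missing from a lane", protein)
  if (ctl <= 0)
    .stop("control %s signal must be positive to form a ratio", protein)
  100 * (v / variant$loading_signal) / (ctl / control$loading_signal)
}
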