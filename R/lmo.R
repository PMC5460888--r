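# Design of targeting oligonucleotides (LMO-style single-stranded DNA
# oligos carrying a 1-2 base codon substitution).

#' Design a codon-substitution targeting oligonucleotide
#'
#' Builds the mutant window around a codon replacement in a coding
#' sequence. The window is centered on the first base that differs between
#' the reference and replacement codons; if a centered window would run off
#' either end of the reference it is shifted just enough to fit (the
#' substitution then sits off-center). The sense oligo is the mutant
#' window on the coding strand; the antisense oligo is its reverse
#' complement. Oligo chemistry (LNA modification) is not represented.
#'
#' @param reference_cds coding sequence: a character scalar or anything
#'   `Biostrings::DNAString()` accepts. Length must be a multiple of 3.
#' @param codon_index 1-based codon to replace.
#' @param replacement_codon 3-mer differing from the reference codon in 1
#'   or 2 bases (a full-codon replacement is outside the screen's design,
#'   and an identical codon is a no-op error).
#' @param oligo_length window length (default 35; must be <= reference
#'   length).
#' @param orientation `"sense"` or `"antisense"`.
#' @return character scalar of class `lmo_design` with attributes
#'   `substitution_position` (1-based reference coordinate of the first
#'   changed base), `window_start`, `window_end`, `orientation`.
#' @export
design_lmo <- function(reference_cds, codon_index, replacement_codon,
                       oligo_length = 35L, orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  ref <- toupper(as.character(reference_cds))
  if (!grepl("^[ACGT]+$", ref)) .stop("reference must be an unambiguous DNA sequence")
  if (nchar(ref) %% 3 != 0) .stop("reference CDS length must be a multiple of 3")
  replacement_codon <- toupper(replacement_codon)
  if (!grepl("^[ACGT]{3}$", replacement_codon)) .stop("replacement must be a 3-base codon")
  n_codons <- nchar(ref) / 3
  if (codon_index < 1 || codon_index > n_codons)
    .stop("codon_index %d outside reference (%d codons)", codon_index, n_codons)
  if (oligo_length > nchar(ref))
    .stop("oligo window (%d) longer than the reference (%d)", oligo_length, nchar(ref))

  codon_start <- 3L * (codon_index - 1L) + 1L
  ref_codon <- substr(ref, codon_start, codon_start + 2L)
  diffs <- which(strsplit(ref_codon, "")[[1]] != strsplit(replacement_codon, "")[[1]])
  if (length(diffs) == 0)
    .stop("replacement codon is identical to the reference codon (no-op)")
  if (length(diffs) == 3)
    .stop("replacement differs in all 3 bases; the design substitutes 1-2 bases")

  mutant <- ref
  substr(mutant, codon_start, codon_start + 2L) <- replacement_codon
  sub_pos <- codon_start + diffs[1] - 1L

  start <- sub_pos - (oligo_length %/% 2L)
  start <- max(1L, min(start, nchar(ref) - oligo_length + 1L))  # shift to fit
  end <- start + oligo_length - 1L
  oligo <- substr(mutant, start, end)
  if (orientation == "antisense")
    oligo <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(oligo)))

  structure(oligo, substitution_position = sub_pos,
            window_start = start, window_end = end,
            orientation = orientation, class = "lmo_design")
}

#' @export
print.lmo_design <- function(x, ...) {
  cat(sprintf("<lmo_design> %s oligo %s (ref %d-%d, substitution at %d)\n",
              attr(x, "orientation"), unclass(x),
              attr(x, "window_start"), attr(x, "window_end"),
              attr(x, "substitution_position")))
  invisible(x)
}

#' Read a reference coding sequence from a FASTA file
#'
#' @param path FASTA file; the first record is used.
#' @return character scalar (the sequence), named by its FASTA header.
#' @export
read_reference_cds <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) .stop("no sequences in %s", path)
  setNames(as.character(seqs[[1]]), names(seqs)[1])
}
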