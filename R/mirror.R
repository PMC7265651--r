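## Strand-contract validation utilities: reverse-complementing the
## genome and mirroring every annotation and signal must leave all
## oriented metrics (median TSS, spread, efficiency, motif keys)
## unchanged. Position p on a chromosome of length L maps to L - 1 - p.

#' Reverse-complement every chromosome of a genome
#' @param genome Named character vector of sequences.
#' @return Mirrored genome.
#' @export
mirror_genome <- function(genome) {
  out <- revcomp(genome)
  names(out) <- names(genome)
  out
}

#' Mirror promoter windows onto the reverse-complemented genome
#' @param windows A `promoter_windows` table.
#' @param chrom_lengths Named chromosome lengths.
#' @return Windows with flipped strands and mirrored anchors.
#' @export
mirror_windows <- function(windows, chrom_lengths) {
  out <- windows
  L <- chrom_lengths[windows$chrom]
  out$anchor_pos <- as.integer(L - 1L - windows$anchor_pos)
  out$strand <- ifelse(windows$strand == "+", "-", "+")
  out
}

#' Mirror a stranded signal onto the reverse-complemented genome
#' @param signal A `stranded_signal`.
#' @return Signal with reversed, strand-swapped count vectors.
#' @export
mirror_signal <- function(signal) {
  out <- signal
  out$plus <- lapply(signal$minus, rev)
  out$minus <- lapply(signal$plus, rev)
  out
}

#' Mirror a fragment table onto the reverse-complemented genome
#' @param fragments Fragment table (0-based half-open).
#' @param chrom_lengths Named chromosome lengths.
#' @return Mirrored fragment table.
#' @export
mirror_fragments <- function(fragments, chrom_lengths) {
  L <- chrom_lengths[fragments$chrom]
  fragment_table(fragments$chrom, L - fragments$end, L - fragments$start)
}
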