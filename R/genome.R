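#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a genome (named character vector) to FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## oriented subsequence: `len` bases starting at 0-based `pos0` reading
## in promoter orientation (for "-", reads leftward and complements)
subseq_oriented <- function(genome, chrom, pos0, len, strand) {
  seqlen <- nchar(genome[[chrom]], type = "bytes")
  if (strand == "+") {
    if (pos0 < 0 || pos0 + len > seqlen) return(NA_character_)
    substr(genome[[chrom]], pos0 + 1L, pos0 + len)
  } else {
    if (pos0 - len + 1L < 0 || pos0 >= seqlen) return(NA_character_)
    revcomp(substr(genome[[chrom]], pos0 - len + 2L, pos0 + 1L))
  }
}

## single oriented base at 0-based genomic pos
base_oriented <- function(genome, chrom, pos0, strand) {
  seqlen <- nchar(genome[[chrom]], type = "bytes")
  if (pos0 < 0 || pos0 >= seqlen) return(NA_character_)
  b <- substr(genome[[chrom]], pos0 + 1L, pos0 + 1L)
  if (strand == "+") b else chartr("ACGTN", "TGCAN", b)
}

.complement_map <- c(A = "T", C = "G", G = "C", T = "A")

## vector of oriented bases over relative coordinates rel_lo..rel_hi
## around an anchor; one substring extraction, so cost is O(window),
## not O(chromosome) per base. Out-of-genome or non-ACGT bases are NA.
oriented_chars <- function(genome, chrom, anchor_pos, strand,
                           rel_lo, rel_hi) {
  seqlen <- nchar(genome[[chrom]], type = "bytes")
  rel <- rel_lo:rel_hi
  g <- if (strand == "+") anchor_pos + rel else anchor_pos - rel
  lo <- max(0L, min(g)); hi <- min(seqlen - 1L, max(g))
  out <- rep(NA_character_, length(rel))
  if (lo > hi) return(out)
  block <- strsplit(substr(genome[[chrom]], lo + 1L, hi + 1L), "")[[1]]
  ok <- g >= lo & g <= hi
  b <- block[g[ok] - lo + 1L]
  if (strand == "-") b <- unname(.complement_map[b])
  b[!b %in% c("A", "C", "G", "T")] <- NA_character_
  out[ok] <- b
  out
}
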