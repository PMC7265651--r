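#' Stranded per-base signal container
#'
#' Holds one non-negative count vector per chromosome per strand over
#' every genomic position (0-based). Used for TSS-seq 5' ends, ChIP-exo
#' read 5' ends, and nucleosome fragment midpoints alike.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param library_id Identifier carried through to outputs.
#' @return An object of class `stranded_signal` with per-chromosome
#'   `plus` and `minus` count vectors.
#' @export
stranded_signal <- function(chrom_lengths, library_id = "lib") {
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)),
            all(chrom_lengths >= 1))
  mk <- function() lapply(chrom_lengths, function(n) numeric(n))
  structure(list(chrom_lengths = chrom_lengths, plus = mk(), minus = mk(),
                 library_id = library_id),
            class = "stranded_signal")
}

#' @export
print.stranded_signal <- function(x, ...) {
  cat("stranded_signal '", x$library_id, "': ",
      length(x$chrom_lengths), " chromosome(s), ",
      format(signal_total_reads(x), big.mark = ","), " reads\n", sep = "")
  invisible(x)
}

#' Total reads in a stranded signal (both strands, all chromosomes)
#' @param signal A `stranded_signal`.
#' @return Numeric total count.
#' @export
signal_total_reads <- function(signal) {
  sum(vapply(signal$plus, sum, numeric(1))) +
    sum(vapply(signal$minus, sum, numeric(1)))
}

## add `count` at 0-based positions pos0 (vector) on one strand
signal_add <- function(signal, chrom, pos0, strand, count = 1) {
  stopifnot(chrom %in% names(signal$chrom_lengths))
  len <- signal$chrom_lengths[[chrom]]
  keep <- pos0 >= 0 & pos0 < len
  pos0 <- pos0[keep]
  if (length(count) > 1) count <- count[keep]
  if (!length(pos0)) return(signal)
  slot <- if (strand == "+") "plus" else "minus"
  tab <- rowsum(rep_len(as.numeric(count), length(pos0)), pos0)
  idx <- as.integer(rownames(tab)) + 1L
  signal[[slot]][[chrom]][idx] <- signal[[slot]][[chrom]][idx] + tab[, 1]
  signal
}

## strand-restricted count slice over 0-based positions (in order given)
signal_slice <- function(signal, chrom, pos0, strand) {
  slot <- if (strand == "+") "plus" else "minus"
  v <- signal[[slot]][[chrom]]
  out <- numeric(length(pos0))
  ok <- pos0 >= 0 & pos0 < length(v)
  out[ok] <- v[pos0[ok] + 1L]
  out
}

#' Read a strand-split bedGraph pair into a stranded signal
#'
#' bedGraph records are 0-based half-open with integer values; each
#' record is expanded to per-position counts and overlapping records are
#' summed. Unsorted input is accepted.
#'
#' @param plus_path,minus_path bedGraph files for the plus and minus
#'   strand tracks.
#' @param chrom_lengths Named lengths; inferred from the records
#'   (maximum end per chromosome) when `NULL`.
#' @param library_id Identifier for the resulting signal.
#' @return A `stranded_signal`.
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, chrom_lengths = NULL,
                               library_id = "lib") {
  grp <- .import_bedgraph(plus_path)
  grm <- .import_bedgraph(minus_path)
  if (is.null(chrom_lengths)) {
    chroms <- union(as.character(GenomicRanges::seqnames(grp)),
                    as.character(GenomicRanges::seqnames(grm)))
    if (!length(chroms)) stop("cannot infer chromosome lengths from empty tracks")
    chrom_lengths <- vapply(chroms, function(ch) {
      max(c(0L, BiocGenerics::end(grp[GenomicRanges::seqnames(grp) == ch]),
            BiocGenerics::end(grm[GenomicRanges::seqnames(grm) == ch])))
    }, numeric(1))
  }
  sig <- stranded_signal(chrom_lengths, library_id)
  sig <- .add_bedgraph(sig, grp, "+")
  sig <- .add_bedgraph(sig, grm, "-")
  sig
}

.import_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(GenomicRanges::GRanges(score = numeric(0)))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) stop("bedGraph format error: negative value in ", path)
  gr
}

.add_bedgraph <- function(sig, gr, strand) {
  if (!length(gr)) return(sig)
  for (ch in unique(as.character(GenomicRanges::seqnames(gr)))) {
    g <- gr[GenomicRanges::seqnames(gr) == ch]
    ## expand 1-based closed GRanges back to 0-based positions
    pos0 <- unlist(mapply(function(s, e) s:e, BiocGenerics::start(g) - 1L,
                          BiocGenerics::end(g) - 1L, SIMPLIFY = FALSE))
    cnt <- rep(g$score, BiocGenerics::width(g))
    sig <- signal_add(sig, ch, pos0, strand, cnt)
  }
  sig
}

#' Write a stranded signal as a strand-split bedGraph pair
#'
#' @param signal A `stranded_signal`.
#' @param plus_path,minus_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_bedgraph_pair <- function(signal, plus_path, minus_path) {
  .export_bedgraph(signal, "plus", plus_path)
  .export_bedgraph(signal, "minus", minus_path)
  invisible(c(plus_path, minus_path))
}

.export_bedgraph <- function(signal, slot, path) {
  chrom <- character(0); s1 <- integer(0); e1 <- integer(0)
  val <- numeric(0)
  for (ch in names(signal$chrom_lengths)) {
    r <- rle(signal[[slot]][[ch]])
    ends <- cumsum(r$lengths)            # 0-based half-open ends
    keep <- r$values != 0
    if (!any(keep)) next
    chrom <- c(chrom, rep(ch, sum(keep)))
    s1 <- c(s1, (ends - r$lengths)[keep] + 1L)
    e1 <- c(e1, ends[keep])
    val <- c(val, r$values[keep])
  }
  if (!length(chrom)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = s1, end = e1),
                               score = val,
                               seqlengths = signal$chrom_lengths)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Extract read 5' ends from a BAM file into a stranded signal
#'
#' Thin optional converter for coordinate-sorted BAM input: the 5' end
#' of each aligned read is taken strand-aware (leftmost base for plus,
#' rightmost for minus alignments). Requires Rsamtools.
#'
#' @param bam_path Path to an indexed BAM file.
#' @param chrom_lengths Named chromosome lengths.
#' @param library_id Identifier.
#' @return A `stranded_signal` of 5'-end counts.
#' @export
signal_from_bam <- function(bam_path, chrom_lengths, library_id = "lib") {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required for BAM input")
  res <- Rsamtools::scanBam(bam_path,
    param = Rsamtools::ScanBamParam(what = c("rname", "pos", "strand", "qwidth")))[[1]]
  keep <- !is.na(res$pos)
  sig <- stranded_signal(chrom_lengths, library_id)
  rname <- as.character(res$rname)[keep]
  pos <- res$pos[keep]; str <- as.character(res$strand)[keep]
  qw <- res$qwidth[keep]
  for (ch in unique(rname)) {
    i <- rname == ch
    p <- i & str == "+"
    m <- i & str == "-"
    if (any(p)) sig <- signal_add(sig, ch, pos[p] - 1L, "+")
    if (any(m)) sig <- signal_add(sig, ch, pos[m] + qw[m] - 2L, "-")
  }
  sig
}
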