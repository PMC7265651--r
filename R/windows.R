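#' Construct a promoter window table
#'
#' A promoter window is an oriented genomic interval around an anchor
#' (a TATA/TATA-like element, a median TSS, or a +1 nucleosome dyad).
#' `anchor_pos` is the 0-based genomic coordinate of the first anchor
#' base in promoter orientation; relative coordinate 0 is that base and
#' relative coordinates increase downstream. The window spans `up_ext`
#' nt upstream of the anchor through `down_ext` nt downstream of its
#' last base, so its width is `up_ext + anchor_len + down_ext` — 408 nt
#' for the default element-anchored windows (200 + 8 + 200) and 401 nt
#' for median-TSS-anchored windows (200 + 1 + 200).
#'
#' @param chrom,strand,anchor_pos Vectors of chromosome, strand
#'   (`"+"`/`"-"`) and 0-based anchor start (promoter orientation).
#' @param anchor_len Anchor length in nt (8 for TATA-box anchors, 1 for
#'   TSS or +1-nucleosome anchors).
#' @param up_ext,down_ext Extensions in nt (defaults 200/200).
#' @param promoter_id Unique identifiers (generated when `NULL`).
#' @param promoter_class One of `"taf1_enriched"`, `"taf1_depleted"`,
#'   `"neither"` per promoter.
#' @param anchor_kind One of `"element"`, `"median_tss"`, `"plus1_nuc"`.
#' @return A data.frame of class `promoter_windows`.
#' @export
promoter_windows <- function(chrom, strand, anchor_pos, anchor_len = 8L,
                             up_ext = 200L, down_ext = 200L,
                             promoter_id = NULL,
                             promoter_class = "neither",
                             anchor_kind = "element") {
  n <- length(anchor_pos)
  stopifnot(all(strand %in% c("+", "-")),
            all(promoter_class %in% c("taf1_enriched", "taf1_depleted", "neither")),
            all(anchor_kind %in% c("element", "median_tss", "plus1_nuc")))
  if (is.null(promoter_id)) promoter_id <- sprintf("p%05d", seq_len(n))
  w <- data.frame(promoter_id = promoter_id,
                  chrom = rep_len(chrom, n), strand = rep_len(strand, n),
                  anchor_pos = as.integer(anchor_pos),
                  anchor_len = as.integer(rep_len(anchor_len, n)),
                  up_ext = as.integer(rep_len(up_ext, n)),
                  down_ext = as.integer(rep_len(down_ext, n)),
                  promoter_class = rep_len(promoter_class, n),
                  anchor_kind = rep_len(anchor_kind, n),
                  stringsAsFactors = FALSE)
  class(w) <- c("promoter_windows", "data.frame")
  w
}

window_width <- function(w) w$up_ext + w$anchor_len + w$down_ext

## relative coordinates covered by window row `i` (upstream -> downstream)
window_rel_coords <- function(w, i = 1L) {
  seq.int(-w$up_ext[i], w$anchor_len[i] - 1L + w$down_ext[i])
}

## 0-based genomic positions of window row `i`, ordered by increasing rel
window_genomic_positions <- function(w, i = 1L) {
  rel <- window_rel_coords(w, i)
  if (w$strand[i] == "+") w$anchor_pos[i] + rel else w$anchor_pos[i] - rel
}

## genomic 0-based position of a relative coordinate, vectorised over rows
rel_to_genomic <- function(w, rel) {
  ifelse(w$strand == "+", w$anchor_pos + rel, w$anchor_pos - rel)
}

## check all window rows fit inside their chromosome
validate_windows <- function(w, chrom_lengths) {
  for (i in seq_len(nrow(w))) {
    g <- window_genomic_positions(w, i)
    len <- chrom_lengths[[w$chrom[i]]]
    if (is.null(len)) stop("unknown chromosome: ", w$chrom[i])
    if (min(g) < 0 || max(g) >= len)
      stop("coordinate error: window ", w$promoter_id[i], " off chromosome ",
           w$chrom[i])
  }
  invisible(w)
}

#' Read promoter annotations from a 6-column BED file
#'
#' The BED interval is the anchor span (0-based half-open); the name
#' field carries `promoter_id|promoter_class`, the score field encodes
#' the anchor kind (0 = element, 1 = median_tss, 2 = plus1_nuc). The
#' strand column is required.
#'
#' @param bed_path Path to the BED6 file.
#' @param up_ext,down_ext Window extensions applied around the anchors.
#' @param chrom_lengths Optional named lengths; windows are validated
#'   against them when supplied.
#' @return A `promoter_windows` data.frame (empty when the file is empty).
#' @export
read_promoters <- function(bed_path, up_ext = 200L, down_ext = 200L,
                           chrom_lengths = NULL) {
  if (file.size(bed_path) == 0)
    return(promoter_windows(character(0), character(0), integer(0))[0, ])
  gr <- rtracklayer::import(bed_path, format = "BED")
  str <- as.character(BiocGenerics::strand(gr))
  if (any(str == "*")) stop("format error: promoter BED requires a strand column")
  nm <- gr$name %||% sprintf("p%05d", seq_along(gr))
  parts <- strsplit(nm, "|", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  cls <- vapply(parts, function(p) if (length(p) > 1) p[2] else "neither",
                character(1))
  kind <- c("element", "median_tss", "plus1_nuc")[
    (as.integer(gr$score %||% 0) %% 3L) + 1L]
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)              # half-open end
  anchor_len <- end0 - start0
  anchor_pos <- ifelse(str == "+", start0, end0 - 1L)
  w <- promoter_windows(as.character(GenomicRanges::seqnames(gr)), str,
                        anchor_pos, anchor_len, up_ext, down_ext,
                        promoter_id = ids, promoter_class = cls,
                        anchor_kind = kind)
  if (!is.null(chrom_lengths)) validate_windows(w, chrom_lengths)
  w
}

#' Write promoter windows as a 6-column BED file
#'
#' Inverse of [read_promoters()]: writes the anchor spans with
#' `promoter_id|promoter_class` names and anchor-kind scores.
#'
#' @param windows A `promoter_windows` data.frame.
#' @param bed_path Output path.
#' @return Invisibly, `bed_path`.
#' @export
write_promoters <- function(windows, bed_path) {
  if (!nrow(windows)) {
    file.create(bed_path)
    return(invisible(bed_path))
  }
  start0 <- ifelse(windows$strand == "+", windows$anchor_pos,
                   windows$anchor_pos - windows$anchor_len + 1L)
  gr <- GenomicRanges::GRanges(windows$chrom,
    IRanges::IRanges(start = start0 + 1L, width = windows$anchor_len),
    strand = windows$strand,
    name = paste(windows$promoter_id, windows$promoter_class, sep = "|"),
    score = match(windows$anchor_kind,
                  c("element", "median_tss", "plus1_nuc")) - 1L)
  rtracklayer::export(gr, bed_path, format = "BED")
  invisible(bed_path)
}

#' Read paired-end fragments from a BED file
#'
#' Fragment midpoint convention for a half-open interval `[s, e)`:
#' `floor((s + e - 1) / 2)` — deterministic and consistent with the
#' integer-position signal model (a 147-nt fragment at `[100, 247)` has
#' midpoint 173).
#'
#' @param bed_path Path to a BED file of fragment intervals.
#' @return A data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `length`, and `midpoint` columns; empty for an empty file.
#' @export
read_fragments <- function(bed_path) {
  if (file.size(bed_path) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      midpoint = integer(0)))
  gr <- rtracklayer::import(bed_path, format = "BED")
  fragment_table(as.character(GenomicRanges::seqnames(gr)),
                 BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr))
}

## build the canonical fragment table from 0-based half-open intervals
fragment_table <- function(chrom, start0, end0) {
  stopifnot(all(end0 > start0))
  data.frame(chrom = chrom, start = as.integer(start0), end = as.integer(end0),
             length = as.integer(end0 - start0),
             midpoint = as.integer(floor((start0 + end0 - 1) / 2)))
}

#' Write a fragment table as a 6-column BED file
#' @param fragments Fragment table from [read_fragments()] or
#'   [simulate_mnase()].
#' @param bed_path Output path.
#' @return Invisibly, `bed_path`.
#' @export
write_fragments <- function(fragments, bed_path) {
  if (!nrow(fragments)) {
    file.create(bed_path)
    return(invisible(bed_path))
  }
  gr <- GenomicRanges::GRanges(fragments$chrom,
    IRanges::IRanges(start = fragments$start + 1L, end = fragments$end),
    strand = "+", name = sprintf("f%07d", seq_len(nrow(fragments))), score = 0L)
  rtracklayer::export(gr, bed_path, format = "BED")
  invisible(bed_path)
}
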