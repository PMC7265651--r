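#' TSS usage vector
#'
#' Usage at each window position: reads at the position divided by
#' total reads in the promoter window. Sums to 1.
#'
#' @param dist A `tss_dist`.
#' @return Numeric vector (NA when expression is 0).
#' @export
tss_usage <- function(dist) norm_density(dist)

#' TSS efficiency vector with exclusion flags
#'
#' Efficiency at position i is reads at i divided by reads at or
#' downstream of i within the window — the fraction of scanning
#' polymerase that initiates there rather than continuing. Positions
#' with efficiency >= `min_eff` computed from <= `max_reads` reads are
#' flagged excluded (such high-efficiency/low-read calls arise only at
#' downstream window edges); zero-denominator positions are undefined
#' (NA).
#'
#' @param dist A `tss_dist`.
#' @param min_eff Exclusion efficiency threshold (default 0.20).
#' @param max_reads Exclusion read threshold (default 5).
#' @return List with `efficiency` (in `[0, 1]` or NA), `excluded`
#'   (logical), and `counts`.
#' @export
tss_efficiency <- function(dist, min_eff = 0.20, max_reads = 5) {
  cnt <- dist$counts
  suffix <- rev(cumsum(rev(cnt)))
  eff <- ifelse(suffix > 0, cnt / suffix, NA_real_)
  excluded <- !is.na(eff) & eff >= min_eff & cnt <= max_reads
  list(efficiency = eff, excluded = excluded, counts = cnt)
}

#' Extract the N(-8)N(-1)N(+1) motif key underlying a TSS
#'
#' Bases are read in promoter orientation: +1 is the TSS itself, -1
#' the base immediately upstream, -8 eight bases upstream. On a minus
#' strand TSS the context is complemented with -8 on the
#' higher-coordinate side. Out-of-bounds or non-ACGT context yields
#' `NA` (the "ambiguous" key, excluded from 64-way tallies).
#'
#' @param genome Named character vector of sequences.
#' @param chrom Chromosome name.
#' @param tss_pos 0-based genomic position of the TSS.
#' @param strand `"+"` or `"-"`.
#' @return A 3-character key such as `"ACA"`, or `NA_character_`.
#' @export
extract_motif <- function(genome, chrom, tss_pos, strand) {
  off <- c(-8L, -1L, 0L)
  gpos <- if (strand == "+") tss_pos + off else tss_pos - off
  b <- vapply(gpos, function(p) base_oriented(genome, chrom, p, strand),
              character(1))
  if (anyNA(b) || !all(b %in% c("A", "C", "G", "T"))) return(NA_character_)
  paste(b, collapse = "")
}

## motif key per relative position of a window (NA where ambiguous);
## vectorized over one oriented substring including 8 nt of upstream
## context for the -8 base
window_motif_keys <- function(genome, window) {
  rel <- window_rel_coords(window, 1L)
  lo <- min(rel) - 8L; hi <- max(rel)
  ch <- oriented_chars(genome, window$chrom, window$anchor_pos,
                       window$strand, lo, hi)
  idx <- rel - lo + 1L
  keys <- paste0(ch[idx - 8L], ch[idx - 1L], ch[idx])
  keys[is.na(ch[idx - 8L]) | is.na(ch[idx - 1L]) | is.na(ch[idx])] <-
    NA_character_
  keys
}

#' Per-library motif usage fractions
#'
#' Reads within the promoter windows are summed per
#' N(-8)N(-1)N(+1) key; fractions are reads per key over total reads,
#' so the 64 keys plus the ambiguous bucket sum to 1.
#'
#' @param signal A `stranded_signal`.
#' @param windows A `promoter_windows` table.
#' @param genome Named character vector of sequences.
#' @return Named numeric vector over the 64 keys plus `"ambiguous"`
#'   (all NA when no reads fall in the windows).
#' @export
motif_usage_fractions <- function(signal, windows, genome) {
  keys <- c(all_motif_keys(), "ambiguous")
  acc <- stats::setNames(numeric(length(keys)), keys)
  for (i in seq_len(nrow(windows))) {
    d <- window_counts(signal, windows[i, ])
    nz <- which(d$counts > 0)
    if (!length(nz)) next
    k <- window_motif_keys(genome, windows[i, ])[nz]
    k[is.na(k)] <- "ambiguous"
    add <- rowsum(d$counts[nz], k)
    acc[rownames(add)] <- acc[rownames(add)] + add[, 1]
  }
  tot <- sum(acc)
  if (tot == 0) return(acc * NA_real_)
  acc / tot
}

#' Motif usage-fraction difference, library minus WT
#'
#' @param frac_lib,frac_wt Vectors from [motif_usage_fractions()].
#' @return Difference over the shared keys (sums to 0).
#' @export
motif_usage_diff <- function(frac_lib, frac_wt) {
  keys <- intersect(names(frac_lib), names(frac_wt))
  frac_lib[keys] - frac_wt[keys]
}

#' Primary/secondary/tertiary TSS positions by usage
#'
#' Used positions ranked by read count, descending; ties broken
#' upstream-first.
#'
#' @param dist A `tss_dist`.
#' @param n_ranks Number of ranks reported (default 3; fewer when
#'   fewer positions are used).
#' @return data.frame with `rank`, `rel_pos`, `counts`.
#' @export
rank_tss <- function(dist, n_ranks = 3L) {
  used <- which(dist$counts > 0)
  ord <- used[order(-dist$counts[used], dist$rel[used])]
  take <- utils::head(ord, n_ranks)
  data.frame(rank = seq_along(take), rel_pos = dist$rel[take],
             counts = dist$counts[take])
}

#' Per-position per-motif usage and efficiency aggregates
#'
#' For every motif key and relative position in `span`, aggregates
#' usage and efficiency over the promoters carrying that motif at that
#' position. Efficiency values flagged excluded (or undefined) do not
#' enter the efficiency aggregates; usage aggregates use all covered
#' positions.
#'
#' @param signal A `stranded_signal`.
#' @param windows WT-median-anchored `promoter_windows`.
#' @param genome Named character vector of sequences.
#' @param motif_subset Keys to report (default: all 64).
#' @param span Relative span, default `c(-100, 100)`.
#' @return data.frame with `motif`, `rel_pos`, `n`, `mean_usage`,
#'   `median_usage`, `n_eff`, `mean_eff`, `median_eff`.
#' @export
positional_motif_aggregates <- function(signal, windows, genome,
                                        motif_subset = NULL,
                                        span = c(-100L, 100L)) {
  if (is.null(motif_subset)) motif_subset <- all_motif_keys()
  recs <- list()
  for (i in seq_len(nrow(windows))) {
    d <- window_counts(signal, windows[i, ])
    if (d$expression <= 0) next
    keys <- window_motif_keys(genome, windows[i, ])
    eff <- tss_efficiency(d)
    use <- tss_usage(d)
    sel <- which(d$rel >= span[1] & d$rel <= span[2] &
                   !is.na(keys) & keys %in% motif_subset)
    if (!length(sel)) next
    recs[[length(recs) + 1L]] <- data.frame(
      motif = keys[sel], rel_pos = d$rel[sel], usage = use[sel],
      eff = ifelse(eff$excluded[sel], NA_real_, eff$efficiency[sel]))
  }
  if (!length(recs))
    return(data.frame(motif = character(0), rel_pos = integer(0),
                      n = integer(0), mean_usage = numeric(0),
                      median_usage = numeric(0), n_eff = integer(0),
                      mean_eff = numeric(0), median_eff = numeric(0)))
  long <- do.call(rbind, recs)
  agg <- function(x, f) stats::aggregate(x, by = list(motif = long$motif,
                                                      rel_pos = long$rel_pos),
                                         FUN = f)
  out <- agg(long$usage, length)
  names(out)[3] <- "n"
  out$mean_usage <- agg(long$usage, mean)$x
  out$median_usage <- agg(long$usage, stats::median)$x
  out$n_eff <- agg(long$eff, function(v) sum(!is.na(v)))$x
  out$mean_eff <- agg(long$eff, function(v) mean(v, na.rm = TRUE))$x
  out$median_eff <- agg(long$eff, function(v) stats::median(v, na.rm = TRUE))$x
  out
}
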