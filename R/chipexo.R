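## promoter-sense ("top") or anti-sense ("bot") genomic strand of a window
.window_strand <- function(window, which) {
  if (which == "top") window$strand
  else if (window$strand == "+") "-" else "+"
}

#' Directional median position of strand-restricted signal in a window
#'
#' "Top" and "bot" are defined relative to promoter orientation: top is
#' the promoter-sense strand (for a minus-strand promoter, the genomic
#' minus strand). The median is directional — the first position
#' (upstream to downstream) whose cumulative count reaches 50%.
#'
#' @param signal A `stranded_signal`.
#' @param window One row of a `promoter_windows` table.
#' @param which_strand `"top"` or `"bot"`.
#' @param min_reads Minimum strand reads for a defined median
#'   (default 10).
#' @return Relative position, or `NA` below the read minimum.
#' @export
strand_median_position <- function(signal, window,
                                   which_strand = c("top", "bot"),
                                   min_reads = 10) {
  which_strand <- match.arg(which_strand)
  g <- window_genomic_positions(window, 1L)
  cnt <- signal_slice(signal, window$chrom, g,
                      .window_strand(window, which_strand))
  if (sum(cnt) < min_reads) return(NA_integer_)
  window_rel_coords(window, 1L)[dir_quantile_index(cnt, 0.5)]
}

#' Per-promoter ChIP-exo strand-median summaries
#'
#' @param signal A `stranded_signal` of ChIP-exo read 5' ends.
#' @param windows A `promoter_windows` table.
#' @param min_reads Per-strand minimum for a defined median.
#' @param median_tss_rel Optional per-promoter median TSS (relative
#'   coordinates) used to report distances.
#' @return data.frame with `promoter_id`, `promoter_class`,
#'   `median_top`, `median_bot`, `reads_top`, `reads_bot`, and (when
#'   `median_tss_rel` is given) `dist_to_median_tss_top/bot`.
#' @export
chipexo_summaries <- function(signal, windows, min_reads = 10,
                              median_tss_rel = NULL) {
  out <- data.frame(promoter_id = windows$promoter_id,
                    promoter_class = windows$promoter_class)
  for (side in c("top", "bot")) {
    med <- integer(nrow(windows)); rds <- numeric(nrow(windows))
    for (i in seq_len(nrow(windows))) {
      g <- window_genomic_positions(windows, i)
      cnt <- signal_slice(signal, windows$chrom[i], g,
                          .window_strand(windows[i, ], side))
      rds[i] <- sum(cnt)
      med[i] <- if (rds[i] >= min_reads)
        window_rel_coords(windows, i)[dir_quantile_index(cnt, 0.5)]
      else NA_integer_
    }
    out[[paste0("median_", side)]] <- med
    out[[paste0("reads_", side)]] <- rds
  }
  if (!is.null(median_tss_rel)) {
    out$dist_to_median_tss_top <- out$median_top - median_tss_rel
    out$dist_to_median_tss_bot <- out$median_bot - median_tss_rel
  }
  out
}

#' Binned histograms of strand-median positions
#'
#' @param summaries Output of [chipexo_summaries()].
#' @param binwidth Bin width in nt (default 5).
#' @return List with `histogram` (data.frame `promoter_class`,
#'   `strand`, `bin_start`, `count`) and `class_means` (mean distance
#'   to median TSS per class and strand, when distances are present).
#'   Empty classes are skipped.
#' @export
median_histograms <- function(summaries, binwidth = 5) {
  rows <- list()
  for (cl in unique(summaries$promoter_class)) {
    for (side in c("top", "bot")) {
      v <- summaries[[paste0("median_", side)]][
        summaries$promoter_class == cl]
      v <- v[!is.na(v)]
      if (!length(v)) next
      bin <- floor(v / binwidth) * binwidth
      tab <- table(bin)
      rows[[length(rows) + 1L]] <- data.frame(
        promoter_class = cl, strand = side,
        bin_start = as.integer(names(tab)), count = as.integer(tab))
    }
  }
  hist <- if (length(rows)) do.call(rbind, rows) else
    data.frame(promoter_class = character(0), strand = character(0),
               bin_start = integer(0), count = integer(0))
  class_means <- NULL
  if ("dist_to_median_tss_top" %in% names(summaries)) {
    class_means <- do.call(rbind, lapply(unique(summaries$promoter_class),
      function(cl) {
        s <- summaries[summaries$promoter_class == cl, ]
        data.frame(promoter_class = cl,
                   mean_dist_top = mean(s$dist_to_median_tss_top, na.rm = TRUE),
                   mean_dist_bot = mean(s$dist_to_median_tss_bot, na.rm = TRUE))
      }))
  }
  list(histogram = hist, class_means = class_means)
}

#' Smoothed aggregate ChIP-exo profile over top promoters
#'
#' Promoters are ranked by total WT ChIP-exo reads in their windows and
#' the top fraction selected; per promoter and strand, window counts
#' are normalized to sum 1, averaged across selected promoters, and
#' smoothed with the 21-point local quadratic smoother
#' ([smooth_quadratic()]).
#'
#' @param signal ChIP-exo `stranded_signal` to profile.
#' @param windows A `promoter_windows` table.
#' @param signal_wt Signal used for ranking (default: `signal`).
#' @param top_fraction Fraction of promoters kept (default 0.5).
#' @param half Smoother half-width (default 10 neighbors).
#' @return List with `rel`, `top`, `bot` (smoothed mean normalized
#'   profiles) and `n_promoters`.
#' @export
aggregate_profile <- function(signal, windows, signal_wt = signal,
                              top_fraction = 0.5, half = 10L) {
  totals <- vapply(seq_len(nrow(windows)), function(i) {
    g <- window_genomic_positions(windows, i)
    sum(signal_slice(signal_wt, windows$chrom[i], g, windows$strand[i])) +
      sum(signal_slice(signal_wt, windows$chrom[i], g,
                       .window_strand(windows[i, ], "bot")))
  }, numeric(1))
  keep <- order(-totals, windows$promoter_id)[
    seq_len(max(1L, floor(top_fraction * nrow(windows))))]
  rel <- window_rel_coords(windows, 1L)
  prof <- list()
  for (side in c("top", "bot")) {
    acc <- numeric(length(rel)); used <- 0L
    for (i in keep) {
      g <- window_genomic_positions(windows, i)
      cnt <- signal_slice(signal, windows$chrom[i], g,
                          .window_strand(windows[i, ], side))
      if (sum(cnt) == 0) next
      acc <- acc + cnt / sum(cnt)
      used <- used + 1L
    }
    prof[[side]] <- smooth_quadratic(if (used) acc / used else acc, half)
  }
  list(rel = rel, top = prof$top, bot = prof$bot,
       n_promoters = length(keep))
}

#' Per-promoter ChIP-exo median shifts, mutant vs WT
#'
#' Oriented deltas (downstream positive), per strand, for promoters
#' with defined medians on both sides.
#'
#' @param summaries_mut,summaries_wt Outputs of [chipexo_summaries()].
#' @return data.frame with `promoter_id`, `delta_top`, `delta_bot`.
#' @export
chipexo_shift <- function(summaries_mut, summaries_wt) {
  m <- merge(summaries_mut, summaries_wt, by = "promoter_id",
             suffixes = c("_mut", "_wt"))
  data.frame(promoter_id = m$promoter_id,
             delta_top = m$median_top_mut - m$median_top_wt,
             delta_bot = m$median_bot_mut - m$median_bot_wt)
}
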