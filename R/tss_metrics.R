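#' Per-promoter TSS distribution from a stranded signal
#'
#' Counts are taken from the window's own strand only; relative
#' coordinates increase downstream regardless of genomic strand (on a
#' minus-strand promoter, genomic position `anchor - k` maps to
#' relative `+k`).
#'
#' @param signal A `stranded_signal` of 5'-end counts.
#' @param window One row of a `promoter_windows` table.
#' @return An object of class `tss_dist`: `promoter_id`, `rel`
#'   (relative coordinates), `counts`, `expression` (total reads).
#' @export
window_counts <- function(signal, window) {
  stopifnot(nrow(window) == 1)
  g <- window_genomic_positions(window, 1L)
  len <- signal$chrom_lengths[[window$chrom]]
  if (is.null(len)) stop("coordinate error: unknown chromosome ", window$chrom)
  if (min(g) < 0 || max(g) >= len)
    stop("coordinate error: window ", window$promoter_id, " off chromosome")
  counts <- signal_slice(signal, window$chrom, g, window$strand)
  structure(list(promoter_id = window$promoter_id,
                 rel = window_rel_coords(window, 1L),
                 counts = counts, expression = sum(counts)),
            class = "tss_dist")
}

#' Construct a TSS distribution directly from counts
#'
#' @param counts Non-negative counts per position.
#' @param rel Relative coordinates (default `0..n-1`), increasing
#'   downstream.
#' @param promoter_id Identifier.
#' @return A `tss_dist` object.
#' @export
tss_dist <- function(counts, rel = seq_along(counts) - 1L,
                     promoter_id = "p") {
  stopifnot(length(counts) == length(rel), all(counts >= 0))
  structure(list(promoter_id = promoter_id, rel = as.integer(rel),
                 counts = as.numeric(counts), expression = sum(counts)),
            class = "tss_dist")
}

#' @export
print.tss_dist <- function(x, ...) {
  cat("tss_dist ", x$promoter_id, ": ", x$expression, " reads over [",
      min(x$rel), ", ", max(x$rel), "]\n", sep = "")
  invisible(x)
}

#' Count matrix over a set of equally sized windows
#'
#' @param signal A `stranded_signal`.
#' @param windows A `promoter_windows` table whose rows share the same
#'   extents.
#' @return Numeric matrix (promoters x positions) with relative
#'   coordinates as column names and promoter ids as row names.
#' @export
window_count_matrix <- function(signal, windows) {
  stopifnot(length(unique(window_width(windows))) == 1)
  m <- t(vapply(seq_len(nrow(windows)), function(i) {
    window_counts(signal, windows[i, ])$counts
  }, numeric(window_width(windows)[1])))
  rownames(m) <- windows$promoter_id
  colnames(m) <- window_rel_coords(windows, 1L)
  m
}

#' Median TSS position of a distribution
#'
#' The smallest relative position (scanning upstream to downstream)
#' whose cumulative count reaches 50% of the window total. Ties go
#' upstream by construction. Undefined (NA) when the window holds no
#' reads.
#'
#' @param dist A `tss_dist`.
#' @return Relative position, or `NA` when expression is 0.
#' @export
median_tss <- function(dist) {
  if (dist$expression <= 0) return(NA_integer_)
  dist$rel[dir_quantile_index(dist$counts, 0.5)]
}

#' TSS spread of a distribution
#'
#' Distance between the directional 10th- and 90th-percentile TSS
#' positions (each the first position whose cumulative count reaches
#' the quantile), measuring the width of the TSS distribution.
#'
#' @param dist A `tss_dist`.
#' @return Spread in nt (>= 0), or `NA` when expression is 0.
#' @export
tss_spread <- function(dist) {
  if (dist$expression <= 0) return(NA_integer_)
  abs(dist$rel[dir_quantile_index(dist$counts, 0.9)] -
        dist$rel[dir_quantile_index(dist$counts, 0.1)])
}

#' Normalized TSS density
#' @param dist A `tss_dist`.
#' @return Counts divided by expression (sums to 1), or all-NA when
#'   expression is 0.
#' @export
norm_density <- function(dist) {
  if (dist$expression <= 0) return(rep(NA_real_, length(dist$counts)))
  dist$counts / dist$expression
}

#' Per-promoter TSS metric table
#'
#' @param signal A `stranded_signal`.
#' @param windows A `promoter_windows` table.
#' @return data.frame with `promoter_id`, `promoter_class`,
#'   `expression`, `median_pos`, `spread`.
#' @export
tss_metrics_table <- function(signal, windows) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    d <- window_counts(signal, windows[i, ])
    data.frame(promoter_id = d$promoter_id,
               promoter_class = windows$promoter_class[i],
               expression = d$expression,
               median_pos = median_tss(d),
               spread = tss_spread(d))
  })
  do.call(rbind, rows)
}

#' Build median-TSS-anchored windows from WT signal
#'
#' For each element-anchored window the WT median TSS is located, a
#' 401-nt window (200 up, 200 down) is centered on it, and the median
#' is recomputed once in the new window with the window re-centered
#' once — new TSSs revealed by the shift are accounted for exactly one
#' time, and no further passes are applied. Promoters with zero WT
#' reads are dropped (recorded in the `dropped` attribute). A display
#' extent of -250..+150 is recorded in attributes `display_up` /
#' `display_down`.
#'
#' @param signal_wt WT `stranded_signal` (anchoring is always on WT).
#' @param element_windows Element-anchored `promoter_windows`.
#' @param up_ext,down_ext Extensions of the new windows (defaults 200).
#' @return A `promoter_windows` table with `anchor_kind = "median_tss"`
#'   and 1-nt anchors.
#' @export
build_tss_anchored_windows <- function(signal_wt, element_windows,
                                       up_ext = 200L, down_ext = 200L) {
  keep <- logical(nrow(element_windows))
  anchors <- integer(nrow(element_windows))
  for (i in seq_len(nrow(element_windows))) {
    d0 <- window_counts(signal_wt, element_windows[i, ])
    if (d0$expression <= 0) next
    c1 <- rel_to_genomic_scalar(element_windows$anchor_pos[i],
                                element_windows$strand[i], median_tss(d0))
    w1 <- promoter_windows(element_windows$chrom[i],
                           element_windows$strand[i], c1, 1L,
                           up_ext, down_ext,
                           promoter_id = element_windows$promoter_id[i],
                           promoter_class = element_windows$promoter_class[i],
                           anchor_kind = "median_tss")
    d1 <- window_counts(signal_wt, w1)
    c2 <- rel_to_genomic_scalar(c1, element_windows$strand[i], median_tss(d1))
    anchors[i] <- c2
    keep[i] <- TRUE
  }
  out <- promoter_windows(element_windows$chrom[keep],
                          element_windows$strand[keep], anchors[keep], 1L,
                          up_ext, down_ext,
                          promoter_id = element_windows$promoter_id[keep],
                          promoter_class = element_windows$promoter_class[keep],
                          anchor_kind = "median_tss")
  attr(out, "dropped") <- element_windows$promoter_id[!keep]
  attr(out, "display_up") <- 250L
  attr(out, "display_down") <- 150L
  out
}

#' Median-TSS shift and spread change, mutant vs WT
#'
#' Sign convention: an upstream shift of the mutant median TSS is
#' negative, a downstream shift positive.
#'
#' @param dist_mut,dist_wt `tss_dist` objects over the same WT-anchored
#'   window.
#' @return One-row data.frame with `promoter_id`, `delta_median`,
#'   `delta_spread`, `defined`.
#' @export
shift_and_spread <- function(dist_mut, dist_wt) {
  ok <- dist_mut$expression > 0 && dist_wt$expression > 0
  data.frame(promoter_id = dist_wt$promoter_id,
             delta_median = if (ok) median_tss(dist_mut) - median_tss(dist_wt)
                            else NA_integer_,
             delta_spread = if (ok) tss_spread(dist_mut) - tss_spread(dist_wt)
                            else NA_integer_,
             defined = ok)
}

#' Per-promoter shift table, mutant vs WT
#'
#' @param signal_mut,signal_wt `stranded_signal`s.
#' @param windows WT-anchored `promoter_windows`.
#' @param min_expression Promoters below this WT expression are flagged
#'   `included = FALSE` (default 200 reads).
#' @return data.frame of [shift_and_spread()] rows plus `expression_wt`
#'   and `included`.
#' @export
shift_table <- function(signal_mut, signal_wt, windows,
                        min_expression = 200) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    dm <- window_counts(signal_mut, windows[i, ])
    dw <- window_counts(signal_wt, windows[i, ])
    r <- shift_and_spread(dm, dw)
    r$expression_wt <- dw$expression
    r
  })
  out <- do.call(rbind, rows)
  out$included <- out$defined & out$expression_wt >= min_expression
  out
}

#' Normalized usage difference, mutant minus WT
#'
#' Per-position difference of normalized densities over a common
#' relative span; each row sums to 0 for a valid pair.
#'
#' @param dist_mut,dist_wt `tss_dist`s on the same window.
#' @param span Relative span, default `c(-100, 100)`.
#' @return Named numeric vector over the span (all NA when either side
#'   is undefined).
#' @export
normalized_difference <- function(dist_mut, dist_wt, span = c(-100L, 100L)) {
  idx <- dist_wt$rel >= span[1] & dist_wt$rel <= span[2]
  out <- norm_density(dist_mut)[idx] - norm_density(dist_wt)[idx]
  names(out) <- dist_wt$rel[idx]
  out
}

#' Normalized-difference matrix over promoters
#'
#' @param signal_mut,signal_wt `stranded_signal`s.
#' @param windows WT-median-anchored `promoter_windows`.
#' @param span Relative span, default `c(-100, 100)`.
#' @return Matrix (promoters x positions); rows of undefined promoters
#'   are NA.
#' @export
normalized_difference_matrix <- function(signal_mut, signal_wt, windows,
                                         span = c(-100L, 100L)) {
  m <- t(vapply(seq_len(nrow(windows)), function(i) {
    normalized_difference(window_counts(signal_mut, windows[i, ]),
                          window_counts(signal_wt, windows[i, ]), span)
  }, numeric(span[2] - span[1] + 1L)))
  rownames(m) <- windows$promoter_id
  m
}

#' Base-by-base Pearson correlation between two libraries
#'
#' Only positions with at least `min_count` reads in BOTH libraries
#' enter the correlation (low-coverage positions dominate Pearson r
#' otherwise).
#'
#' @param signal_a,signal_b `stranded_signal`s on the same chromosomes.
#' @param scope `"genome"` (all positions, both strands) or
#'   `"windows"` (promoter-sense strand within `windows`).
#' @param windows Required when `scope = "windows"`.
#' @param min_count Per-library inclusion threshold (default 3).
#' @return List with `r`, `n_positions`; `r` is NA (flagged) with fewer
#'   than 2 qualifying positions.
#' @export
library_correlation <- function(signal_a, signal_b,
                                scope = c("genome", "windows"),
                                windows = NULL, min_count = 3) {
  scope <- match.arg(scope)
  if (scope == "genome") {
    a <- unlist(c(signal_a$plus, signal_a$minus), use.names = FALSE)
    b <- unlist(c(signal_b$plus, signal_b$minus), use.names = FALSE)
  } else {
    stopifnot(!is.null(windows))
    a <- unlist(lapply(seq_len(nrow(windows)), function(i)
      window_counts(signal_a, windows[i, ])$counts))
    b <- unlist(lapply(seq_len(nrow(windows)), function(i)
      window_counts(signal_b, windows[i, ])$counts))
  }
  keep <- a >= min_count & b >= min_count
  if (sum(keep) < 2)
    return(list(r = NA_real_, n_positions = sum(keep)))
  list(r = stats::cor(a[keep], b[keep]), n_positions = sum(keep))
}

#' Expression deciles over promoters
#'
#' Decile 1 holds the highest-expressed promoters, decile 10 the
#' lowest. Ties are broken by promoter id for determinism. With fewer
#' than 10 promoters, coarser quantiles are used with a warning.
#'
#' @param expression Numeric vector of total window reads.
#' @param promoter_id Matching identifiers.
#' @return Integer decile labels in input order.
#' @export
expression_deciles <- function(expression, promoter_id) {
  n <- length(expression)
  nq <- 10L
  if (n < 10) {
    warning("fewer than 10 promoters; using ", n, " quantile groups")
    nq <- max(1L, n)
  }
  ord <- order(-expression, promoter_id)
  rank_in <- integer(n)
  rank_in[ord] <- seq_len(n)
  as.integer(ceiling(rank_in * nq / n))
}
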