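#' Midpoint profile from a fragment table
#'
#' Midpoints follow the half-open convention `floor((s + e - 1) / 2)`.
#' A fragment length histogram is emitted for digestion QC;
#' non-positive-length fragments are rejected and counted.
#'
#' @param fragments Fragment table (`chrom`, `start`, `end`; 0-based
#'   half-open), e.g. from [read_fragments()] or [simulate_mnase()].
#' @param chrom_lengths Named chromosome lengths.
#' @return An object of class `midpoint_profile`: per-chromosome raw
#'   midpoint count vectors (`counts`), `length_hist`, `n_fragments`,
#'   `n_rejected`.
#' @export
midpoints_from_fragments <- function(fragments, chrom_lengths) {
  len <- fragments$end - fragments$start
  bad <- len <= 0
  fragments <- fragments[!bad, , drop = FALSE]
  counts <- lapply(chrom_lengths, numeric)
  mids <- floor((fragments$start + fragments$end - 1) / 2)
  for (ch in unique(fragments$chrom)) {
    idx <- fragments$chrom == ch
    tab <- rowsum(rep(1, sum(idx)), mids[idx])
    pos <- as.integer(rownames(tab)) + 1L
    ok <- pos >= 1 & pos <= chrom_lengths[[ch]]
    counts[[ch]][pos[ok]] <- counts[[ch]][pos[ok]] + tab[ok, 1]
  }
  structure(list(chrom_lengths = chrom_lengths, counts = counts,
                 length_hist = table(fragments$end - fragments$start),
                 n_fragments = nrow(fragments), n_rejected = sum(bad)),
            class = "midpoint_profile")
}

#' @export
print.midpoint_profile <- function(x, ...) {
  cat("midpoint_profile: ", x$n_fragments, " fragments (",
      x$n_rejected, " rejected) on ", length(x$counts),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Average chromosomal midpoint coverage
#'
#' Sum of raw midpoints divided by chromosome length, per chromosome
#' (never genome-pooled); used as the per-position read threshold for
#' peak qualification.
#'
#' @param profile A `midpoint_profile`.
#' @return Named numeric vector of reads/nt.
#' @export
chrom_average_coverage <- function(profile) {
  if (any(profile$chrom_lengths <= 0)) stop("zero-length chromosome")
  vapply(names(profile$counts), function(ch) {
    sum(profile$counts[[ch]]) / profile$chrom_lengths[[ch]]
  }, numeric(1))
}

#' Smooth midpoint profiles (uniform then triweight kernel)
#'
#' Raw midpoint counts are convolved with a uniform kernel of
#' half-width `uni_half` (default 5 nt each side) and then with a
#' normalized triweight kernel `w(d) ~ (1 - (d/(tri_half+1))^2)^3` of
#' half-width `tri_half` (default 75 nt each side). Both kernels sum
#' to 1, so total mass is conserved away from chromosome ends; the
#' composition order does not affect the result (symmetric FIR
#' kernels commute).
#'
#' @param profile A `midpoint_profile`.
#' @param tri_half,uni_half Kernel half-widths in nt.
#' @return The profile with a `smoothed` element added.
#' @export
smooth_midpoints <- function(profile, tri_half = 75L, uni_half = 5L) {
  wu <- kernel_uniform(uni_half)
  wt <- kernel_triweight(tri_half)
  profile$smoothed <- lapply(profile$counts, function(v) {
    convolve_kernel(convolve_kernel(v, wu), wt)
  })
  profile
}

## local maxima of a vector: s[i] > s[i-1] and s[i] >= s[i+1] (plateau
## ties resolved upstream), positive values only; returns 1-based idx
.local_maxima <- function(s) {
  n <- length(s)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[s[i] > s[i - 1] & s[i] >= s[i + 1] & s[i] > 0]
}

#' Call nucleosome peaks from a smoothed midpoint profile
#'
#' Local maxima of the smoothed profile; among maxima closer than
#' `min_dist` (150 nt) only the highest is retained (ties go
#' upstream), giving one peak per nucleosome. Every peak is annotated
#' with its raw midpoint coverage as a fraction of the chromosomal
#' average; peaks below `min_frac` are retained but flagged
#' (`passes = FALSE`) so both the +1 assignment rule and QC can see
#' them.
#'
#' @param profile A smoothed `midpoint_profile` (see
#'   [smooth_midpoints()]).
#' @param min_frac Qualification threshold on raw coverage relative to
#'   the chromosomal average (default 0.20).
#' @param min_dist Minimum peak spacing in nt (default 150).
#' @return data.frame with `chrom`, `pos` (0-based), `height`
#'   (smoothed), `raw`, `frac`, `passes`.
#' @export
call_peaks <- function(profile, min_frac = 0.20, min_dist = 150L) {
  stopifnot(!is.null(profile$smoothed))
  avg <- chrom_average_coverage(profile)
  rows <- list()
  for (ch in names(profile$counts)) {
    s <- profile$smoothed[[ch]]
    cand <- .local_maxima(s)
    if (!length(cand)) next
    ## greedy suppression: highest first, ties upstream
    ord <- cand[order(-s[cand], cand)]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(kept - i) >= min_dist))
        kept <- c(kept, i)
    }
    kept <- sort(kept)
    raw <- profile$counts[[ch]][kept]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, pos = kept - 1L, height = s[kept], raw = raw,
      frac = if (avg[[ch]] > 0) raw / avg[[ch]] else NA_real_,
      passes = avg[[ch]] > 0 & raw / avg[[ch]] >= min_frac)
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), pos = integer(0),
                      height = numeric(0), raw = numeric(0),
                      frac = numeric(0), passes = logical(0)))
  do.call(rbind, rows)
}

#' Assign the +1 nucleosome peak of a promoter
#'
#' The first called peak downstream of the promoter's median TSS that
#' passes the coverage threshold and lies within the plausible +1
#' range (`search_range`, default 0 < rel <= 300 nt downstream) is the
#' +1 nucleosome; undefined when none qualifies.
#'
#' @param peaks Peak table from [call_peaks()].
#' @param window One row of a median-TSS-anchored `promoter_windows`
#'   table (the anchor is the median TSS).
#' @param search_range Relative range `(lo, hi]` searched downstream.
#' @return List with `rel` and `pos` (0-based genomic), or both `NA`.
#' @export
assign_plus1 <- function(peaks, window, search_range = c(0L, 300L)) {
  p <- peaks[peaks$chrom == window$chrom & peaks$passes, , drop = FALSE]
  if (!nrow(p)) return(list(rel = NA_integer_, pos = NA_integer_))
  rel <- if (window$strand == "+") p$pos - window$anchor_pos
         else window$anchor_pos - p$pos
  ok <- rel > search_range[1] & rel <= search_range[2]
  if (!any(ok)) return(list(rel = NA_integer_, pos = NA_integer_))
  i <- which(ok)[which.min(rel[ok])]
  list(rel = rel[i], pos = p$pos[i])
}

#' +1 assignments for a set of promoters
#'
#' @param peaks Peak table from [call_peaks()].
#' @param windows Median-TSS-anchored `promoter_windows`.
#' @param search_range Passed to [assign_plus1()].
#' @return data.frame with `promoter_id`, `chrom`, `strand`,
#'   `plus1_rel`, `plus1_pos` (NA where unassigned).
#' @export
plus1_table <- function(peaks, windows, search_range = c(0L, 300L)) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    a <- assign_plus1(peaks, windows[i, ], search_range)
    data.frame(promoter_id = windows$promoter_id[i],
               chrom = windows$chrom[i], strand = windows$strand[i],
               plus1_rel = a$rel, plus1_pos = a$pos)
  })
  do.call(rbind, rows)
}

#' +1-anchored windows from +1 assignments
#'
#' Windows of `up + 1 + down` nt (1001 by default) anchored on the +1
#' nucleosome positions; promoters without a +1 call are skipped.
#'
#' @param plus1 Table from [plus1_table()].
#' @param windows The promoter windows the calls came from (supplies
#'   class labels).
#' @param up,down Extensions (defaults 500/500).
#' @return A `promoter_windows` table with `anchor_kind = "plus1_nuc"`.
#' @export
plus1_windows <- function(plus1, windows, up = 500L, down = 500L) {
  keep <- !is.na(plus1$plus1_pos)
  p <- plus1[keep, , drop = FALSE]
  cls <- windows$promoter_class[match(p$promoter_id, windows$promoter_id)]
  promoter_windows(p$chrom, p$strand, p$plus1_pos, 1L, up, down,
                   promoter_id = p$promoter_id, promoter_class = cls,
                   anchor_kind = "plus1_nuc")
}

#' Aggregate midpoint counts over oriented windows
#'
#' Sums the raw midpoint counts position-by-position across windows
#' (promoter orientation applied), optionally split by a grouping
#' vector (e.g. class x expression decile).
#'
#' @param profile A `midpoint_profile`.
#' @param windows A `promoter_windows` table with equal extents.
#' @param group Optional per-window grouping labels.
#' @return A named numeric vector over relative coordinates, or a list
#'   of such vectors per group.
#' @export
aggregate_midpoints <- function(profile, windows, group = NULL) {
  one <- function(rows) {
    rel <- window_rel_coords(rows, 1L)
    acc <- numeric(length(rel))
    for (i in seq_len(nrow(rows))) {
      g <- window_genomic_positions(rows, i)
      v <- profile$counts[[rows$chrom[i]]]
      ok <- g >= 0 & g < length(v)
      sl <- numeric(length(g)); sl[ok] <- v[g[ok] + 1L]
      acc <- acc + sl
    }
    stats::setNames(acc, rel)
  }
  if (is.null(group)) return(one(windows))
  lapply(split(seq_len(nrow(windows)), group),
         function(idx) one(windows[idx, , drop = FALSE]))
}

#' Nucleosome repeat length by autocorrelation
#'
#' Sample autocorrelation of an aggregate midpoint profile (typically
#' over windows spanning -200..+800 nt around the average +1
#' position), smoothed with a uniform kernel of half-width
#' `smooth_half` (5 nt) with truncated-kernel renormalization at the
#' lag boundaries. The NRL is the smallest positive lag that is a
#' local maximum of the smoothed autocorrelation with value above
#' `threshold` (0.05); `NA` when no such peak exists (e.g. white
#' noise or an all-zero profile).
#'
#' @param x Numeric aggregate profile.
#' @param max_lag Largest lag examined (default 400 nt).
#' @param smooth_half Uniform kernel half-width (default 5 nt).
#' @param threshold Minimum smoothed autocorrelation at the peak.
#' @return List with `nrl` (nt or NA), `acf` (raw), `smoothed`.
#' @export
autocorrelation_nrl <- function(x, max_lag = 400L, smooth_half = 5L,
                                threshold = 0.05) {
  if (all(x == 0) || stats::sd(x) == 0)
    return(list(nrl = NA_integer_, acf = NULL, smoothed = NULL))
  max_lag <- min(max_lag, length(x) - 2L)
  a <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                             demean = TRUE)$acf)
  ## unbiased per-lag normalization: the default (n-k)/n taper of the
  ## sample ACF drags periodic peaks toward shorter lags
  n <- length(x)
  a <- a * n / (n - 0:max_lag)
  s <- convolve_kernel(a, kernel_uniform(smooth_half), edge = "renorm")
  ## lag of index i is i - 1; search local maxima at positive lags
  cand <- .local_maxima_signed(s)
  cand <- cand[cand > 1 & s[cand] > threshold]
  if (!length(cand))
    return(list(nrl = NA_integer_, acf = a, smoothed = s))
  ## peak located on the smoothed function (outlier-robust), then
  ## refined to the raw-autocorrelation argmax within the kernel span
  ## (smoothing over a sloped background can drag a plateau edge by up
  ## to the kernel half-width)
  c0 <- min(cand)
  span <- max(2L, c0 - smooth_half):min(length(a), c0 + smooth_half)
  list(nrl = as.integer(span[which.max(a[span])] - 1L), acf = a,
       smoothed = s)
}

## local maxima allowing negative values (autocorrelation scale)
.local_maxima_signed <- function(s) {
  n <- length(s)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[s[i] > s[i - 1] & s[i] >= s[i + 1]]
}

#' Per-promoter +1 offsets of replicates against a WT reference
#'
#' For each promoter and replicate, the oriented offset (downstream
#' positive) of the replicate's +1 position from the WT reference +1;
#' reports the median offset and a two-sided sign test.
#'
#' @param calls_reps List of [plus1_table()] outputs, one per
#'   replicate.
#' @param wt_reference A [plus1_table()] output from the averaged WT
#'   profile.
#' @return List with `offsets` (data.frame `promoter_id`, `replicate`,
#'   `offset`), `median_offset`, `sign_p`.
#' @export
plus1_shift <- function(calls_reps, wt_reference) {
  rows <- list()
  for (r in seq_along(calls_reps)) {
    m <- merge(calls_reps[[r]], wt_reference, by = "promoter_id",
               suffixes = c("_rep", "_wt"))
    ok <- !is.na(m$plus1_pos_rep) & !is.na(m$plus1_pos_wt)
    m <- m[ok, , drop = FALSE]
    if (!nrow(m)) next
    off <- ifelse(m$strand_rep == "+",
                  m$plus1_pos_rep - m$plus1_pos_wt,
                  m$plus1_pos_wt - m$plus1_pos_rep)
    rows[[length(rows) + 1L]] <- data.frame(
      promoter_id = m$promoter_id, replicate = r, offset = off)
  }
  if (!length(rows))
    return(list(offsets = data.frame(promoter_id = character(0),
                                     replicate = integer(0),
                                     offset = integer(0)),
                median_offset = NA_real_, sign_p = NA_real_))
  off <- do.call(rbind, rows)
  nz <- off$offset[off$offset != 0]
  sign_p <- if (length(nz)) stats::binom.test(sum(nz > 0),
                                              length(nz))$p.value else 1
  list(offsets = off, median_offset = stats::median(off$offset),
       sign_p = sign_p)
}
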