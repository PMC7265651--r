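test_that("midpoint profiles conserve fragments and reject zero lengths", {
  fr <- data.frame(chrom = "chrI", start = c(100L, 300L, 300L, 50L),
                   end = c(247L, 447L, 447L, 50L))
  mp <- midpoints_from_fragments(fr, c(chrI = 1000L))
  expect_equal(mp$n_fragments, 3L)
  expect_equal(mp$n_rejected, 1L)
  expect_equal(sum(mp$counts$chrI), 3)
  expect_equal(mp$counts$chrI[174], 1)       # midpoint 173, 0-based
  expect_equal(mp$counts$chrI[374], 2)
  expect_equal(sum(mp$length_hist), 3L)
  empty <- midpoints_from_fragments(fr[0, ], c(chrI = 1000L))
  expect_equal(empty$n_fragments, 0L)
})

test_that("chromosomal average coverage is an exact per-chromosome ratio", {
  fr <- data.frame(chrom = rep("chrA", 1000),
                   start = rep(100L, 1000), end = rep(247L, 1000))
  mp <- midpoints_from_fragments(fr, c(chrA = 10000L, chrB = 5000L))
  avg <- chrom_average_coverage(mp)
  expect_equal(unname(avg["chrA"]), 0.1)
  expect_equal(unname(avg["chrB"]), 0)
})

test_that("kernel smoothing matches the brute-force convolution oracle", {
  set.seed(40)
  x <- rpois(400, 1)
  wu <- initscan:::kernel_uniform(5L)
  wt <- initscan:::kernel_triweight(75L)
  ours <- convolve_kernel(convolve_kernel(x, wu), wt)
  oracle <- oracle_convolve(oracle_convolve(x, wu), wt)
  expect_equal(ours, oracle, tolerance = 1e-9)
  ## kernels are normalized; smoothing conserves interior mass
  expect_equal(sum(wu), 1, tolerance = 1e-12)
  expect_equal(sum(wt), 1, tolerance = 1e-12)
  interior <- c(numeric(200), rpois(100, 3), numeric(200))
  expect_equal(sum(convolve_kernel(convolve_kernel(interior, wu), wt)),
               sum(interior), tolerance = 1e-6)
  ## a delta smooths to a symmetric hump peaked at the delta
  d <- numeric(301); d[151] <- 100
  s <- convolve_kernel(convolve_kernel(d, wu), wt)
  expect_equal(which.max(s), 151L)
  expect_equal(s[151 - 30], s[151 + 30], tolerance = 1e-12)
})

test_that("peak calling enforces 150-nt spacing and annotates coverage", {
  mk_profile <- function(pos, heights, len = 2000L) {
    cnt <- numeric(len)
    cnt[pos + 1L] <- heights
    p <- structure(list(chrom_lengths = c(chrI = len),
                        counts = list(chrI = cnt)),
                   class = "midpoint_profile")
    smooth_midpoints(p)
  }
  ## two deltas 300 nt apart: both called
  p <- mk_profile(c(500L, 800L), c(100, 100))
  pk <- call_peaks(p)
  expect_equal(pk$pos, c(500L, 800L))
  ## two deltas 100 nt apart: a single peak survives, at the higher one
  p2 <- mk_profile(c(500L, 600L), c(80, 120))
  pk2 <- call_peaks(p2)
  near <- pk2$pos[pk2$pos >= 420L & pk2$pos <= 680L]
  expect_equal(length(near), 1L)
  expect_lte(abs(near - 600L), 10L)
  ## brute-force check on well-separated deltas: every delta is a peak
  set.seed(41)
  pos <- sort(sample(seq(200L, 4800L, by = 200L), 8))
  p3 <- mk_profile(pos, rep(100, 8), len = 5000L)
  pk3 <- call_peaks(p3)
  expect_equal(pk3$pos, pos)
  ## a weak peak on a densely covered chromosome is reported but fails
  ## the 20%-of-average threshold (average ~30 reads/nt, peak raw 3)
  cnt <- c(rep(50, 600), numeric(400)); cnt[851] <- 3
  p4 <- structure(list(chrom_lengths = c(chrI = 1000L),
                       counts = list(chrI = cnt)),
                  class = "midpoint_profile")
  pk4 <- call_peaks(smooth_midpoints(p4))
  expect_true(850L %in% pk4$pos)
  expect_false(pk4$passes[pk4$pos == 850L])
  expect_true(any(pk4$passes))
})

test_that("+1 assignment takes the first qualifying downstream peak", {
  w <- toy_window(up = 200L, down = 400L)
  peaks <- data.frame(chrom = "chrI",
                      pos = w$anchor_pos + c(20L, 80L, 250L),
                      height = c(5, 3, 4), raw = c(1, 30, 30),
                      frac = c(0.1, 0.3, 0.3),
                      passes = c(FALSE, TRUE, TRUE))
  a <- assign_plus1(peaks, w)
  expect_equal(a$rel, 80L)                   # 20 fails the threshold
  ## qualifying peak upstream only -> undefined
  up <- data.frame(chrom = "chrI", pos = w$anchor_pos - 50L, height = 5,
                   raw = 30, frac = 0.3, passes = TRUE)
  expect_true(is.na(assign_plus1(up, w)$rel))
  ## no peaks -> undefined
  expect_true(is.na(assign_plus1(peaks[0, ], w)$rel))
  ## beyond the search range -> undefined
  farw <- data.frame(chrom = "chrI", pos = w$anchor_pos + 350L, height = 5,
                     raw = 30, frac = 0.3, passes = TRUE)
  expect_true(is.na(assign_plus1(farw, w, search_range = c(0L, 300L))$rel))
})

test_that("+1-anchored windows are 1001 nt and aggregation conserves counts", {
  prom <- small_promoters(n = 10, seed = 58)
  fr <- simulate_mnase(prom, jitter_sd = 0, depth = 100, seed = 42)
  mp <- midpoints_from_fragments(fr, nchar(prom$genome))
  p1 <- data.frame(promoter_id = prom$windows$promoter_id,
                   chrom = prom$windows$chrom,
                   strand = prom$windows$strand,
                   plus1_rel = 150L,
                   plus1_pos = initscan:::rel_to_genomic(prom$windows, 150L))
  p1w <- plus1_windows(p1, prom$windows)
  expect_equal(unique(initscan:::window_width(p1w)), 1001L)
  ## widen downstream to cover the whole 6-nucleosome array
  p1w_full <- plus1_windows(p1, prom$windows, up = 200L, down = 900L)
  agg <- aggregate_midpoints(mp, p1w_full)
  ## jitter-free arrays put all mass at k * nrl offsets
  expect_setequal(as.integer(names(agg)[agg > 0]), (0:5) * 165L)
  expect_equal(sum(agg), nrow(fr))
})

test_that("autocorrelation recovers periodicities from constructed profiles", {
  ## delta train with period 165
  x <- numeric(1001)
  x[seq(1, 1001, by = 165)] <- 50
  expect_equal(autocorrelation_nrl(x)$nrl, 165L)
  ## sinusoid with period 150
  s <- sin(2 * pi * (0:1000) / 150)
  expect_equal(autocorrelation_nrl(s)$nrl, 150L)
  ## all-zero profile is undefined
  expect_true(is.na(autocorrelation_nrl(numeric(500))$nrl))
  ## white noise rarely produces a confident repeat length
  set.seed(43)
  hits <- vapply(1:40, function(i) {
    !is.na(autocorrelation_nrl(rpois(1001, 2))$nrl)
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("NRL estimation recovers the planted repeat length from jittered arrays", {
  prom <- small_promoters(n = 50, seed = 59)
  fr <- simulate_mnase(prom, nrl = 165, jitter_sd = 10, n_nucs = 6,
                       depth = 400, seed = 44)
  mp <- midpoints_from_fragments(fr, nchar(prom$genome))
  p1w <- plus1_windows(
    data.frame(promoter_id = prom$windows$promoter_id,
               chrom = prom$windows$chrom, strand = prom$windows$strand,
               plus1_rel = 150L,
               plus1_pos = initscan:::rel_to_genomic(prom$windows, 150L)),
    prom$windows, up = 200L, down = 800L)
  agg <- aggregate_midpoints(mp, p1w)
  est <- autocorrelation_nrl(agg)
  expect_lte(abs(est$nrl - 165), 5)
})

test_that("replicate +1 offsets recover planted shifts and antisymmetry", {
  prom <- small_promoters(n = 20, seed = 60)
  base <- data.frame(promoter_id = prom$windows$promoter_id,
                     chrom = prom$windows$chrom,
                     strand = prom$windows$strand,
                     plus1_rel = 150L,
                     plus1_pos = initscan:::rel_to_genomic(prom$windows, 150L))
  shifted <- base
  shifted$plus1_pos <- initscan:::rel_to_genomic(prom$windows, 153L)
  ## identical data: all offsets zero
  r0 <- plus1_shift(list(base), base)
  expect_true(all(r0$offsets$offset == 0))
  ## planted +3 downstream shift
  r3 <- plus1_shift(list(shifted), base)
  expect_equal(r3$median_offset, 3)
  expect_lt(r3$sign_p, 0.01)
  ## antisymmetric under swapping mutant and WT
  rswap <- plus1_shift(list(base), shifted)
  expect_equal(rswap$median_offset, -3)
})
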