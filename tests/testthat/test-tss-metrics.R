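test_that("median TSS matches cumulative enumeration with upstream ties", {
  ## frozen: counts [1,2,3,4] at 0..3 -> position 2 (cumulative 6 >= 5)
  expect_equal(median_tss(tss_dist(c(1, 2, 3, 4))), 2L)
  ## frozen: counts [5,5] -> position 0 (tie goes upstream)
  expect_equal(median_tss(tss_dist(c(5, 5))), 0L)
  expect_equal(median_tss(tss_dist(c(0, 0, 7, 0))), 2L)
  set.seed(1)
  for (rep in 1:50) {
    cnt <- rpois(sample(3:30, 1), 2)
    if (sum(cnt) == 0) cnt[1] <- 1
    rel <- seq_along(cnt) - 17L
    d <- tss_dist(cnt, rel)
    expect_equal(median_tss(d), oracle_quantile_pos(cnt, rel, 0.5))
    expect_equal(tss_spread(d),
                 abs(oracle_quantile_pos(cnt, rel, 0.9) -
                       oracle_quantile_pos(cnt, rel, 0.1)))
  }
})

test_that("TSS spread matches the 10th-90th percentile distance", {
  ## frozen: 10 reads at each of positions 0..9 -> spread 8
  expect_equal(tss_spread(tss_dist(rep(10, 10))), 8L)
  expect_equal(tss_spread(tss_dist(c(0, 42, 0))), 0L)
})

test_that("zero-expression distributions yield undefined metrics", {
  d <- tss_dist(rep(0, 10))
  expect_true(is.na(median_tss(d)))
  expect_true(is.na(tss_spread(d)))
  expect_true(all(is.na(norm_density(d))))
})

test_that("metrics are translation-equivariant and scale-invariant", {
  set.seed(2)
  for (rep in 1:20) {
    cnt <- rpois(20, 3); cnt[1] <- cnt[1] + 1
    rel <- -5:14
    d <- tss_dist(cnt, rel)
    dk <- tss_dist(cnt, rel + 7L)        # shift downstream by 7
    expect_equal(median_tss(dk), median_tss(d) + 7L)
    expect_equal(tss_spread(dk), tss_spread(d))
    dc <- tss_dist(cnt * 13, rel)        # scale counts
    expect_equal(median_tss(dc), median_tss(d))
    expect_equal(tss_spread(dc), tss_spread(d))
    expect_equal(norm_density(dc), norm_density(d))
  }
})

test_that("window counts obey the orientation contract on both strands", {
  wm <- toy_window(strand = "-", up = 10L, down = 10L)
  ## reads at genomic anchor-3 on the minus strand -> relative +3
  sig <- stranded_signal(c(chrI = 2000))
  sig <- initscan:::signal_add(sig, "chrI", wm$anchor_pos - 3L, "-", 6)
  d <- window_counts(sig, wm)
  expect_equal(d$counts[d$rel == 3L], 6)
  expect_equal(d$expression, 6)
  ## reads on the opposite strand only -> expression 0
  sig2 <- stranded_signal(c(chrI = 2000))
  sig2 <- initscan:::signal_add(sig2, "chrI", wm$anchor_pos - 3L, "+", 6)
  expect_equal(window_counts(sig2, wm)$expression, 0)
  ## off-chromosome window errors
  bad <- promoter_windows("chrI", "+", 50L, 1L, 200L, 200L)
  expect_error(window_counts(sig, bad), "coordinate")
})

test_that("element windows are 408 nt and TSS windows 401 nt wide", {
  we <- promoter_windows("chrI", "+", 1000L, anchor_len = 8L)
  wt <- promoter_windows("chrI", "+", 1000L, anchor_len = 1L)
  expect_equal(length(initscan:::window_rel_coords(we, 1L)), 408L)
  expect_equal(length(initscan:::window_rel_coords(wt, 1L)), 401L)
})

test_that("TSS-anchored windows re-center exactly once", {
  we <- toy_window(anchor_len = 8L, up = 50L, down = 50L, kind = "element")
  ## all WT reads at one site: window centers there after one pass
  sig <- toy_signal(100, 30L, we)
  aw <- build_tss_anchored_windows(sig, we, up_ext = 50L, down_ext = 50L)
  expect_equal(aw$anchor_pos, we$anchor_pos + 30L)
  expect_equal(aw$anchor_len, 1L)
  ## reads beyond the element window edge: the second pass sees them,
  ## a third pass would move again but is not applied
  sig2 <- toy_signal(c(60, 41, 80), c(50L, 57L, 80L), we)
  aw2 <- build_tss_anchored_windows(sig2, we, up_ext = 40L, down_ext = 40L)
  ## pass 1 sees rel <= 57 only (median 50); pass 2 window 10..90 also
  ## sees the reads at 80, moving the median once
  cnt <- c(60, 41, 80); pos <- c(50L, 57L, 80L)
  in1 <- pos <= 57L
  c1 <- oracle_quantile_pos(cnt[in1], pos[in1], 0.5)
  in2 <- pos >= c1 - 40L & pos <= c1 + 40L
  c2 <- oracle_quantile_pos(cnt[in2], pos[in2], 0.5)
  expect_true(c2 != c1)
  expect_equal(aw2$anchor_pos, we$anchor_pos + c2)
  ## idempotent when all reads are interior
  aw3 <- build_tss_anchored_windows(sig, aw, up_ext = 50L, down_ext = 50L)
  expect_equal(aw3$anchor_pos, aw$anchor_pos)
  ## zero-read promoters are dropped and recorded
  empty <- stranded_signal(c(chrI = 2000))
  aw4 <- build_tss_anchored_windows(empty, we)
  expect_equal(nrow(aw4), 0L)
  expect_equal(attr(aw4, "dropped"), "p1")
})

test_that("shift results follow the polar sign convention", {
  w <- toy_window(up = 50L, down = 50L)
  wt <- toy_signal(c(10, 20, 10), c(-5L, 0L, 5L), w)
  identical_mut <- toy_signal(c(10, 20, 10), c(-5L, 0L, 5L), w)
  r0 <- shift_and_spread(window_counts(identical_mut, w),
                         window_counts(wt, w))
  expect_equal(r0$delta_median, 0L)
  expect_equal(r0$delta_spread, 0L)
  shifted <- toy_signal(c(10, 20, 10), c(-5L, 0L, 5L) + 5L, w)
  r5 <- shift_and_spread(window_counts(shifted, w), window_counts(wt, w))
  expect_equal(r5$delta_median, 5L)    # downstream positive
  expect_equal(r5$delta_spread, 0L)
})

test_that("normalized difference rows sum to zero and localize the shift", {
  w <- toy_window(up = 100L, down = 100L)
  wt <- toy_signal(c(30, 40, 30), c(-10L, 0L, 10L), w)
  mut <- toy_signal(c(30, 40, 30), c(-30L, -20L, -10L), w)  # upstream shift
  nd <- normalized_difference(window_counts(mut, w), window_counts(wt, w))
  expect_equal(sum(nd), 0, tolerance = 1e-9)
  expect_true(all(nd[c("-30", "-20")] > 0))
  expect_true(all(nd[c("0", "10")] < 0))
  same <- normalized_difference(window_counts(wt, w), window_counts(wt, w))
  expect_true(all(same == 0))
})

test_that("library correlation applies the 3-read threshold in both libraries", {
  w <- toy_window(up = 50L, down = 50L)
  a <- toy_signal(c(5, 10, 2, 100), c(0L, 1L, 2L, 3L), w)
  b <- toy_signal(c(6, 9, 100, 50), c(0L, 1L, 2L, 3L), w)
  r <- library_correlation(a, b, scope = "windows", windows = w)
  ## positions 2 (2 reads in a) is excluded; qualifying set is 0,1,3
  expect_equal(r$n_positions, 3L)
  expect_equal(r$r, cor(c(5, 10, 100), c(6, 9, 50)), tolerance = 1e-12)
  expect_equal(library_correlation(a, a, scope = "windows",
                                   windows = w)$r, 1.0)
  ## textbook-formula oracle on a 5-position toy
  x <- c(3, 7, 12, 5, 9); y <- c(4, 6, 15, 3, 10)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  aa <- toy_signal(x, 0:4, w); bb <- toy_signal(y, 0:4, w)
  expect_equal(library_correlation(aa, bb, scope = "windows",
                                   windows = w)$r, num / den,
               tolerance = 1e-12)
  ## under 2 qualifying positions -> undefined
  lo <- toy_signal(c(1, 1), 0:1, w)
  expect_true(is.na(library_correlation(lo, lo, scope = "windows",
                                        windows = w)$r))
})

test_that("expression deciles are descending, balanced and tie-stable", {
  expr <- seq(1000, 10, length.out = 100)
  ids <- sprintf("p%03d", 1:100)
  d <- expression_deciles(expr, ids)
  expect_equal(as.vector(table(d)), rep(10L, 10))
  expect_equal(d[which.max(expr)], 1L)
  expect_equal(d[which.min(expr)], 10L)
  ## all-equal expression: deterministic by id
  d2 <- expression_deciles(rep(5, 100), ids)
  expect_equal(d2, as.integer(ceiling(seq_len(100) / 10)))
  expect_warning(expression_deciles(1:5, letters[1:5]), "fewer")
})
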