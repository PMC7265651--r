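test_that("usage normalizes to 1 and is scale-invariant", {
  d <- tss_dist(c(50, 25, 25))
  expect_equal(tss_usage(d), c(0.5, 0.25, 0.25))
  set.seed(3)
  for (rep in 1:10) {
    cnt <- rpois(15, 2); cnt[3] <- cnt[3] + 1
    expect_equal(sum(tss_usage(tss_dist(cnt))), 1)
    expect_equal(tss_usage(tss_dist(cnt * 9)), tss_usage(tss_dist(cnt)))
  }
})

test_that("efficiency equals the suffix-sum oracle exactly", {
  ## frozen: counts [50,25,25] -> efficiencies [0.5, 0.5, 1.0]
  e <- tss_efficiency(tss_dist(c(50, 25, 25)))
  expect_equal(e$efficiency, c(0.5, 0.5, 1.0))
  set.seed(4)
  for (rep in 1:200) {
    cnt <- rpois(sample(2:40, 1), sample(1:4, 1))
    e <- tss_efficiency(tss_dist(cnt))
    expect_identical(e$efficiency, oracle_suffix_efficiency(cnt))
  }
})

test_that("the exclusion rule flags low-read high-efficiency positions", {
  ## 5 reads with 15 downstream: eff 0.25, excluded (<=5 reads, >=20%)
  e1 <- tss_efficiency(tss_dist(c(5, 10, 5)))
  expect_equal(e1$efficiency[1], 0.25)
  expect_true(e1$excluded[1])
  ## 6 reads with 18 downstream: eff 0.25, kept
  e2 <- tss_efficiency(tss_dist(c(6, 12, 6)))
  expect_equal(e2$efficiency[1], 0.25)
  expect_false(e2$excluded[1])
  ## trailing zero positions have undefined efficiency
  e3 <- tss_efficiency(tss_dist(c(10, 0, 0)))
  expect_true(all(is.na(e3$efficiency[2:3])))
  ## downstream-most position with reads has efficiency 1
  expect_equal(e3$efficiency[1], 1.0)
})

test_that("usage is reconstructed from efficiencies by the product chain", {
  set.seed(5)
  for (rep in 1:20) {
    cnt <- rpois(12, 5)
    if (sum(cnt) == 0) cnt[1] <- 1
    e <- tss_efficiency(tss_dist(cnt))$efficiency
    u <- tss_usage(tss_dist(cnt))
    ok <- !is.na(e)
    expect_equal(oracle_chain_usage(e[ok]), u[ok], tolerance = 1e-12)
  }
})

test_that("motif keys are read in promoter orientation on both strands", {
  ## + strand: A at -8, C at -1, A at +1 around tss_pos 50
  s <- paste(rep("G", 100), collapse = "")
  substr(s, 43, 43) <- "A"   # 0-based 42 = tss 50 - 8
  substr(s, 50, 50) <- "C"   # 0-based 49 = -1
  substr(s, 51, 51) <- "A"   # 0-based 50 = +1
  g <- c(chrT = s)
  expect_equal(extract_motif(g, "chrT", 50L, "+"), "ACA")
  ## - strand: reverse complement context gives the same key
  rc <- initscan:::revcomp(s)
  expect_equal(extract_motif(c(chrT = rc), "chrT", 49L, "-"), "ACA")
  ## N in context -> ambiguous
  substr(s, 43, 43) <- "N"
  expect_true(is.na(extract_motif(c(chrT = s), "chrT", 50L, "+")))
  ## out of bounds -> ambiguous
  expect_true(is.na(extract_motif(g, "chrT", 3L, "+")))
})

test_that("motif fractions sum to 1 and respond to activity changes", {
  prom <- small_promoters(n = 40, seed = 51)
  wt <- simulate_tss_reads(prom, scanning_params(depth = 3000, seed = 61))
  fr <- motif_usage_fractions(wt, prom$windows, prom$genome)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(length(fr), 65L)
  expect_identical(motif_usage_diff(fr, fr), fr - fr)
  ## all strong-site reads: single-key fraction 1 (constructed window)
  w1 <- toy_window(up = 20L, down = 20L)
  s <- paste(rep("G", 2000), collapse = "")
  ## plant ACA context at the anchor (rel 0, genomic 1000 0-based)
  substr(s, 993, 993) <- "A"; substr(s, 1000, 1000) <- "C"
  substr(s, 1001, 1001) <- "A"
  sig1 <- toy_signal(10, 0L, w1)
  fr1 <- motif_usage_fractions(sig1, w1, c(chrI = s))
  expect_equal(unname(fr1["ACA"]), 1)
})

test_that("faster polymerase depletes downstream strong-motif usage", {
  ## strong A(-8) sites planted downstream of weak sites: lambda = 2
  ## truncates scanning earlier, so A(-8)YR usage falls and B(-8)YR rises
  s <- paste(rep("G", 4000), collapse = "")
  g <- c(chrF = s)
  gv <- strsplit(s, "")[[1]]
  ## weak sites (C at -8) at rel 60, 75; strong (A at -8) at rel 120, 135
  anchor <- 2000L
  for (r in c(60L, 75L)) {
    gv[anchor + r - 8L + 1L] <- "C"; gv[anchor + r - 1L + 1L] <- "C"
    gv[anchor + r + 1L] <- "A"
  }
  for (r in c(120L, 135L)) {
    gv[anchor + r - 8L + 1L] <- "A"; gv[anchor + r - 1L + 1L] <- "C"
    gv[anchor + r + 1L] <- "A"
  }
  g <- c(chrF = paste(gv, collapse = ""))
  w <- promoter_windows("chrF", "+", anchor, 8L, 200L, 200L)
  prom <- structure(list(genome = g, windows = w,
                         specs = list(list())),
                    class = "synthetic_promoters")
  u1 <- expected_tss_usage(prom, scanning_params(activity_scale = 1))[[1]]
  u2 <- expected_tss_usage(prom, scanning_params(activity_scale = 2))[[1]]
  strong <- u1$rel %in% c(120L, 135L)
  expect_lt(sum(u2$usage[strong]), sum(u1$usage[strong]))
  expect_gt(sum(u2$usage[!strong]), sum(u1$usage[!strong]))
})

test_that("TSS ranks order by usage with upstream tie-breaking", {
  r <- rank_tss(tss_dist(c(10, 30, 20)))
  expect_equal(r$rel_pos, c(1L, 2L, 0L))
  tie <- rank_tss(tss_dist(c(10, 10)))
  expect_equal(tie$rel_pos[tie$rank == 1], 0L)
  single <- rank_tss(tss_dist(c(0, 9, 0)))
  expect_equal(nrow(single), 1L)
  expect_equal(single$rel_pos, 1L)
})

test_that("positional aggregates cover exactly the occupied cells", {
  w1 <- toy_window(up = 100L, down = 100L)
  s <- paste(rep("G", 2000), collapse = "")
  substr(s, 1003, 1003) <- "A"    # -8 of rel +10 (0-based 1002)
  substr(s, 1010, 1010) <- "C"    # -1 of rel +10
  substr(s, 1011, 1011) <- "A"    # +1 at rel +10
  g <- c(chrI = s)
  sig <- toy_signal(20, 10L, w1)
  tab <- positional_motif_aggregates(sig, w1, g, motif_subset = "ACA")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$rel_pos, 10L)
  expect_equal(tab$mean_usage, 1)
  expect_equal(tab$mean_eff, 1)
})

test_that("reduced activity flattens median efficiency profiles", {
  prom <- small_promoters(n = 40, seed = 52)
  p1 <- scanning_params(activity_scale = 1, depth = 5000, seed = 71)
  p05 <- scanning_params(activity_scale = 0.5, depth = 5000, seed = 72)
  s1 <- simulate_tss_reads(prom, p1)
  s05 <- simulate_tss_reads(prom, p05)
  anch <- build_tss_anchored_windows(s1, prom$windows)
  a1 <- positional_motif_aggregates(s1, anch, prom$genome)
  a05 <- positional_motif_aggregates(s05, anch, prom$genome)
  m <- merge(a1, a05, by = c("motif", "rel_pos"), suffixes = c("_1", "_05"))
  m <- m[m$n_eff_1 >= 5 & m$n_eff_05 >= 5 & !is.na(m$median_eff_1) &
           !is.na(m$median_eff_05), ]
  expect_gt(nrow(m), 10)
  ## efficiencies drop (or hold) for the bulk of occupied cells
  expect_gt(mean(m$median_eff_05 <= m$median_eff_1), 0.9)
})
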