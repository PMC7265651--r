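test_that("generated genomes match the requested GC content and are seeded", {
  g <- gen_genome(1, c(chrI = 10000), 0.38)
  bases <- strsplit(g[[1]], "")[[1]]
  expect_true(all(bases %in% c("A", "C", "G", "T")))
  expect_lt(abs(mean(bases %in% c("G", "C")) - 0.38), 0.02)
  expect_identical(gen_genome(1, c(chrI = 10000), 0.38), g)
  g0 <- gen_genome(2, c(chrI = 2000), 0)
  expect_true(all(strsplit(g0[[1]], "")[[1]] %in% c("A", "T")))
  expect_error(gen_genome(1, c(chrI = 10), 0.38), "length")
})

test_that("planted elements are recoverable at their planted offsets", {
  prom <- small_promoters(n = 30, seed = 5)
  w <- prom$windows
  for (k in seq_len(nrow(w))) {
    cls <- w$promoter_class[k]
    kind <- if (cls == "taf1_depleted") "tata_consensus" else "gae"
    hits <- scan_elements(prom$genome, w[k, ], kind)
    expect_true(0L %in% hits$offset)
    ## element sits 50-100 nt upstream of the first candidate TSS
    first <- prom$specs[[k]]$candidate_tss_offsets[1]
    expect_gte(first, 50L); expect_lte(first, 100L)
  }
})

test_that("a pure taf1_enriched mix plants no TATA (chance hits are flagged)", {
  g <- gen_genome(9, c(chrI = 100000), 0.38)
  prom <- gen_promoters(g, 15, class_mix = c(taf1_enriched = 1), seed = 9)
  expect_true(all(prom$windows$promoter_class == "taf1_enriched"))
  for (k in seq_len(15)) {
    hits <- scan_elements(prom$genome, prom$windows[k, ], "tata_consensus")
    if (nrow(hits) > 0) expect_true(prom$windows$chance_tata[k])
  }
})

test_that("promoter generation is deterministic and capacity-checked", {
  g <- gen_genome(4, c(chrI = 100000), 0.38)
  a <- gen_promoters(g, 10, seed = 3)
  b <- gen_promoters(g, 10, seed = 3)
  expect_identical(a$windows, b$windows)
  expect_identical(a$genome, b$genome)
  expect_error(gen_promoters(g, 5000, seed = 3), "capacity")
})

test_that("scanning usage follows the first-success product chain", {
  ## frozen expectation: p = [0.5, 0.5, 1.0] gives usage [0.5, 0.25, 0.25]
  expect_equal(initscan:::chain_usage(c(0.5, 0.5, 1.0)),
               c(0.5, 0.25, 0.25))
  set.seed(11)
  for (rep in 1:20) {
    p <- runif(sample(1:8, 1))
    expect_equal(initscan:::chain_usage(p), oracle_chain_usage(p))
  }
})

test_that("a single certain site receives all reads", {
  prom <- small_promoters(n = 5, seed = 21)
  ## single-candidate chain: p = 1 at the only site puts depth there
  u <- initscan:::chain_usage(1.0)
  expect_equal(u, 1.0)
  sig <- simulate_tss_reads(prom, scanning_params(depth = 1000, seed = 2))
  for (k in 1:5) {
    d <- window_counts(sig, prom$windows[k, ])
    expect_equal(d$expression, 1000)
  }
})

test_that("doubled activity shifts the expected cumulative median upstream", {
  prom <- small_promoters(n = 15, seed = 31)
  u1 <- expected_tss_usage(prom, scanning_params(activity_scale = 1))
  u2 <- expected_tss_usage(prom, scanning_params(activity_scale = 2))
  med <- function(u) u$rel[which(cumsum(u$usage) >= 0.5)[1]]
  m1 <- vapply(u1, med, numeric(1))
  m2 <- vapply(u2, med, numeric(1))
  expect_true(all(m2 <= m1))
  expect_true(any(m2 < m1))
})

test_that("simulated reads land on the promoter strand with exact depth", {
  prom <- small_promoters(n = 10, seed = 8)
  sig <- simulate_tss_reads(prom, scanning_params(depth = 500, seed = 3))
  w <- prom$windows
  for (k in seq_len(nrow(w))) {
    d <- window_counts(sig, w[k, ])
    expect_equal(d$expression, 500)
    ## opposite strand is empty in this window
    anti <- if (w$strand[k] == "+") "-" else "+"
    g <- initscan:::window_genomic_positions(w, k)
    expect_equal(sum(initscan:::signal_slice(sig, w$chrom[k], g, anti)), 0)
  }
  expect_identical(
    simulate_tss_reads(prom, scanning_params(depth = 500, seed = 3))$plus,
    sig$plus)
})

test_that("ChIP-exo borders land at their centers with zero spread", {
  prom <- small_promoters(n = 8, seed = 13)
  sig <- simulate_chipexo(prom, center_top = -60, center_bot = 20,
                          spread = 0, depth = 50, seed = 1)
  s <- chipexo_summaries(sig, prom$windows)
  expect_true(all(s$median_top == -60))
  expect_true(all(s$median_bot == 20))
  expect_error(simulate_chipexo(prom, spread = -1), "spread")
})

test_that("extended scanning shifts only the downstream border", {
  prom <- small_promoters(n = 30, seed = 14)
  a <- simulate_chipexo(prom, spread = 5, depth = 200, scan_extent = 0,
                        seed = 4)
  b <- simulate_chipexo(prom, spread = 5, depth = 200, scan_extent = 20,
                        seed = 5)
  sh <- chipexo_shift(chipexo_summaries(b, prom$windows),
                      chipexo_summaries(a, prom$windows))
  expect_equal(median(sh$delta_bot, na.rm = TRUE), 20, tolerance = 0.15)
  expect_lte(abs(median(sh$delta_top, na.rm = TRUE)), 2)
})

test_that("zero-depth promoters are excluded from medians, not errors", {
  prom <- small_promoters(n = 4, seed = 15)
  sig <- simulate_chipexo(prom, depth = c(0, 50, 50, 50), spread = 0,
                          seed = 2)
  s <- chipexo_summaries(sig, prom$windows)
  expect_true(is.na(s$median_top[1]))
  expect_true(all(!is.na(s$median_top[-1])))
})

test_that("jitter-free nucleosome arrays give exactly spaced midpoints", {
  prom <- small_promoters(n = 3, seed = 16)
  fr <- simulate_mnase(prom, nrl = 165, plus1_offset = 150, jitter_sd = 0,
                       n_nucs = 5, depth = 200, seed = 6)
  w <- prom$windows
  for (k in 1:3) {
    rel <- if (w$strand[k] == "+") fr$midpoint[fr$chrom == w$chrom[k]] - w$anchor_pos[k]
           else w$anchor_pos[k] - fr$midpoint[fr$chrom == w$chrom[k]]
    rel <- rel[rel >= 0 & rel <= 150 + 4 * 165]
    expect_setequal(unique(rel), 150 + (0:4) * 165)
  }
  expect_equal(nrow(simulate_mnase(prom, depth = 0, seed = 1)), 0L)
  expect_error(simulate_mnase(prom, jitter_sd = -2), "jitter")
})
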