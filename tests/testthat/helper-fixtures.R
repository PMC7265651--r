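## In-code fixtures: small signals, windows and promoter sets built at
## test time (no data files).

## a single window on a 2000-nt chromosome, anchor at 1000
toy_window <- function(strand = "+", anchor_len = 1L, up = 200L,
                       down = 200L, class = "neither",
                       kind = "median_tss", id = "p1") {
  promoter_windows("chrI", strand, 1000L, anchor_len, up, down,
                   promoter_id = id, promoter_class = class,
                   anchor_kind = kind)
}

## signal holding `counts` at the oriented positions `rel` of `window`
toy_signal <- function(counts, rel, window, chrom_len = 2000L,
                       strand_override = NULL) {
  sig <- stranded_signal(c(chrI = chrom_len))
  st <- strand_override %||% window$strand
  gpos <- if (window$strand == "+") window$anchor_pos + rel
          else window$anchor_pos - rel
  initscan:::signal_add(sig, "chrI", gpos, st, counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## small seeded synthetic promoter set shared across tests
small_promoters <- function(n = 20L, seed = 42L, chrom_len = 150000L) {
  g <- gen_genome(substream_seed(seed, 1), c(chrI = chrom_len), 0.38)
  gen_promoters(g, n, seed = substream_seed(seed, 2))
}
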