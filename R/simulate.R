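#' All 64 three-base initiation motif keys
#'
#' Keys are the bases at positions -8, -1 and +1 relative to a TSS
#' (+1 = the TSS itself), read on the promoter strand and concatenated,
#' e.g. `"ACA"` for A at -8, C at -1, A at +1.
#'
#' @return Character vector of the 64 keys in lexicographic order.
#' @export
all_motif_keys <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Default per-motif initiation probabilities
#'
#' Qualitative shape of initiation preference: TSSs need a pyrimidine at
#' -1 and a purine at +1 (Y-1R+1), and an A at -8 strengthens
#' initiation. Keys violating Y-1R+1 get probability `p_other`
#' (default 0). The exact values are simulator configuration, not
#' measured constants.
#'
#' @param p_strong Probability for A(-8)Y(-1)R(+1) sites.
#' @param p_weak Probability for B(-8)Y(-1)R(+1) sites (B = C/G/T).
#' @param p_other Probability for non-Y(-1)R(+1) positions.
#' @return Named numeric vector over the 64 motif keys.
#' @export
default_motif_probs <- function(p_strong = 0.25, p_weak = 0.08, p_other = 0) {
  keys <- all_motif_keys()
  m8 <- substr(keys, 1, 1); m1 <- substr(keys, 2, 2); p1 <- substr(keys, 3, 3)
  yr <- m1 %in% c("C", "T") & p1 %in% c("A", "G")
  p <- ifelse(yr & m8 == "A", p_strong, ifelse(yr, p_weak, p_other))
  stats::setNames(p, keys)
}

#' Scanning-model ("shooting gallery") simulation parameters
#'
#' The generative model: a pre-initiation complex assembles near the
#' core-promoter element and scans downstream from
#' `scan_start_offset`. At each candidate TSS i (ordered
#' upstream to downstream) it initiates with probability
#' `p_i = clamp(activity_scale * motif_base_prob[motif_i] *
#' processivity^dist_i, 0, 1)` where `dist_i` is the distance scanned,
#' else continues. Expected usage is the product chain
#' `u_i = p_i * prod_{j<i}(1 - p_j)`. Polymerases that scan past every
#' candidate are dropped (observed reads are conditioned on
#' initiation), and `depth` reads are drawn multinomially from the
#' renormalized usage vector.
#'
#' @param motif_base_prob Named probability vector over the 64 motif
#'   keys ([default_motif_probs()]).
#' @param activity_scale Catalytic-activity multiplier (lambda); 1 = WT,
#'   >1 models hyperactive (upstream-shifting) and <1 hypoactive
#'   (downstream-shifting) polymerase.
#' @param processivity Per-nucleotide scanning survival probability in
#'   (0, 1]; 1 = no distance penalty.
#' @param scan_start_offset nt downstream of the window anchor at which
#'   scanning begins.
#' @param depth Reads emitted per promoter.
#' @param seed Integer seed.
#' @return A list of class `scanning_params`.
#' @export
scanning_params <- function(motif_base_prob = default_motif_probs(),
                            activity_scale = 1, processivity = 1,
                            scan_start_offset = 25L, depth = 10000L,
                            seed = 1L) {
  stopifnot(all(motif_base_prob >= 0), all(motif_base_prob <= 1),
            activity_scale > 0,
            processivity > 0, processivity <= 1,
            depth >= 1)
  structure(list(motif_base_prob = motif_base_prob,
                 activity_scale = activity_scale,
                 processivity = processivity,
                 scan_start_offset = as.integer(scan_start_offset),
                 depth = as.integer(depth), seed = as.integer(seed)),
            class = "scanning_params")
}

#' Generate a random genome
#'
#' @param seed Integer seed.
#' @param chrom_lengths Named (or unnamed; names generated) integer
#'   vector of lengths, each at least 1000.
#' @param gc_fraction Expected G+C fraction in `[0, 1]`.
#' @return Named character vector of sequences.
#' @export
gen_genome <- function(seed, chrom_lengths, gc_fraction = 0.38) {
  if (any(chrom_lengths < 1000)) stop("invalid argument: chromosome length < 1000")
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  with_seed(seed, {
    vapply(chrom_lengths, function(n) {
      paste(sample(names(probs), n, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
}

## write `s` into the genome in promoter orientation starting at rel 0
## = 0-based genomic pos0 and extending downstream
plant_oriented <- function(genome, chrom, pos0, strand, s) {
  n <- nchar(s)
  if (strand == "+") {
    substr(genome[[chrom]], pos0 + 1L, pos0 + n) <- s
  } else {
    substr(genome[[chrom]], pos0 - n + 2L, pos0 + 1L) <- revcomp(s)
  }
  genome
}

## one random TATA consensus instance TATAWAWR (W = A/T, R = A/G)
.random_tata <- function() {
  paste0("TATA", sample(c("A", "T"), 1), "A", sample(c("A", "T"), 1),
         sample(c("A", "G"), 1))
}

#' Generate synthetic promoters on a genome
#'
#' Places `n` non-overlapping promoters (evenly spaced, strands chosen
#' at random) and edits the genome so each promoter carries the
#' architecture of its class: `taf1_depleted` promoters get a TATA
#' consensus (TATAWAWR) instance at the window anchor, `taf1_enriched`
#' promoters a GA-rich element (GAAAAA). Candidate TSSs — Y(-1)R(+1)
#' dinucleotides with a strong (A) or weak (C/G/T) -8 base — are
#' planted 50–100 nt downstream of the element, i.e. the element sits
#' 50–100 nt upstream of the first candidate TSS, with subsequent sites
#' every 9–15 nt.
#'
#' @param genome Named character vector from [gen_genome()].
#' @param n Number of promoters (>= 1).
#' @param class_mix Named proportions over promoter classes.
#' @param seed Integer seed.
#' @param up_ext,down_ext Window extensions (defaults 200/200; the
#'   element anchor is 8 nt, giving 408-nt windows).
#' @param n_sites_range Range of candidate-TSS counts per promoter.
#' @param first_tss_range Offset range (nt downstream of the anchor
#'   start) of the first candidate TSS.
#' @param site_spacing_range Range of spacings between candidate TSSs.
#' @param strong_m8_frac Fraction of candidate sites given an A at -8.
#' @return A list of class `synthetic_promoters` with elements
#'   `genome` (edited sequences), `windows` (a `promoter_windows`
#'   table with a `chance_tata` flag column), and `specs` (per-promoter
#'   planted-element and candidate-offset records).
#' @export
gen_promoters <- function(genome, n,
                          class_mix = c(taf1_enriched = 0.5,
                                        taf1_depleted = 0.5),
                          seed = 1L, up_ext = 200L, down_ext = 200L,
                          n_sites_range = c(6L, 12L),
                          first_tss_range = c(50L, 100L),
                          site_spacing_range = c(9L, 15L),
                          strong_m8_frac = 0.5) {
  stopifnot(n >= 1, abs(sum(class_mix) - 1) < 1e-9)
  anchor_len <- 8L
  ## slot size leaves room downstream of every anchor for a full phased
  ## nucleosome array (+1 at ~150 plus 5 repeats of ~165 nt) and
  ## upstream for +1-anchored +/-500 aggregation windows
  margin <- 1200L
  footprint <- up_ext + anchor_len + down_ext + margin
  lens <- nchar(genome)
  capacity <- sum(pmax(0, (lens - 200) %/% footprint))
  if (capacity < n)
    stop("capacity error: genome too small for ", n, " non-overlapping promoters")
  ## allocate promoters to chromosomes proportionally, deterministic
  per <- pmax(0, (lens - 200) %/% footprint)
  alloc <- integer(length(per))
  i <- 1L
  for (k in seq_len(n)) {
    while (alloc[i] >= per[i]) i <- i %% length(per) + 1L
    alloc[i] <- alloc[i] + 1L
    i <- i %% length(per) + 1L
  }
  ## edit chromosomes as character vectors (string replacement would
  ## copy the whole chromosome per planted base)
  gv <- lapply(genome, function(s) strsplit(s, "")[[1]])
  plant_chars <- function(ch, pos0, strand, s) {
    b <- strsplit(s, "")[[1]]
    if (strand == "+") gv[[ch]][pos0 + seq_along(b)] <<- b
    else gv[[ch]][pos0 + 2L - seq_along(b)] <<- unname(
      c(A = "T", C = "G", G = "C", T = "A")[b])
  }
  with_seed(seed, {
    chroms <- character(0); anchors <- integer(0); strands <- character(0)
    for (ci in seq_along(genome)) {
      if (alloc[ci] == 0) next
      starts <- 100L + (seq_len(alloc[ci]) - 1L) * footprint
      chroms <- c(chroms, rep(names(genome)[ci], alloc[ci]))
      st <- sample(c("+", "-"), alloc[ci], replace = TRUE)
      strands <- c(strands, st)
      ## anchor 500 nt into the slot from the upstream side, so the
      ## downstream array region stays inside the slot on either strand
      a <- ifelse(st == "+", starts + 500L, starts + footprint - 500L)
      anchors <- c(anchors, as.integer(a))
    }
    classes <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
    specs <- vector("list", n)
    for (k in seq_len(n)) {
      ch <- chroms[k]; a <- anchors[k]; st <- strands[k]
      cls <- classes[k]
      planted <- list()
      if (cls == "taf1_depleted") {
        el <- .random_tata()
        plant_chars(ch, a, st, el)
        planted <- c(planted, list(list(kind = "tata_consensus", offset = 0L,
                                        seq = el)))
      } else if (cls == "taf1_enriched") {
        plant_chars(ch, a, st, "GAAAAA")
        planted <- c(planted, list(list(kind = "gae", offset = 0L,
                                        seq = "GAAAAA")))
      }
      n_sites <- sample(n_sites_range[1]:n_sites_range[2], 1)
      first <- sample(first_tss_range[1]:first_tss_range[2], 1)
      offs <- first + c(0L, cumsum(sample(
        site_spacing_range[1]:site_spacing_range[2], n_sites - 1L,
        replace = TRUE)))
      offs <- offs[offs <= anchor_len - 1L + down_ext - 1L]
      for (r in offs) {
        m8 <- if (stats::runif(1) < strong_m8_frac) "A" else sample(c("C", "G", "T"), 1)
        m1 <- sample(c("C", "T"), 1)
        p1 <- sample(c("A", "G"), 1)
        plant_chars(ch, rel_to_genomic_scalar(a, st, r - 8L), st, m8)
        plant_chars(ch, rel_to_genomic_scalar(a, st, r - 1L), st, m1)
        plant_chars(ch, rel_to_genomic_scalar(a, st, r), st, p1)
      }
      specs[[k]] <- list(promoter_class = cls, planted_elements = planted,
                         candidate_tss_offsets = offs)
    }
    genome <- vapply(gv, paste, character(1), collapse = "")
    windows <- promoter_windows(chroms, strands, anchors, anchor_len,
                                up_ext, down_ext,
                                promoter_class = classes,
                                anchor_kind = "element")
    ## flag chance TATA consensus occurrences (not planted at offset 0)
    windows$chance_tata <- vapply(seq_len(n), function(k) {
      hits <- scan_elements(genome, windows[k, ], "tata_consensus")
      any(hits$offset != 0L)
    }, logical(1))
    structure(list(genome = genome, windows = windows, specs = specs),
              class = "synthetic_promoters")
  })
}

## scalar rel -> genomic helper used during planting
rel_to_genomic_scalar <- function(anchor_pos, strand, rel) {
  if (strand == "+") anchor_pos + rel else anchor_pos - rel
}

#' @export
print.synthetic_promoters <- function(x, ...) {
  cat("synthetic_promoters: ", nrow(x$windows), " promoters on ",
      length(x$genome), " chromosome(s)\n", sep = "")
  print(table(x$windows$promoter_class))
  invisible(x)
}

## candidate TSSs and their initiation probabilities for one window:
## every position in the scan region whose motif has base prob > 0
scan_candidates <- function(genome, window_row, params) {
  rel_max <- window_row$anchor_len + window_row$down_ext - 1L
  rels <- seq.int(params$scan_start_offset, rel_max)
  lo <- params$scan_start_offset - 8L
  ch <- oriented_chars(genome, window_row$chrom, window_row$anchor_pos,
                       window_row$strand, lo, rel_max)
  idx <- rels - lo + 1L
  keys <- paste0(ch[idx - 8L], ch[idx - 1L], ch[idx])
  keys[is.na(ch[idx - 8L]) | is.na(ch[idx - 1L]) | is.na(ch[idx])] <-
    NA_character_
  base_p <- ifelse(is.na(keys), 0,
                   unname(params$motif_base_prob[keys]))
  base_p[is.na(base_p)] <- 0
  keep <- base_p > 0
  dist <- rels[keep] - params$scan_start_offset
  p <- clamp01(params$activity_scale * base_p[keep] *
                 params$processivity^dist)
  list(rel = rels[keep], p = p)
}

## expected usage chain u_i = p_i * prod_{j<i}(1 - p_j)
chain_usage <- function(p) {
  if (!length(p)) return(numeric(0))
  surv <- cumprod(c(1, 1 - p))[seq_along(p)]
  p * surv
}

#' Simulate TSS-seq reads under the scanning model
#'
#' For each promoter, candidate TSSs are the Y(-1)R(+1)-compatible
#' positions in the scan region (any position whose motif has nonzero
#' configured probability). Expected usage follows the first-success
#' product chain; the residual probability of scanning past all
#' candidates is dropped and `depth` reads are drawn multinomially from
#' the renormalized usage, so reads are conditioned on initiation.
#' Counts are written at the TSS positions on the promoter's strand.
#'
#' @param promoters A `synthetic_promoters` object.
#' @param params A `scanning_params` object.
#' @param library_id Identifier for the output signal.
#' @return A `stranded_signal` of 5'-end counts.
#' @export
simulate_tss_reads <- function(promoters, params,
                               library_id = sprintf("tss_lambda%g",
                                                    params$activity_scale)) {
  w <- promoters$windows
  chrom_lengths <- nchar(promoters$genome)
  sig <- stranded_signal(chrom_lengths, library_id)
  with_seed(params$seed, {
    for (k in seq_len(nrow(w))) {
      cand <- scan_candidates(promoters$genome, w[k, ], params)
      if (!length(cand$p)) {
        warning("promoter ", w$promoter_id[k],
                ": no candidate TSSs; emitted zero reads")
        next
      }
      u <- chain_usage(cand$p)
      if (sum(u) <= 0) next
      counts <- stats::rmultinom(1, params$depth, u / sum(u))[, 1]
      nz <- counts > 0
      gpos <- rel_to_genomic_scalar(w$anchor_pos[k], w$strand[k], cand$rel[nz])
      sig <- signal_add(sig, w$chrom[k], gpos, w$strand[k], counts[nz])
    }
  })
  sig
}

#' Expected (infinite-depth) TSS usage for each promoter
#'
#' Deterministic companion to [simulate_tss_reads()]: returns per
#' promoter the candidate relative positions, their initiation
#' probabilities, and the renormalized expected usage.
#'
#' @inheritParams simulate_tss_reads
#' @return A list per promoter with `rel`, `p` and `usage` (summing
#'   to 1 when candidates exist).
#' @export
expected_tss_usage <- function(promoters, params) {
  w <- promoters$windows
  lapply(seq_len(nrow(w)), function(k) {
    cand <- scan_candidates(promoters$genome, w[k, ], params)
    u <- chain_usage(cand$p)
    list(rel = cand$rel, p = cand$p,
         usage = if (sum(u) > 0) u / sum(u) else u)
  })
}

#' Simulate ChIP-exo border signal around PIC assembly points
#'
#' Emulates the two exonuclease borders flanking a bound factor: reads
#' on the promoter-sense ("top") strand pile up at the upstream border
#' and reads on the anti-sense ("bottom") strand at the downstream
#' border, each as a discretized Gaussian. `scan_extent` shifts the
#' downstream border only, emulating mutants with extended scanning.
#'
#' @param promoters A `synthetic_promoters` object.
#' @param center_top,center_bot Border centers in promoter-relative nt.
#' @param spread Gaussian SD in nt (>= 0; 0 puts all reads at the
#'   center).
#' @param depth Reads per strand per promoter (scalar or per-promoter
#'   vector; 0 gives an empty promoter, not an error).
#' @param scan_extent Additive shift of the downstream border.
#' @param seed Integer seed.
#' @param library_id Identifier.
#' @return A `stranded_signal`; the "top" border is on each promoter's
#'   sense strand and the "bottom" border on the opposite strand.
#' @export
simulate_chipexo <- function(promoters, center_top = -40, center_bot = 40,
                             spread = 8, depth = 200, scan_extent = 0,
                             seed = 1L, library_id = "chipexo") {
  if (spread < 0) stop("invalid argument: negative spread")
  w <- promoters$windows
  depth <- rep_len(depth, nrow(w))
  sig <- stranded_signal(nchar(promoters$genome), library_id)
  cb <- center_bot + scan_extent
  with_seed(seed, {
    for (k in seq_len(nrow(w))) {
      if (depth[k] <= 0) next
      rel_top <- round(stats::rnorm(depth[k], center_top, spread))
      rel_bot <- round(stats::rnorm(depth[k], cb, spread))
      anti <- if (w$strand[k] == "+") "-" else "+"
      sig <- signal_add(sig, w$chrom[k],
                        rel_to_genomic_scalar(w$anchor_pos[k], w$strand[k],
                                              rel_top),
                        w$strand[k], 1)
      sig <- signal_add(sig, w$chrom[k],
                        rel_to_genomic_scalar(w$anchor_pos[k], w$strand[k],
                                              rel_bot),
                        anti, 1)
    }
  })
  sig
}

#' Simulate MNase-seq fragments from phased nucleosome arrays
#'
#' For each promoter, fragment midpoints are drawn around
#' `plus1_offset + k * nrl` (k = 0..n_nucs-1, promoter-relative) with
#' Gaussian jitter; fragment lengths are drawn around 147 nt.
#'
#' @param promoters A `synthetic_promoters` object.
#' @param nrl Nucleosome repeat length in nt (> 0).
#' @param plus1_offset +1 nucleosome dyad offset downstream of the
#'   window anchor (scalar or per-promoter vector).
#' @param jitter_sd Positional jitter SD in nt (>= 0).
#' @param n_nucs Nucleosomes per array (>= 1).
#' @param depth Fragments per promoter (0 gives an empty table).
#' @param len_mean,len_sd Fragment length distribution (nt).
#' @param seed Integer seed.
#' @return A fragment table (`chrom`, `start`, `end`, `length`,
#'   `midpoint`; 0-based half-open).
#' @export
simulate_mnase <- function(promoters, nrl = 165, plus1_offset = 150,
                           jitter_sd = 10, n_nucs = 6L, depth = 500L,
                           len_mean = 147, len_sd = 0, seed = 1L) {
  if (jitter_sd < 0) stop("invalid argument: negative jitter_sd")
  stopifnot(nrl > 0, n_nucs >= 1)
  w <- promoters$windows
  plus1_offset <- rep_len(plus1_offset, nrow(w))
  depth <- rep_len(depth, nrow(w))
  out <- vector("list", nrow(w))
  with_seed(seed, {
    for (k in seq_len(nrow(w))) {
      if (depth[k] <= 0) next
      nuc <- sample.int(n_nucs, depth[k], replace = TRUE) - 1L
      rel_mid <- plus1_offset[k] + nuc * nrl +
        round(stats::rnorm(depth[k], 0, jitter_sd))
      len <- pmax(50L, as.integer(round(stats::rnorm(depth[k], len_mean,
                                                     len_sd))))
      gmid <- rel_to_genomic_scalar(w$anchor_pos[k], w$strand[k], rel_mid)
      start0 <- gmid - (len - 1L) %/% 2L
      keep <- start0 >= 0 & start0 + len <= nchar(promoters$genome[[w$chrom[k]]])
      out[[k]] <- fragment_table(rep(w$chrom[k], sum(keep)),
                                 start0[keep], (start0 + len)[keep])
    }
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(fragment_table(character(0), integer(0), integer(0))[0, ])
  do.call(rbind, out)
}
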