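#' Default pipeline configuration
#'
#' Every analysis parameter defaults to its literature-standard value:
#' 200-nt window extensions (408-nt element windows, 401-nt TSS
#' windows), the 3-read correlation threshold, the 20%-efficiency /
#' 5-read exclusion rule, 150-nt peak spacing, the 20% chromosomal
#' coverage fraction, the 0.05 autocorrelation peak threshold, and
#' +/-500-nt +1-anchored windows. Simulator parameters (motif
#' probabilities, activity scales, border centers, array geometry) are
#' model configuration; see the package vignette for rationale.
#'
#' @param seed Root seed; all stage randomness is derived from it via
#'   named sub-streams.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "tss", "motif", "chipexo", "nuc"),
    genome = list(chrom_lengths = c(chrI = 400000L), gc_fraction = 0.38),
    promoters = list(n = 200L,
                     class_mix = c(taf1_enriched = 0.5, taf1_depleted = 0.5),
                     up_ext = 200L, down_ext = 200L),
    scanning = list(strains = c(wt = 1, fast = 2, slow = 0.5),
                    p_strong = 0.25, p_weak = 0.08,
                    processivity = 1, scan_start_offset = 25L,
                    depth = 10000L),
    chipexo = list(center_top = -40, center_bot = 40, spread = 8,
                   depth = 200L, scan_extent_mut = 20),
    mnase = list(nrl = 165, plus1_offset = 150, jitter_sd = 10,
                 n_nucs = 6L, depth = 500L),
    analysis = list(min_expression = 200, corr_min_count = 3,
                    eff_min = 0.20, eff_max_reads = 5,
                    peak_min_dist = 150L, peak_min_frac = 0.20,
                    acf_threshold = 0.05, plus1_search = c(0L, 300L),
                    plus1_win = 500L, ndm_span = c(-100L, 100L))
  )
}

#' Validate a pipeline configuration
#'
#' @param config Nested configuration list (see [default_config()]),
#'   or a path to a YAML file holding one (merged over the defaults).
#' @return The validated (merged) configuration.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config error at 'config': no such file ", config)
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  }
  need <- function(path, test) {
    parts <- strsplit(path, "$", fixed = TRUE)[[1]]
    v <- config
    for (p in parts) {
      if (is.null(v[[p]])) stop("config error at '", path, "': missing")
      v <- v[[p]]
    }
    if (!test(v)) stop("config error at '", path, "': invalid value")
    invisible(v)
  }
  need("seed", function(v) is.numeric(v) && length(v) == 1)
  need("genome$chrom_lengths", function(v) all(v >= 1000))
  need("genome$gc_fraction", function(v) v >= 0 && v <= 1)
  need("promoters$n", function(v) v >= 1)
  need("scanning$strains", function(v) "wt" %in% names(v) && all(v > 0))
  need("scanning$processivity", function(v) v > 0 && v <= 1)
  need("scanning$depth", function(v) v >= 1)
  need("chipexo$spread", function(v) v >= 0)
  need("mnase$nrl", function(v) v > 0)
  need("mnase$jitter_sd", function(v) v >= 0)
  need("analysis$peak_min_frac", function(v) v >= 0 && v <= 1)
  config
}

#' Run the full synthetic scanning-model pipeline
#'
#' Stages: `simulate` (genome, promoters, TSS-seq per strain, ChIP-exo
#' WT and extended-scanning mutant, MNase fragments; all written as
#' FASTA/BED/bedGraph plus a run manifest), `tss` (per-strain metric
#' tables, WT-anchored windows, shift tables), `motif` (usage
#' fractions and differences, element enrichment), `chipexo`
#' (strand-median summaries and shifts), `nuc` (peaks, +1 calls,
#' aggregate, NRL). Outputs are deterministic under a fixed seed.
#'
#' @param config Configuration list or YAML path
#'   (see [default_config()], [validate_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of in-memory results per stage.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  seed <- config$seed

  ## --- simulate ------------------------------------------------------
  genome <- gen_genome(substream_seed(seed, "genome"),
                       config$genome$chrom_lengths,
                       config$genome$gc_fraction)
  prom <- gen_promoters(genome, config$promoters$n,
                        config$promoters$class_mix,
                        seed = substream_seed(seed, "promoters"),
                        up_ext = config$promoters$up_ext,
                        down_ext = config$promoters$down_ext)
  probs <- default_motif_probs(config$scanning$p_strong,
                               config$scanning$p_weak)
  tss_signals <- lapply(names(config$scanning$strains), function(s) {
    simulate_tss_reads(prom, scanning_params(
      motif_base_prob = probs,
      activity_scale = config$scanning$strains[[s]],
      processivity = config$scanning$processivity,
      scan_start_offset = config$scanning$scan_start_offset,
      depth = config$scanning$depth,
      seed = substream_seed(seed, paste0("tss_", s))), library_id = s)
  })
  names(tss_signals) <- names(config$scanning$strains)
  chip_wt <- simulate_chipexo(prom, config$chipexo$center_top,
                              config$chipexo$center_bot,
                              config$chipexo$spread, config$chipexo$depth,
                              scan_extent = 0,
                              seed = substream_seed(seed, "chip_wt"),
                              library_id = "chipexo_wt")
  chip_mut <- simulate_chipexo(prom, config$chipexo$center_top,
                               config$chipexo$center_bot,
                               config$chipexo$spread, config$chipexo$depth,
                               scan_extent = config$chipexo$scan_extent_mut,
                               seed = substream_seed(seed, "chip_mut"),
                               library_id = "chipexo_mut")
  frags <- simulate_mnase(prom, config$mnase$nrl, config$mnase$plus1_offset,
                          config$mnase$jitter_sd, config$mnase$n_nucs,
                          config$mnase$depth,
                          seed = substream_seed(seed, "mnase"))
  if ("simulate" %in% config$stages) {
    write_genome_fasta(prom$genome, file.path(out_dir, "genome.fa"))
    write_promoters(prom$windows, file.path(out_dir, "promoters.bed"))
    for (s in names(tss_signals))
      write_bedgraph_pair(tss_signals[[s]],
                          file.path(out_dir, paste0("tss_", s, ".plus.bedGraph")),
                          file.path(out_dir, paste0("tss_", s, ".minus.bedGraph")))
    write_bedgraph_pair(chip_wt,
                        file.path(out_dir, "chipexo_wt.plus.bedGraph"),
                        file.path(out_dir, "chipexo_wt.minus.bedGraph"))
    write_bedgraph_pair(chip_mut,
                        file.path(out_dir, "chipexo_mut.plus.bedGraph"),
                        file.path(out_dir, "chipexo_mut.minus.bedGraph"))
    write_fragments(frags, file.path(out_dir, "mnase_fragments.bed"))
    write_manifest(c(list(package_version = as.character(
                            utils::packageVersion("initscan")),
                          seed = seed),
                     list(n_promoters = config$promoters$n,
                          tss_depth = config$scanning$depth,
                          processivity = config$scanning$processivity,
                          scan_start_offset = config$scanning$scan_start_offset,
                          nrl = config$mnase$nrl,
                          plus1_search_paper_silent = paste(
                            config$analysis$plus1_search, collapse = ".."),
                          element_region_paper_silent = "-200..0",
                          obs_cap_paper_silent = 5000,
                          mwu_level_paper_silent = "read")),
                   file.path(out_dir, "manifest.txt"))
  }
  res$simulate <- list(promoters = prom, tss = tss_signals,
                       chip_wt = chip_wt, chip_mut = chip_mut,
                       fragments = frags)

  ## --- tss -----------------------------------------------------------
  wt <- tss_signals$wt
  anchored <- build_tss_anchored_windows(wt, prom$windows)
  if ("tss" %in% config$stages) {
    metrics <- lapply(tss_signals, tss_metrics_table, windows = anchored)
    shifts <- lapply(setdiff(names(tss_signals), "wt"), function(s) {
      shift_table(tss_signals[[s]], wt, anchored,
                  config$analysis$min_expression)
    })
    names(shifts) <- setdiff(names(tss_signals), "wt")
    for (s in names(metrics))
      write_table_tsv(metrics[[s]],
                      file.path(out_dir, paste0("tss_metrics_", s, ".tsv")))
    for (s in names(shifts))
      write_table_tsv(shifts[[s]],
                      file.path(out_dir, paste0("tss_shift_", s, "_vs_wt.tsv")))
    res$tss <- list(windows = anchored, metrics = metrics, shifts = shifts)
  }

  ## --- motif ---------------------------------------------------------
  if ("motif" %in% config$stages) {
    fracs <- lapply(tss_signals, motif_usage_fractions, windows = anchored,
                    genome = prom$genome)
    diffs <- lapply(setdiff(names(fracs), "wt"), function(s)
      motif_usage_diff(fracs[[s]], fracs$wt))
    names(diffs) <- setdiff(names(fracs), "wt")
    expr <- vapply(seq_len(nrow(anchored)), function(i)
      window_counts(wt, anchored[i, ])$expression, numeric(1))
    dec <- expression_deciles(expr, anchored$promoter_id)
    enr <- lapply(c("tata_consensus", "tata_like", "gae"), function(kind) {
      element_enrichment_by_decile(
        element_presence(prom$genome, anchored, kind),
        dec, anchored$promoter_class)
    })
    names(enr) <- c("tata_consensus", "tata_like", "gae")
    frac_tab <- data.frame(motif = names(fracs$wt))
    for (s in names(fracs)) frac_tab[[s]] <- as.numeric(fracs[[s]])
    write_table_tsv(frac_tab, file.path(out_dir, "motif_fractions.tsv"))
    for (kind in names(enr))
      write_table_tsv(enr[[kind]],
                      file.path(out_dir, paste0("element_", kind, ".tsv")))
    res$motif <- list(fractions = fracs, diffs = diffs, deciles = dec,
                      enrichment = enr)
  }

  ## --- chipexo -------------------------------------------------------
  if ("chipexo" %in% config$stages) {
    sum_wt <- chipexo_summaries(chip_wt, prom$windows)
    sum_mut <- chipexo_summaries(chip_mut, prom$windows)
    shift <- chipexo_shift(sum_mut, sum_wt)
    hist_wt <- median_histograms(sum_wt)
    prof <- aggregate_profile(chip_wt, prom$windows)
    write_table_tsv(sum_wt, file.path(out_dir, "chipexo_summary_wt.tsv"))
    write_table_tsv(sum_mut, file.path(out_dir, "chipexo_summary_mut.tsv"))
    write_table_tsv(shift, file.path(out_dir, "chipexo_shift.tsv"))
    write_table_tsv(data.frame(rel = prof$rel, top = prof$top,
                               bot = prof$bot),
                    file.path(out_dir, "chipexo_profile_wt.tsv"))
    res$chipexo <- list(wt = sum_wt, mut = sum_mut, shift = shift,
                        histograms = hist_wt, profile = prof)
  }

  ## --- nuc -----------------------------------------------------------
  if ("nuc" %in% config$stages) {
    prof <- midpoints_from_fragments(frags, nchar(prom$genome))
    prof <- smooth_midpoints(prof)
    peaks <- call_peaks(prof, config$analysis$peak_min_frac,
                        config$analysis$peak_min_dist)
    p1 <- plus1_table(peaks, anchored, config$analysis$plus1_search)
    p1w <- plus1_windows(p1, anchored, config$analysis$plus1_win,
                         config$analysis$plus1_win)
    agg <- if (nrow(p1w)) aggregate_midpoints(prof, p1w) else NULL
    nrl <- if (!is.null(agg)) {
      ## NRL window: 200 nt upstream to 800 nt downstream of +1
      autocorrelation_nrl(agg[as.integer(names(agg)) >= -200 &
                                as.integer(names(agg)) <= 800],
                          threshold = config$analysis$acf_threshold)
    } else list(nrl = NA_integer_)
    write_table_tsv(peaks, file.path(out_dir, "nuc_peaks.tsv"))
    write_table_tsv(p1, file.path(out_dir, "nuc_plus1.tsv"))
    write_table_tsv(data.frame(nrl = nrl$nrl),
                    file.path(out_dir, "nuc_nrl.tsv"))
    res$nuc <- list(profile = prof, peaks = peaks, plus1 = p1,
                    aggregate = agg, nrl = nrl$nrl)
  }
  invisible(res)
}

#' Small end-to-end demonstration run
#'
#' Runs the full pipeline on a reduced synthetic genome (60 promoters,
#' 2000 reads per promoter) and reports the headline recovery
#' quantities: sign-correct polar shift fractions for the fast
#' (lambda = 2) and slow (lambda = 0.5) strains, the slow strain's
#' spread change, the ChIP-exo downstream-border shift, and the
#' recovered nucleosome repeat length.
#'
#' @param out_dir Output directory.
#' @param seed Root seed.
#' @return List of headline numbers (also printed).
#' @export
demo_run <- function(out_dir = file.path(tempdir(), "initscan_demo"),
                     seed = 1L) {
  cfg <- default_config(seed)
  cfg$genome$chrom_lengths <- c(chrI = 150000L)
  cfg$promoters$n <- 60L
  cfg$scanning$depth <- 2000L
  res <- run_pipeline(cfg, out_dir)
  sh_fast <- res$tss$shifts$fast
  sh_slow <- res$tss$shifts$slow
  out <- list(
    n_promoters = nrow(res$tss$windows),
    frac_upstream_fast = mean(sh_fast$delta_median[sh_fast$included] <= 0),
    frac_downstream_slow = mean(sh_slow$delta_median[sh_slow$included] >= 0),
    median_delta_spread_slow = stats::median(
      sh_slow$delta_spread[sh_slow$included]),
    chipexo_bot_shift = stats::median(res$chipexo$shift$delta_bot,
                                      na.rm = TRUE),
    nrl = res$nuc$nrl)
  cat(sprintf("promoters analysed:              %d\n", out$n_promoters))
  cat(sprintf("upstream-shift fraction (fast):  %.3f\n", out$frac_upstream_fast))
  cat(sprintf("downstream-shift fraction (slow): %.3f\n",
              out$frac_downstream_slow))
  cat(sprintf("median spread change (slow):     %+.1f nt\n",
              out$median_delta_spread_slow))
  cat(sprintf("ChIP-exo bottom-strand shift:    %+.1f nt\n",
              out$chipexo_bot_shift))
  cat(sprintf("recovered NRL:                   %s nt\n",
              ifelse(is.na(out$nrl), "NA", out$nrl)))
  invisible(out)
}
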