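# initscan

Analysis of transcription start site (TSS) selection under the RNA
polymerase II promoter-scanning ("shooting gallery") model in budding
yeast, plus a seeded generative simulator of the scanning process so that
every statistic in the stack can be validated as a parameter-recovery
experiment.

## Who this is for

Groups analysing strand-specific 5′-end sequencing (TSS-seq), ChIP-exo of
pre-initiation-complex (PIC) components, and MNase-seq nucleosome data at
yeast promoters — and anyone who wants a tested, self-contained
implementation of the scanning-model statistics:

* **Promoter TSS metrics** — per-promoter count windows (408-nt
  element-anchored, 401-nt median-TSS-anchored), directional median TSS,
  TSS spread (10th–90th percentile distance), expression, normalized
  densities; mutant-vs-WT shift tables with the polar sign convention
  (upstream negative, downstream positive); base-by-base library
  correlation with a ≥ 3-read joint threshold; Kruskal–Wallis /
  Dunn / Mann–Whitney U shift testing with BH adjustment.
* **TSS efficiency and motifs** — efficiency at position *i* is
  `reads_i / reads at or downstream of i`, the natural estimator of
  per-site initiation probability under scanning; positions with ≥ 20%
  efficiency computed from ≤ 5 reads are flagged excluded. 64-way
  N₋₈N₋₁N₊₁ motif usage fractions and mutant−WT differences; primary/
  secondary/tertiary TSS ranking; TATA consensus (TATAWAWR), TATA-like
  (1–2 mismatches) and GA-element (GAAAAA) scanning with per-class,
  per-expression-decile enrichment.
* **ChIP-exo positioning** — strand-median PIC position estimates per
  promoter (top = promoter-sense strand), class histograms, 21-point
  local-quadratic smoothed aggregate profiles, mutant-vs-WT border shifts.
* **Nucleosomes** — fragment-midpoint profiles, uniform+triweight kernel
  smoothing, 150-nt-spaced peak calling against per-chromosome average
  coverage, +1 nucleosome assignment, 1001-nt +1-anchored aggregation,
  and nucleosome repeat length (NRL) by smoothed autocorrelation.
* **Simulator** — seeded synthetic genomes, promoter classes with planted
  elements and candidate TSSs, multinomial TSS-seq reads from the
  first-success scanning chain `u_i = p_i · Π_{j<i}(1 − p_j)` with
  `p_i = clamp(λ · b(motif_i) · ρ^dist, 0, 1)`, Gaussian ChIP-exo borders,
  and phased nucleosome arrays.

Formats: FASTA genomes (Biostrings), strand-split bedGraph signal pairs
and BED6 annotations (rtracklayer), TSV report tables. Internal
coordinates are 0-based half-open; all written tables are 1-based.

## Worked example

```r
library(initscan)
demo_run(out_dir = "initscan_demo", seed = 1)
```

```
promoters analysed:              60
upstream-shift fraction (fast):  1.000
downstream-shift fraction (slow): 1.000
median spread change (slow):     +45.0 nt
ChIP-exo bottom-strand shift:    +20.0 nt
recovered NRL:                   164 nt
```

The demo simulates 60 promoters at three catalytic-activity levels
(λ = 2, 1, 0.5), anchors windows on the WT median TSS, and reports: the
fraction of promoters whose median TSS moves upstream under the fast
mutant and downstream under the slow mutant (the polar-shift prediction —
both 1.000 here), the slow mutant's median TSS-spread widening (+45 nt:
distributions flatten when initiation weakens), the recovered shift of the
downstream ChIP-exo border after a planted 20-nt scanning extension
(+20.0 nt), and the NRL recovered by autocorrelation from jittered
nucleosome arrays planted at 165 nt (164 nt at demo depth).

A full-scale run (200 promoters, 10,000 reads each) is one call:

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "run1")
```

which writes the simulated genome/annotations/tracks, per-strain TSS
metric tables, shift tables, motif fractions, element enrichment,
ChIP-exo summaries and nucleosome calls, plus a manifest of every
parameter (assumptions flagged explicitly). A thin CLI wrapper lives at
`inst/cli/initscan` (`initscan demo`, `initscan simulate --config cfg.yaml`).

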