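---
title: "TSS selection under promoter scanning: models, metrics and simulator design"
author: "initscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TSS selection under promoter scanning: models, metrics and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(initscan)
```

## The scientific problem

In *Saccharomyces cerevisiae*, the pre-initiation complex (PIC) of RNA
polymerase II and the general transcription factors assembles upstream of the
transcribed region and then scans the template downstream to select
transcription start sites (TSSs). Under this "shooting gallery" picture, each
position the polymerase passes is a target it may fire at: the probability of
initiating at a given position depends on the local sequence (a pyrimidine at
−1 followed by a purine at +1, strengthened by an A at −8), on the catalytic
activity of the polymerase, and on how much polymerase flux is left after
upstream positions have fired. The model makes a sharp, testable prediction:
raising catalytic activity shifts TSS usage *upstream* in a polar fashion,
lowering it shifts usage *downstream* and flattens the usage distribution.

`initscan` implements the complete analysis stack needed to test those
predictions — promoter-window TSS metrics, the directional TSS efficiency
statistic, 64-way initiation-motif decomposition, core-promoter element
scanning, strand-specific ChIP-exo positioning of PIC components, and
MNase-seq nucleosome positioning with repeat-length estimation — together
with a seeded generative simulator of the scanning process itself, so that
every downstream statistic can be exercised as a parameter-recovery
experiment without external sequencing data.

## The generative model

For a promoter with candidate TSSs ordered upstream → downstream at relative
positions $x_1 < x_2 < \dots < x_m$, the simulator assigns each candidate an
initiation probability

$$p_i = \min\!\left(1,\; \lambda \cdot b(\mathrm{motif}_i) \cdot
\rho^{\,d_i}\right),$$

where $b(\cdot)$ is a per-motif base probability over the 64
$N_{-8}N_{-1}N_{+1}$ keys, $\lambda$ is a catalytic-activity multiplier
(1 = wild type), $\rho \in (0,1]$ is a per-nucleotide scanning survival
probability, and $d_i$ is the distance scanned from the scan start. Expected
usage is the first-success product chain

$$u_i = p_i \prod_{j<i} (1 - p_j),$$

and the residual probability $\prod_j (1-p_j)$ of scanning past every
candidate is *dropped*: observed 5′ ends are conditioned on initiation
having occurred, so `depth` reads are drawn multinomially from the
renormalized $u_i$. This conditioning is why `tss_efficiency()` — reads at a
position over reads at or downstream — is the natural estimator here: at
infinite depth it returns the $p_i$ exactly up to the trailing
renormalization (the most downstream used position always reports
efficiency 1).

Candidate positions are not declared; they are *read from the sequence*.
Any position in the scan region whose motif key has nonzero configured
probability is a candidate, which includes chance Y$_{-1}$R$_{+1}$
occurrences in the random genomic background as well as planted sites. This
matters: it makes motif-usage shifts between activity mutants an emergent
property of the sequence rather than an artifact of fixture bookkeeping.

### Simulator defaults and why

* `default_motif_probs(p_strong = 0.25, p_weak = 0.08, p_other = 0)` —
  A$_{-8}$Y$_{-1}$R$_{+1}$ sites fire at 0.25, other Y$_{-1}$R$_{+1}$ at
  0.08, non-Y$_{-1}$R$_{+1}$ not at all. The ordering (strong ≫ weak ≫ ~0)
  is the empirically motivated shape; the absolute values are model
  configuration chosen so that a typical promoter with 6–12 sites consumes
  most of its polymerase flux within ~100 nt, as real yeast promoters do.
* `processivity = 1` — scanning processivity is not quantified
  experimentally; the geometric survival term is exposed as configuration
  and disabled by default so that activity effects are attributable to
  $\lambda$ alone.
* `scan_start_offset = 25` nt downstream of the core-promoter element
  anchor, reflecting PIC assembly over the element with DNA opening
  downstream.
* `depth = 10000` reads per promoter and 200 promoters per experiment —
  the scale at which shift recovery is tested throughout.
* Promoter classes: `taf1_depleted` promoters carry a planted TATA
  consensus (TATAWAWR) at the window anchor; `taf1_enriched` promoters a
  GA-rich element (GAAAAA); candidate TSSs are planted 50–100 nt downstream
  of the element with 9–15 nt spacing (spacings below 9 nt would let one
  site's −8 context overwrite its neighbour's +1 base).
* ChIP-exo borders are discretized Gaussians: reads on the promoter-sense
  ("top") strand at the upstream border, anti-sense ("bot") reads at the
  downstream border. Only median positions are asserted against — the
  Gaussian shape is an explicit simplification. A `scan_extent` parameter
  shifts the downstream border only, emulating extended-scanning mutants.
* MNase fragments: midpoints at `plus1_offset + k * nrl` (defaults 150 nt,
  165 nt, 6 nucleosomes) with Gaussian jitter (SD 10 nt), lengths 147 nt.
  Odd fragment lengths make midpoints exactly mirror-symmetric under
  reverse complementation, which the strand-symmetry suite exploits.

## Coordinate and orientation contract

Internally all coordinates are 0-based, intervals half-open; every report
table written to disk is 1-based inclusive. Promoter-relative coordinates
increase *downstream* regardless of genomic strand; on a minus-strand
promoter "upstream" is the higher-coordinate side, and all sequence context
is complemented. The package ships mirroring utilities
(`mirror_genome()`, `mirror_windows()`, `mirror_signal()`,
`mirror_fragments()`) whose defining property — every oriented metric is
invariant under reverse-complementing the genome and mirroring all
annotations — is enforced by the test suite.

Fragment midpoints use $\lfloor (s + e - 1)/2 \rfloor$ for a half-open
interval $[s, e)$: deterministic and consistent with the integer-position
signal model (a 147-nt fragment at $[100, 247)$ has midpoint 173).

## TSS metrics

* **Median TSS** — the first position, scanning upstream → downstream, whose
  cumulative count reaches 50% of the window total. Ties therefore resolve
  upstream, matching the directional semantics of scanning; the same rule is
  applied to the 10th/90th percentiles.
* **TSS spread** — distance between the directional 10th and 90th percentile
  positions.
* **Windows** — element-anchored windows extend 200 nt around an 8-nt
  TATA/TATA-like anchor (408 nt); TSS-anchored windows extend 200 nt around
  the 1-nt WT median TSS (401 nt) and are re-centered exactly once after the
  median is recomputed in the shifted window (new TSSs revealed by the shift
  are accounted for one time; the pass is deliberately not iterated to a
  fixed point). A display extent of −250..+150 is recorded separately.
  +1-nucleosome windows extend 500 nt around the dyad (1001 nt).
* **Shifts** — `delta_median = median(mut) − median(wt)` in oriented
  coordinates: upstream shifts are negative, downstream positive.
* **Inclusion** — shift analyses default to promoters with ≥ 200 WT reads.
* **Correlation** — base-by-base Pearson r restricted to positions with
  ≥ 3 reads in *both* libraries, since low-coverage positions otherwise
  dominate.

## Efficiency, motifs and elements

TSS efficiency at position $i$ is $c_i / \sum_{j \ge i} c_j$ within the
analysis window; reads beyond the window are invisible, so the statistic is
documented as window-relative. Positions with efficiency ≥ 20% computed
from ≤ 5 reads are flagged excluded — such calls are definitionally confined
to downstream window edges, where denominators run dry. Excluded positions
are dropped from efficiency aggregates but retained in usage.

Motif keys take the bases at −8, −1 and +1 in promoter orientation; any
out-of-bounds or non-ACGT context becomes an "ambiguous" bucket excluded
from the 64-way tallies but retained in usage and efficiency. Element scans
match TATAWAWR (W = A/T, R = A/G at zero cost), TATA-like (1–2 mismatches,
disjoint from the exact class), and GAAAAA; overlapping hits are all
reported and enrichment uses presence/absence. The element search region
relative to the median TSS defaults to −200..0 and is recorded in the run
manifest — the informative span is ~50–100 bp upstream of the TSS cluster,
but the wider default is robust to diffuse TSS distributions.

## Statistical testing

Each sequenced 5′ end is one observation of a TSS position. Per promoter,
a Kruskal–Wallis test across all replicate libraries asks whether any
library's positional distribution differs; Dunn's post hoc z statistic
(pooled tie-corrected ranking across strains, replicates pooled within
strain) compares each mutant against WT, with Benjamini–Hochberg adjustment
across promoters within each contrast; a Mann–Whitney U test on the same
pooled positional samples is added when both strains have ≥ 3 replicates.
Observation counts are capped at 5,000 reads per promoter per library by
seeded subsampling — read-level testing is otherwise unbounded in n. Dunn's
test is implemented in-package (no pre-installed implementation exists in
this stack) and is verified against a from-scratch rank computation.

Two open interpretive choices are resolved as follows: the MWU operates on
read-level positions by default (a replicate-level variant on per-replicate
median positions is available via `mwu_level = "replicate"`), and BH across
promoters within a contrast is used for multiple-testing correction. Both
are assumptions, flagged as such in the run manifest.

## ChIP-exo positioning

Per promoter and strand, the PIC position estimate is the directional median
of ChIP-exo read 5′ ends in the window, defined only at ≥ 10 strand reads
(an assumption — the read floor is configurable). "Top" is the
promoter-sense strand. Aggregate profiles normalize each selected promoter's
window to sum 1, average over the top 50% of promoters by WT signal, and
smooth with a 21-point local quadratic (Savitzky–Golay-type) fit applied
once. Edge positions use truncated fitting windows rather than mirror
padding, which would fabricate signal. The smoother reproduces quadratics
to < 1e−9 and is linear, both enforced by tests.

## Nucleosome positioning

Midpoint profiles are smoothed by a uniform kernel (half-width 5 nt)
followed by a normalized triweight kernel
$w(d) \propto (1 - (d/76)^2)^3$, $|d| \le 75$. Composition order is
irrelevant (symmetric FIR kernels commute) and is fixed as uniform-first
for definiteness; the denominator 76 keeps the endpoint weights nonzero.
Peaks are local maxima of the smoothed profile with greedy suppression so
no two peaks sit closer than 150 nt (ties go upstream), yielding one peak
per nucleosome; each peak is annotated with its raw midpoint count as a
fraction of the chromosomal average coverage (sum of raw midpoints over
chromosome length, per chromosome, never pooled). Peaks below the 20%
fraction are retained but flagged, so the +1 rule and QC can both see them.

The +1 nucleosome is the first qualifying peak downstream of the median
TSS within (0, 300] nt — the "plausible +1 range" is not quantified
experimentally, so it is exposed as configuration and recorded in the
manifest. Repeat length is estimated from the aggregate midpoint profile
over −200..+800 windows around +1: the sample autocorrelation by lag,
smoothed with a uniform kernel (half-width 5, truncated-kernel
renormalization at the boundaries — zero padding would fabricate a dip),
and the NRL is the smallest positive lag that is a local maximum with
smoothed value > 0.05.

Two numerical choices deserve note. First, the per-lag normalization is
*unbiased* (covariances divided by $n - k$ rather than $n$): the standard
taper shrinks large-lag values and drags periodic peaks toward shorter
lags by 1–2 nt. Second, after the peak is located on the smoothed
function, the reported lag is refined to the raw-autocorrelation argmax
within one kernel half-width — smoothing over a sloped background can
displace a plateau edge by up to the half-width. With both choices, a
delta train of period 165 returns exactly 165 and a sinusoid of period
150 exactly 150, while jittered simulated arrays (SD 10 nt) recover
165 ± 5 across seeds.

## Problem sizes used in validation

The validation suite runs the recovery experiments at 200 promoters with
10,000 reads per promoter for TSS shifts, 500 null promoters and 200
shifted promoters (3 replicates, 200 reads each) for test calibration, and
200 promoters × 500 fragments for nucleosome recovery — sizes chosen so
each property is measured with useful precision while the whole suite
completes in about a minute on a laptop core. The strand-symmetry check
runs the full metric stack on a 25-promoter fixture and its
reverse-complemented mirror and requires exact equality of all oriented
outputs.

## What the simulator does and does not establish

Passing recovery tests shows the *analysis stack* is faithful: the polar
sign convention is implemented correctly end to end, the efficiency
statistic inverts the generative chain, the smoothing/peak-calling path
recovers planted spacings, and the statistical stage is calibrated on its
own observational model. It does not certify behaviour on real data, which
departs from the simulator in known ways: no sequencing error, mappability
structure, duplicate reads, crosslink sequence bias (ChIP-exo), or MNase
digestion bias is modelled; real TSS distributions have heavier tails than
multinomial sampling of a product chain; and real nucleosome arrays mix
subpopulations that a single phased-array model does not represent.
Conclusions about real libraries should rest on the metric definitions, not
on simulator-derived effect sizes.

## Worked example

```{r demo, eval = FALSE}
library(initscan)
demo_run(out_dir = "initscan_demo", seed = 1)
#> promoters analysed:              60
#> upstream-shift fraction (fast):  1.000
#> downstream-shift fraction (slow): 1.000
#> median spread change (slow):     +45.0 nt
#> ChIP-exo bottom-strand shift:    +20.0 nt
#> recovered NRL:                   164 nt
```

The fast strain ($\lambda = 2$) shifts every promoter's median TSS upstream
(or holds it), the slow strain ($\lambda = 0.5$) downstream, the slow strain
widens TSS spreads, the planted 20-nt extension of the downstream ChIP-exo
border is recovered exactly at the median, and the planted 165-nt repeat
length is recovered within 1 nt at this reduced demo depth.
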