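---
title: "Quantifying ALE usage and pA-site bypass: models and design choices"
author: "apabypass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ALE usage and pA-site bypass: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apabypass)
```

## The problem

Many genes carry more than one cleavage/polyadenylation (pA) site. When the
alternative sites sit in the same terminal exon, alternative polyadenylation
(APA) produces nested short and extended 3'UTRs (tandem-UTR, "TUTR"
structure). When they sit in distinct terminal exons, the gene switches
between alternative last exons ("ALE" structure), changing both the 3'UTR
and possibly the C-terminal coding sequence. Neural ELAV/Hu-family
RNA-binding proteins promote the distal choice by suppressing cleavage at
proximal pA sites through U-rich sequences just downstream of them — the
proximal site is *bypassed* and transcription proceeds to a distal site.

`apabypass` implements the quantitative side of this analysis as a reusable,
tested pipeline: gene-model classification, 3'-seq cluster quantification,
ALE usage and bypass statistics, psi-based APA quantification across a
differentiation timecourse, sequence analyses around cleavage sites, a
simplified cassette-exon stage, and a synthetic-data generator that provides
ground truth for every step.

## Gene models and unique 3'UTRs

Genes are classified from their transcript models after merging 3' termini
closer than 25 nt (the same window used for 3'-seq clustering; this
prevents micro-heterogeneity in annotated ends from inflating the MIXED
class):

* **SINGLE** — one merged terminus;
* **TUTR** — two or more termini, all within one shared last exon;
* **ALE** — all termini in distinct last exons;
* **MIXED** — anything else. MIXED genes are excluded from usage and psi
  quantification.

For ALE/MIXED genes we derive *unique 3'UTRs*: per distinct 3'UTR start
site the longest isoform 3'UTR is kept, and a kept UTR must extend beyond
the exonic sequence of at least one isoform with a different start. A UTR
nested entirely inside the exons of every other isoform is a tandem
extension rather than an ALE-specific segment and is dropped. Start sites
are compared at nucleotide resolution after the 25-nt terminus merge; an
explicit tolerance would add a second, redundant merging layer. When a CDS
is annotated the 3'UTR begins at the CDS 3' boundary, otherwise the full
last exon stands in (`use_cds` flag).

## 3'-seq quantification

Read 3' ends are clustered by a greedy summit-first rule: the
highest-weight position seeds a cluster, positions within half the window
(default 25 nt) are absorbed, and the process repeats; ties break to the
leftmost coordinate so the output is deterministic. The test suite checks
this against an independent recursive implementation on exhaustive small
inputs. Cluster summits are assigned to unique 3'UTRs with a 25-nt
downstream slop (configurable), absorbing cleavage heterogeneity past the
annotated end.

Per gene, with the dominant (highest pooled control count) unique 3'UTR
labeled *universal* (U) and the remaining UTRs *proximal* (P) or *distal*
(D) by position:

* **ALE usage** = (U + D) / (U + P), per replicate;
* **ALE usage ratio** = mean sample usage / mean control usage;
* significance: two-way ANOVA on `log2(count + 1)` with factors condition
  and UTR, reporting the condition-by-UTR *interaction* p-value; a gene is
  called at p < 0.05 **and** at least a 2-fold usage ratio in either
  direction. The log transform stabilizes the variance of overdispersed
  counts, and the interaction term is the isoform-shift term — main effects
  absorb library-size and overall-expression differences.

* **bypass score** of a pA site at rank *r* (5'→3'): 100 × (counts at
  ranks > r) / (total counts over the gene's unique 3'UTRs). The
  denominator is the gene total, the only reading under which the score is
  a percentage in [0, 100]; the most distal site scores 0 by construction.
* **bypass ratio** = sample score / control score; **unbypassed ratio** =
  (100 − sample score) / (100 − control score). These are plain quotients;
  each is undefined when its control denominator is zero. (Verbal
  descriptions of these ratios elsewhere can be read in contradictory ways;
  the quotient semantics used here are the ones all results in this package
  are defined by.)

## psi over a differentiation timecourse

For genes with exactly two pA sites, psi is the fractional distal usage,
`psi = A_distal / (A_proximal + A_distal)` over transcript abundances —
0 means exclusive proximal, 1 exclusive distal usage. Genes with more
sites are rejected rather than approximated; multi-site weighting schemes
answer a different question and are out of scope.

Genes with complete psi trajectories are clustered by k-means on their
delta-psi profile (psi minus psi at the first timepoint), which removes
baseline offsets so that "steadily increasing" is purely a centroid shape.
Clusters whose centroid never decreases by more than `tau` between
consecutive timepoints and rises by at least `delta` overall are called
neurally restricted (NR); members split into NR-TUTR and NR-ALE by gene
structure. The control set contains genes expressed at all late timepoints
whose trajectory is flat (within `delta0`) or decreasing, minus NR genes.

Defaults (all exposed in the API): `k = 6`, `tau = 0.02`, `delta = 0.15`,
`delta0 = 0.05`, expression threshold 1 TPM-equivalent. None of these has a
canonical published value; they were fixed once so that a 0.2→0.8 psi ramp
with measurement noise of sd 0.05 — the regime the generator plants — is
reliably separated from flat trajectories, and they are deliberately
conservative: `delta = 0.15` is three times the planted noise sd, and
`tau = 0.02` tolerates centroid jitter without admitting genuinely
decreasing shapes. k-means runs with a fixed seed and 10 restarts, making
calls bit-for-bit reproducible.

## Sequence analyses

* **PAS classification** searches the 10–30 nt window upstream of a
  cleavage site for hexamers in the priority order AAUAAA > AUUAAA >
  AAUAUA (canonical first, then the two major *Drosophila* variants),
  case- and T/U-insensitive.
* **PWM scanning** slides a position weight matrix over the sequence
  (single strand, transcript orientation) scoring each window by summed
  log-odds against a uniform background with a pseudocount of 0.01. Scores
  are min–max normalized over the achievable range, so a fractional
  threshold ("at least 80%") is robust to motif length and information
  content; the threshold is inclusive. Matches are anchored to the middle
  nucleotide of the window. Windows containing ambiguity codes are
  skipped. The scanner is verified against exhaustive window enumeration.
* **De-duplication** counts distinct (sequence, center) pairs, so similar
  PWMs matching at the exact same position count once; off-by-one centers
  are distinct matches by design.
* **Metaprofiles** report per-position nucleotide frequencies or motif
  densities around anchors, with edge truncation tracked as per-position
  coverage rather than padded.
* Group comparisons use two-sided Wilcoxon rank-sum tests
  (normal approximation with continuity correction); motif–bypass
  association uses Spearman rank correlation.
* Window presets follow the analysis conventions of the field: 50 nt
  downstream of cleavage sites, 100 nt on each side of splice sites, and
  100 nt around the proximal pA site.

The packaged PWM (`synthetic_elav_pwm()`, shipped as
`inst/extdata/elavlike_synth.meme`) is an 8-nt U-rich matrix with an
interior G. It is *synthetic*: constructed for testing and demonstration,
not derived from any binding assay. Real analyses should supply measured
PWMs in MEME minimal format via `read_meme_pwm()`.

## Cassette exons

The splicing stage is deliberately simple: `psi = (I/2) / (I/2 + S)` with
inclusion junctions halved (two junctions support inclusion, one supports
skipping), delta-psi as the difference of replicate-mean psi, a pooled
two-proportion test with Benjamini–Hochberg adjustment, and the filter
"more than 5 junction reads per condition, FDR < 0.05, |delta-psi| > 0.3".
The junction-read cutoff is applied per condition on pooled replicates,
reading "more than 5" strictly. Full likelihood-based splicing models are
not reimplemented; the filter thresholds and the cross-comparison union
rule (events keyed by gene and exon interval, provenance recorded,
direction conflicts flagged discordant) are the point here.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `generate_reference()` and the
`simulate_*` functions are deterministic given the seed. The generator
emulates:

* genes of all four structure classes on both strands (gene layouts keep
  termini > 25 nt apart so terminus merging is exercised but never
  collapses planted sites);
* a canonical AAUAAA planted 10–30 nt upstream of strong 3' ends and the
  weaker AUUAAA variant upstream of proximal ALE ends, mirroring the
  observation that internal ALE termini carry weaker signals;
* 1–3 copies of the test-PWM consensus planted in the +1..+50 window
  downstream of the proximal pA site of "target" ALE genes;
* 3'-seq counts: per gene, bypass probability
  `b = plogis(qlogis(bypass_base) + gain × motif_count × activity)`,
  negative-binomial proximal/distal counts (`mu = nb_mean × (1−b)` and
  `nb_mean × b`, dispersion 0.1 so the ANOVA stage sees realistic
  overdispersion), and read ends jittered ±12 nt around the cleavage site —
  wide enough to exercise the 25-nt clustering, narrow enough never to
  merge distinct sites;
* junction counts as `X ~ Binomial(depth, psi)` with inclusion reported as
  `2X`, so the psi estimator is unbiased for the planted value;
* timecourse abundances over eight timepoints in which NR genes follow a
  logistic psi ramp from 0.2 to 0.8, a third of the background decreases,
  and the rest stay flat, with truncated Gaussian noise (sd 0.05).

What the generator does **not** emulate: sequencing error, fragment-length
and coverage biases, internal priming artifacts, mappability, multi-gene
overlap, expression-level heterogeneity across genes, and annotation
errors. Passing the closure tests therefore demonstrates that the
estimators recover their own forward model — a necessary condition, not
evidence about any particular real dataset.

## Numerical choices and degenerate inputs

* ALE usage is undefined (NA) when the universal + proximal denominator is
  zero; bypass scores of zero-coverage genes return 0 with a
  `zero_coverage` flag; bypass/unbypassed ratios are NA when the control
  score is 0 or 100 respectively.
* psi is NA at zero abundance or below the expression threshold, with the
  reason attached.
* Clustering ties break leftmost; k-means is seeded; every simulation
  function derives its randomness from the configured seed — reruns are
  byte-identical (checked by checksum in the tests).
* Spearman correlation on constant input is reported NA with a warning
  rather than silently 0.

## Problem sizes used in validation

The bundled validation runs use 200 genes per bypass level at a mean of
500 reads per gene with 3 replicates, 500 genes (50 planted NR) for the
timecourse recovery, 60 ALE genes for the motif-enrichment closure, and
100–200 cassette events at depth 100 for filter calibration. These sizes
give stable estimates (standard errors well inside the tested tolerances)
while keeping the full validation suite around a minute of compute.

## Known limitations

* The ALE-usage ANOVA treats log counts as homoskedastic; a count-model
  (negative-binomial GLM) test would be more powerful at low counts.
* Cluster-to-UTR assignment resolves multi-gene ambiguity by nearest
  terminus only; overlapping gene architectures would need a principled
  assignment model.
* The splicing stage's two-proportion surrogate ignores replicate-level
  variance (counts are pooled); its calibration is demonstrated on the
  generator's binomial counts, not on biological replicates.
* psi is restricted to two-site genes by design.
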