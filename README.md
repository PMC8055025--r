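# apabypass

Quantification of alternative 3'-end isoform usage from 3'-end sequencing
and RNA-seq derived inputs, for transcriptomics researchers studying
alternative polyadenylation (APA), alternative last exon (ALE) switching
and its regulation by RNA-binding proteins such as the neural ELAV/Hu
family, which suppress proximal cleavage/polyadenylation (pA) sites
through downstream U-rich sequences so that distal sites are used instead
("pA-site bypass").

## What it computes

With a gene's unique 3'UTRs labeled universal (U, the dominant one in the
control), proximal (P) and distal (D), and 3'-seq cluster counts assigned
to them:

- **ALE usage** = (U + D) / (U + P); **ALE usage ratio** =
  mean(sample usage) / mean(control usage); significance by two-way ANOVA
  on log2(count + 1) (condition × UTR interaction), called at p < 0.05 and
  ≥ 2-fold ratio.
- **Bypass score** of the pA site at rank *r* (5'→3') =
  100 × Σ counts(rank > r) / Σ counts; **bypass ratio** =
  score_sample / score_control; **unbypassed ratio** =
  (100 − score_sample) / (100 − score_control).
- **psi** for two-pA-site genes = A_distal / (A_proximal + A_distal) over
  transcript abundances (0 = exclusively proximal, 1 = exclusively
  distal), with k-means detection of genes whose psi rises monotonically
  across a differentiation timecourse ("neurally restricted", NR) and a
  flat/decreasing control set.
- **Sequence analyses**: PAS hexamer classes (AAUAAA > AUUAAA > AAUAUA,
  scanned 10–30 nt upstream of cleavage sites), nucleotide metaprofiles,
  PWM scanning at a fractional match threshold (≥ 80% of the min–max
  score range) with exact-position de-duplication, positional motif
  density, Wilcoxon group tests and Spearman motif–bypass correlation.
- **Cassette exons**: psi = (I/2) / (I/2 + S) from junction counts,
  delta-psi between condition means, two-proportion test with BH FDR, the
  filter "> 5 junction reads per condition, FDR < 0.05, |ΔPSI| > 0.3",
  and the cross-comparison union rule.
- A **synthetic-data generator** (`sim_config()`, `generate_reference()`,
  `simulate_3pseq()`, `simulate_junction_counts()`,
  `simulate_timecourse()`) that plants all of the above with known ground
  truth — U-rich motifs downstream of bypassable proximal pA sites,
  negative-binomial 3'-seq counts under a logistic bypass model, and
  monotone psi trajectories.

See `vignettes/apa-bypass-methods.Rmd` for the models, parameter defaults
and design decisions.

## Worked example

```r
library(apabypass)

cfg <- sim_config(seed = 42, n_single = 2, n_tutr = 4, n_ale = 10, n_mixed = 2)
ref <- generate_reference(cfg)
ref$gms
#> <gene_model_set: 18 genes (SINGLE=2, TUTR=4, ALE=10, MIXED=2)>

ends <- rbind(simulate_3pseq(ref$truth, cfg, "control"),
              simulate_3pseq(ref$truth, cfg, "treatment"))
counts <- utr_count_maps(ref$gms, ends)   # cluster (25 bp) + assign to UTRs

ale <- ale_usage_table(counts, "control", "treatment")
head(ale[order(ale$p_value), ], 3)
#>     gene_id usage_control usage_sample usage_ratio  p_value significant
#> 1  g007_ale          1.17        24.95       21.37 3.58e-06        TRUE
#> 10 g016_ale          1.38        30.94       22.40 5.27e-06        TRUE
#> 9  g015_ale          1.23         5.51        4.46 3.19e-05        TRUE

byp <- bypass_table(counts, "control", "treatment")
head(byp[order(-byp$bypass_ratio), ], 3)
#>    gene_id pa_rank score_control score_sample bypass_ratio unbypassed_ratio
#> 1 g007_ale       1          14.3         95.9         6.71           0.0481
#> 9 g015_ale       1          16.8         81.0         4.81           0.2289
#> 5 g011_ale       1          17.8         85.4         4.80           0.1781
```

`g007_ale` carries planted downstream U-rich motifs: under RBP activity
its proximal pA site is bypassed in 96% of reads versus 14% in the
control (bypass ratio 6.7), and its ALE usage rises 21-fold — a
significant distal ALE switch. Joining against `ref$truth` shows that
only motif-bearing genes are called significant:

```r
merged <- merge(ale, ref$truth[, c("gene_id", "motif_count")], by = "gene_id")
table(significant = merged$significant, has_motif = merged$motif_count > 0)
#>            has_motif
#> significant FALSE TRUE
#>       FALSE     2    3
#>       TRUE      0    5
```

The same stages are available as subcommands
(`run_subcommand("simulate", outdir, seed = 42)`, then `"ale"`,
`"bypass"`, `"psi"`, `"nr"`, `"motif"`, `"splicing"`, `"report"`), each
writing a TSV and a JSON manifest; `inst/cli/apabypass.R` is a thin
shell wrapper.

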