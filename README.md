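# mircross

Integrative miRNA–mRNA differential-expression and seed-target analysis for
two-group expression contrasts.

## What it is for

Given paired miRNA and mRNA expression matrices from the same two-group
experiment (e.g. diseased versus control tissue), a 3′UTR sequence set and a
miRNA catalog with genomic-cluster annotations, `mircross` identifies the
miRNAs — and co-located miRNA clusters — whose regulation most strongly
opposes that of their predicted target genes. This is the discovery logic
used in vascular-disease transcriptomics to nominate repressive miRNAs
(e.g. a downregulated cluster whose seed-bearing targets rise with disease)
for experimental follow-up, together with the ΔΔCt machinery to quantify
that follow-up by qPCR.

The chain:

* **Differential expression** — empirical-Bayes moderated t with
  Benjamini–Hochberg correction and Wilcoxon rank-sum (exact for small
  samples) for miRNA arrays; two-class unpaired **SAM**
  (d = Δmean / (s + s₀), balanced label permutations, median-count FDR)
  for mRNA arrays.
* **Seed-match target prediction** — canonical site types on the UTR sense
  strand: 6mer = rc(miRNA nt 2–7), 7mer-m8 = rc(nt 2–8), 7mer-A1 and 8mer
  add the anchor adenosine; longer sites absorb contained shorter ones.
* **Anticorrelation ranking** — per miRNA, the predicted targets called in
  the opposite direction; per cluster, the union of member sets; ranked by
  distinct-gene count with deterministic tie-breaks.
* **Seed-hexamer enrichment** — one-sided, tie-corrected Wilcoxon rank-sum
  comparing per-UTR counts of each DE miRNA's seed hexamer in upregulated
  versus non-regulated gene lists, ranked by −ln P.
* **qPCR statistics** — ΔΔCt fold changes (2^−ΔΔCt, control-anchored),
  two-tailed Student t, one-way ANOVA with Bonferroni post test, χ².
* **Synthetic data** — a truth-known generator for the whole design
  (planted downregulated cluster, planted seed-bearing upregulated targets,
  log-normal noise), so every claim above is testable offline.

## Worked example

```r
library(mircross)

cfg <- sim_config(seed = 1)            # 5 vs 5 arrays, planted miR-23b-24-27b cluster
ex  <- generate_expression_experiment(cfg)
res <- run_pipeline(ex$mirna, ex$mrna, ex$utrs, ex$catalog,
                    pipeline_config(seed = 1))

head(res$per_cluster[, c("cluster_id", "n_anticorr", "rank")], 3)
#>       cluster_id n_anticorr rank
#> 1 miR-23b-24-27b         30    1

head(res$enrichment[, c("mirna", "hexamer", "p", "rank")], 3)
#>         mirna hexamer            p rank
#> 1  mmu-miR-24  TGAGCC 6.984438e-09    1
#> 2 mmu-miR-27b  CTGTGA 8.270063e-07    2
#> 3 mmu-miR-23b  ATGTGA 9.795681e-05    3

res$sam
#> sam_result: 600 features; s0 = 0.2761; delta = 1.103
#> calls: 30 up, 0 down; estimated FDR 0 (pi0 = 1)
```

The planted cluster ranks first with all 30 planted targets recovered as
anticorrelated (`n_anticorr`), the SAM stage calls exactly the 30 planted
upregulated genes at FDR < 1%, and the cluster members' seed hexamers top
the enrichment ranking (miR-24's hexamer `TGAGCC` at rank 1 with
p ≈ 7×10⁻⁹). The same functions accept real data through
`read_expression_matrix()`, `read_fasta_utrs()`, `read_mirna_catalog()` and
`read_ct_table()`; `simulate_bundle()` writes a complete synthetic input
bundle as files.

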