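---
title: "Methods: integrative miRNA-mRNA discovery analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative miRNA-mRNA discovery analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircross)
```

# Overview

`mircross` implements the analysis chain by which a two-group expression
contrast (e.g. diseased versus control tissue profiled on paired miRNA and
mRNA arrays) is turned into a ranked list of candidate regulatory miRNAs and
genomic miRNA clusters:

1. call differential expression on the miRNA matrix (moderated t with
   Benjamini–Hochberg correction; Wilcoxon rank-sum as a distribution-free
   alternative) and on the mRNA matrix (two-class unpaired SAM with a
   permutation-estimated FDR);
2. predict miRNA targets by canonical seed matching in 3′UTRs
   (6mer, 7mer-A1, 7mer-m8, 8mer site types);
3. count, per miRNA and per genomic cluster, the predicted targets whose
   mRNA call opposes the miRNA's call, and rank by that count;
4. independently rank differentially expressed miRNAs by enrichment of their
   seed hexamer in the 3′UTRs of upregulated versus non-regulated genes
   (one-sided Wilcoxon rank-sum on per-UTR counts, reported as −ln *P*);
5. quantify follow-up qPCR measurements by the ΔΔCt method, with the
   classical group-comparison statistics (two-tailed Student t, one-way
   ANOVA with Bonferroni post test, χ²).

A truth-known synthetic data generator reproduces the statistical structure
this chain assumes, so every stage — and the chain end-to-end — is testable
without any external download.

# Differential expression

## Moderated t (miRNA arrays)

All DE math operates on log2 intensities (`expression_matrix()` transforms
linear input as `log2(x + offset)`, offset 1 by default; the scale is an
explicit flag because fold-change thresholds are otherwise ambiguous).
For feature $i$ with pooled two-group variance $s_i^2$ on $d_{res}=n_1+n_2-2$
degrees of freedom, an inverse-chi-square prior $(d_0, s_0^2)$ is fitted
across features by moment matching on $\log s^2$ (the excess of
$\mathrm{var}(\log s^2)$ over the chi-square sampling component
$\psi'(d_{res}/2)$ determines $d_0$ through a Newton inversion of the
trigamma function). The posterior variance
$$\tilde s_i^2 = \frac{d_0 s_0^2 + d_{res} s_i^2}{d_0 + d_{res}}$$
yields $t_i = (\bar x_{2i}-\bar x_{1i})/(\tilde s_i\sqrt{1/n_1+1/n_2})$ on
$d_0+d_{res}$ degrees of freedom (capped at the pooled residual df across
features). Two degenerate regimes are defined rather than left to chance:
if the moment fit finds no excess scatter ($d_0$ non-finite), variances are
fully pooled to their mean; if every variance is zero (the noise-free
limit), $t=0, p=1$ where the means agree and $t=\pm\infty, p=0$ where they
differ, so zero-noise data reproduce the planted truth exactly. Setting
`prior_df = 0` recovers the ordinary equal-variance Student t — this limit
is part of the test suite's closed-form checks.

Calls are made by `threshold_de()` with *inclusive* cutoffs (≥ 1.5-fold and
p ≤ 0.05 by default), so boundary features are counted reproducibly. The BH
q-value is always reported; whether the significance gate uses raw p
(default) or q is a flag, since conventions differ between laboratories.

## Wilcoxon rank-sum

The exact null distribution is used whenever the combined sample size is at
most 12 and the feature has no ties; otherwise the normal approximation with
mid-rank tie correction and continuity correction. The exact path is
validated against exhaustive enumeration of all label assignments.

## SAM (mRNA arrays)

The relative difference $d_i = (\bar x_{2i}-\bar x_{1i})/(s_i + s_0)$ uses
an exchangeability constant $s_0$ chosen over the 0–100 percentile grid of
$s$ (5% steps) to minimize the coefficient of variation of the median
absolute centered $d$ across windows of features grouped by $s$ percentile.
When every feature has zero scatter $s_0$ would be 0 and $d$ undefined;
this aborts with an instruction to supply a nonzero `s0_grid`, which is how
noise-free simulations are run (e.g. `s0_grid = 0.5`).

Null order statistics come from two-group label permutations: the full
assignment set is enumerated whenever it contains at most 10,000 assignments
(252 for a 5 vs 5 design), otherwise `n_perm` seeded random assignments are
drawn. For a threshold Δ the asymmetric cutoffs are the first sorted $d$
whose excess over the expected order statistic reaches Δ on either side;
the estimated FDR is
$$\widehat{FDR} = \pi_0 \cdot
  \frac{\mathrm{median}_\text{perm}\,\#\{d^{null} \text{ beyond cutoffs}\}}
       {\#\{\text{features called}\}},\qquad
\pi_0 = \min\!\Big(1,\ 2\cdot\frac{\#\{d_i \in [q_{25}, q_{75}]^{null}\}}{m}\Big),$$
and Δ is the smallest candidate (scanning the distinct values of
$|d_{(i)} - \bar d_{(i)}|$) whose estimated FDR is at or below the target
(1% by default). On toys small enough to enumerate, the estimate is
required to equal an independent plain-loop recount over every assignment.

# Seed-match target prediction

Site patterns are derived from the mature sequence (RNA alphabet) once, at
the seed boundary, into the UTR (DNA) alphabet: the 6mer is the reverse
complement of nucleotides 2–7, the 7mer-m8 of nucleotides 2–8; 7mer-A1 and
8mer append the anchor adenosine, which is matched literally as `A` in the
UTR rather than paired. Coordinates are 0-based half-open on the UTR sense
strand. At a shared locus a longer site absorbs its contained shorter types
(8mer > 7mer-m8/7mer-A1 > 6mer) so loci are not double-counted; the
collapse is a flag. A gene is a predicted target when it carries at least
one site at or above the configured minimum type (7mer-m8 by default — the
weakest type the synthetic generator plants, and a common working
definition of a confident canonical site). No conservation filtering or
context scoring is attempted: predictions here are exact-match arithmetic,
which is what makes them fully testable against sliding-window oracles.

# Anticorrelation ranking

"Negatively correlated target" is operationalized as *sign opposition of
significant calls*: for a downregulated miRNA, predicted targets that are
significantly up, and vice versa. With five samples per group a per-gene
sample-wise correlation coefficient would be a different (and much noisier)
analysis; sign opposition of independently thresholded calls is what a
cross-referencing of DE lists computes, and it is the only mode offered.
Cluster scores aggregate members by the **union** of their anticorrelated
gene sets — shared targets count once, making the cluster score
sub-additive — with a `sum` mode available only for sensitivity analysis.
Unclustered miRNAs compete as singleton pseudo-clusters. Ties are broken
deterministically: larger mean |miRNA log2 fold change| first, then
lexicographic id.

# Seed-hexamer enrichment

For each DE miRNA the single seed hexamer (reverse complement of mature
nucleotides 2–7) is counted — overlapping occurrences included — in the
3′UTRs of the upregulated list and of the *non-regulated* list (genes not
significant at the same thresholds, not merely "not up"). The two count
vectors are compared by a one-sided Wilcoxon rank-sum test (alternative:
regulated counts stochastically greater), with mid-rank tie correction but
no continuity correction — counts are heavily tied at small integers, and
the tie-corrected statistic without continuity is the convention adopted
here; the null calibration test verifies the resulting p-values hold their
nominal level. Ranking is by −ln *P*. The DE-miRNA input list for this
stage uses the Wilcoxon DE test at p ≤ 0.05, keeping the enrichment ranking
methodologically independent of the moderated-t calls used elsewhere. Only
the one seed hexamer per miRNA is tested; a full 4,096-hexamer walk is out
of scope.

# ΔΔCt quantification

Per sample, $\Delta Ct = Ct_{target} - Ct_{ref}$;
$\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{control}$ (normalization
to the control-group mean, not pairwise matching — the two differ only in
the dispersion of the result, noted here because conventions vary); the
per-sample fold is $2^{-\Delta\Delta Ct}$ with amplification efficiency
fixed at 2. Group summaries report $2^{-\overline{\Delta\Delta Ct}}$ — so the
control group's fold is exactly 1 by construction — with the s.e.m. taken
over per-sample folds, matching the mean ± s.e.m. presentation such fold
changes conventionally receive.

# The synthetic generator

`sim_config()` defines a two-group microarray experiment with 5 arrays per
group, one planted 3-member genomic cluster (the miR-23b/miR-24/miR-27b
mature sequences) downregulated by −1.5 log2, and 10 disjoint planted target
genes per member upregulated by +1.0 log2, under i.i.d. Gaussian noise of
sd 0.25 on the log2 scale (equivalently, multiplicative log-normal intensity
noise; no array effects). Where a quantity is not dictated by that design,
a value was chosen once and kept: 60 miRNAs and 600 genes (large enough for
stable empirical-Bayes and permutation machinery, small enough for
hundred-replicate studies on one core), UTR lengths uniform on 200–600 nt at
GC 0.5, and one 7mer-m8 site per planted target written over background at a
uniformly random non-overlapping position (UTR length preserved). All
randomness is Mersenne-Twister, split deterministically from one master seed
per stage, so generation is byte-identical under a fixed seed.

What the generator does **not** emulate — probe-level effects, dye bias,
array batch structure, correlated genes, shared targets between cluster
members, longitudinal designs — bounds what passing tests show: they
demonstrate that the chain recovers planted signal of the stated magnitude
under clean two-group noise, not that it would do so on arrays with
unmodeled artifacts.

# Validation summary

The test suite checks, among others: exact agreement of the no-shrinkage
moderated t with the Student t (1e-10); agreement of the empirical-Bayes
fit with an independent reference implementation; the exact Wilcoxon path
against exhaustive label enumeration; the SAM FDR against brute-force
recounts on fully enumerable toys; site scanning and hexamer counting
against naive sliding-window oracles; type-I error of all three tests
within [0.03, 0.07] at nominal 0.05 on null simulations (100 runs of 1,000
features); perfect truth recovery at zero noise end-to-end; and rank-1
recovery of the planted cluster (and of a planted member's hexamer) in at
least 95 (90) of 100 default-condition replicates. Problem sizes in the
suite — 1,000-sequence oracle sweeps, 100-replicate recovery studies — are
the package's chosen desk-scale study sizes; rates and tolerances are fixed
properties of the methods, not tuned quantities.

# Known limitations

* Target prediction is exact canonical seed matching: no conservation,
  context scores, 3′-supplementary pairing, or non-canonical sites; counts
  are therefore not comparable with scored predictors' lists.
* SAM's π0 and FDR estimators are the simple median-count forms given
  above; other implementations differ in detail.
* The ANOVA post test multiplies pairwise equal-variance t p-values by the
  number of comparisons (classical Bonferroni), which is conservative.
* Paired or multi-class designs, array normalization and QC are out of
  scope; inputs are assumed complete (missing values are a hard error).
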