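---
title: "Models and methods behind sepalsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sepalsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepalsig)
```

`sepalsig` packages the statistics used to ask whether a hormone's
signaling level differs between two genotypes of developing *Arabidopsis*
flower buds, and whether the four sepals of a bud grow at coordinated
rates. This vignette explains each model, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical decisions taken where more than one convention exists.

## The transcript-fraction statistic

The core primitive is deliberately simple: for a cell with raw counts
$x_g$ and a gene set $S$, the percentage of the cell's transcripts that
originate from $S$,
$$f_S = 100\,\frac{\sum_{g\in S}x_g}{\sum_g x_g}.$$
No normalization is applied — the statistic is already a within-cell
composition, invariant to sequencing depth. Unknown gene ids in a set are
dropped with a warning rather than an error, so published set lists
containing genes absent from a given reference still run. A cell with zero
total counts is an error that names the barcode, because a silent 0/0
would propagate as a plausible-looking value.

The biological reading: if a hormone's signaling is higher in one
genotype, the fraction from that hormone's up-regulated response genes
should be higher there and the fraction from its down-regulated genes
lower. `infer_direction()` encodes exactly this two-sided logic, calling a
change *strong* only when both sets shift significantly in concordant
directions and *weak* when only one does; conflicting significant shifts
are *inconclusive* rather than majority-voted.

## Contrasts and multiple testing

Per (cluster × set), genotypes are compared with a two-sided Wilcoxon
rank-sum test over per-cell fractions. Cells, not replicates, are the test
units; a replicate-aware mode is deliberately out of scope. The test is
exact (full enumeration of the rank-sum null) when the combined sample
size is at most 20 and there are no ties, and otherwise uses the normal
approximation with tie-corrected variance and continuity correction. The
switch point keeps the exact branch exhaustively testable: the suite
compares it against an independent `combn()` enumeration for every small
tie-free configuration.

Two Bonferroni families coexist, both counted from the inputs rather than
hard-coded. The dot-plot significance threshold divides $\alpha$ by
(number of clusters × number of sets) — with 17 clusters and 12 hormone
sets at $\alpha=0.05$ this is $0.05/204 = 0.000245$. Star annotations on
per-cluster violin-style comparisons divide the base levels
$(0.05, 0.01, 0.001, 0.0001)$ by the number of clusters only — with 17
clusters, $0.00294$, $0.00059$, $0.000059$, $0.0000059$. Reporting both
families explicitly (as attributes of the contrast table) avoids the
ambiguity of a single unexplained threshold. P-values are never clipped;
the dot size statistic $\log_{10}(1/p)$ is 0 at $p=1$. A cluster with
fewer than two cells in either genotype yields a row with $p=1$ and a
warning instead of being dropped, so the output table always has the full
(cluster × set) grid.

## Cell QC and the cell-cycle variance filter

Cells are retained when the detected-gene count (genes with count > 0)
lies strictly between 600 and 6000 and the mitochondrial and chloroplast
transcript percentages are strictly below 10 and 20. All four inequalities
are strict, reading "greater than 600 but less than 6000" literally and
applying the same convention to the organelle rules, where the wording
does not settle it; the choice only matters on exact boundary values.

Phase scoring reimplements the standard binned-control module score: genes
are ranked by mean log-normalized expression (natural log of
$1 + 10^4\,x_g/\sum x$) and cut into `n_bins = 24` equal-frequency bins;
each target gene contributes `n_ctrl = 100` control genes sampled from its
bin (excluding targets, with replacement when a bin is small); the score
is the mean target expression minus the mean over all drawn controls, per
cell. Both parameters are exposed; the defaults are the de-facto standard
of the single-cell ecosystem. Control sampling is seeded and the seed is
recorded in the outputs. The phase call is G1 when both scores are
non-positive, otherwise the larger score's phase, with the measure-zero
positive tie resolved deterministically to S.

The variance filter computes, per gene, the one-way ANOVA
$R^2 = SS_\text{between}/SS_\text{total}$ of log-normalized expression
grouped by phase, and deletes genes with $R^2 > 0.03$ (strictly, so a gene
at exactly 3% survives) along with all mitochondrial genes. $R^2$ is
computed on the log-normalized scale; raw-count $R^2$ would be dominated
by library-size variation. A constant gene returns $R^2 = 0$ rather than
0/0. The per-gene report records every $R^2$ and the removal reason, so
the filter is auditable.

## Spatial spots

Deconvolution itself is an input, not an implementation: the package
consumes a spots × clusters prediction-score matrix and implements the
downstream logic. `best_cluster()` takes the per-spot argmax, resolving
ties to the lowest cluster label in sort order (logged) and labeling
all-zero rows "unassigned"; unassigned spots are kept and counted.
Proportion summaries omit clusters with fewer than 10 spots in either
genotype but keep all spots in the denominators, so reported proportions
are fractions of all spots — the convention that makes proportions
comparable across genotypes with different spot totals. Capture-area QC
flags an area whose median spot mitochondrial percentage exceeds twice the
median of the other areas' medians; the factor is a parameter because the
original decision is inherently visual.

## Reporter ratios

The BES1/H2B ratio divides a nucleus's BES1 signal by its constitutive H2B
signal, cancelling nuclear size and imaging depth. Per sepal, the summary
is the mean ratio and its coefficient of variation using the sample
($n-1$) standard deviation — per-sepal nucleus counts are small enough
that the denominator convention matters, and the choice is recorded in the
output header. Sepals with fewer than 5 nuclei are dropped (a CV from 2–4
nuclei is mostly noise); the floor is a parameter. Group comparisons run
the same Wilcoxon machinery on per-sepal values, overall and stratified by
sepal position.

## Growth coordination

From per-sepal area series $A(t)$, absolute growth per consecutive
observed interval is $A(t_1)-A(t_0)$, with no interpolation. Negative
deltas are clamped to 0 and flagged: sepal areas at these stages grow
monotonically, so shrinkage indicates a segmentation error, and letting
negative increments into the contribution denominator could push other
sepals' shares above 1. Contributions are increment shares and sum to 1
whenever total growth is positive. Outer/inner area ratios merge two inner
sepals into one before dividing, making the ratio invariant to how the
inner area happens to be split — the alternative (averaging two ratios)
inflates the statistic. Per-cell growth ratios keep the raw value and add
a display column clamped to $[0, 2.5]$, matching the conventional
heat-map range, so no information is lost to the display convention.

For noiseless exponential growth at rate $g$, the increment over
$[t_0,t_1]$ is $A_0(e^{gt_1}-e^{gt_0})$; `exp_growth_contributions()`
provides this closed form as the analytic reference against which
estimated contributions are validated to $10^{-9}$.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with recorded
ground truth. Its defaults define the study conditions used throughout the
tests and the acceptance script.

**Single cells.** Counts are multinomial given a log-normal library size
(log-mean $\log 5000$, log-sd 0.25) — chosen over per-gene negative
binomials because the multinomial models the *fraction* statistic under
test directly, with per-cell totals conserved by construction; optional
overdispersion is unnecessary for the properties being checked. Each
cluster has its own baseline profile (gamma background with a 3× marker
block); phase genes are multiplied by 3 in matching-phase cells; each cell
carries a latent hormone level $h\sim N(\mu_{gc}, 0.3)$, and a hormone
with slope $\beta$ scales its up-set by $1+\beta h$ and its down-set by
$\max(0.05, 1-\beta h)$ — the 0.05 floor keeps rates positive when
$\beta h > 1$. Organelle genes are carved out at expected fractions 3%
(mito) and 5% (chloroplast). Default sizes (1000 genes, 3 clusters,
100 cells per genotype per cluster, six hormones × 30 up + 30 down genes)
keep a full simulation-plus-pipeline run under two minutes on one CPU;
the calibration and recovery analyses state their own sizes (e.g.
150 cells per genotype per cluster — 300 per cluster — for effect
recovery; 240 genes × 160 cells for the 200-replicate null). Effect sizes
are chosen for testability: no effect-size estimates exist for the latent
signaling differences, so the planted shift ($\Delta\mu=1$, $\beta=0.2$,
a ~20% fraction shift) is set large enough that recovery failures indicate
bugs, not power limits.

**Spots** are Dirichlet mixtures (concentration 0.6, so most spots are
dominated by one cluster) of freshly drawn cluster profiles with Poisson
counts; prediction scores are the true weights resampled through a
Dirichlet with concentration 50 (infinite concentration gives noiseless
scores). **Nuclei** draw per-group log-normal ratios parameterized exactly
by the target mean and CV (WT 1.0/0.20 vs mutant 1.3/0.35, 20 sepals ×
50 nuclei per group). **Growth** uses exponential trajectories at rates
(outer 0.06, inner 0.02, laterals 0.03) per hour from equal 100 µm²
initial areas, observed every 12 h with 2% multiplicative log-normal
measurement noise.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: ambient RNA and doublets, UMI saturation
and gene-length effects, overdispersion beyond multinomial sampling,
spatial autocorrelation between neighboring spots, segmentation errors in
nucleus tables, and biological between-sepal variance beyond sampling
noise. The suite validates the *statistics*, not the biology: it shows the
pipeline recovers known planted structure at the stated sizes and stays
calibrated under the null, which is the property a reader needs before
trusting the same machinery on real measurements.

## Determinism and numerical edge cases

A single integer seed drives every generator, with per-component
sub-streams derived by fixed offsets, and identical seeds yield
byte-identical outputs (tested). Wilcoxon inputs where every value is tied
return $p=1$ explicitly rather than a 0/0 z-score. Every CSV the pipeline
writes starts with a comment header recording package version, seed and
the key parameters of the producing stage.

## Known limitations

Dataset-scale published numbers (total cell counts, specific cluster
proportions, figure p-values) depend on data that is not deposited at
preprint stage and are outside what a synthetic study can or should
reproduce; the package targets the *rules* — thresholds, test families,
summary definitions — which are fully specified and fully testable. The
replicate structure is carried but unused in testing (cells are the
units); spatial geometry is recorded as 0-based array indices with no
hexagonal-distance computation; and the pipeline orchestrator runs the
synthetic study only — real datasets are analyzed by calling the stage
functions directly, as the `analysis/` scripts do.
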