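---
title: "Methods: chromatin-state segmentation and state-stratified transcriptome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-state segmentation and state-stratified transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its models, the choices behind
them, and what the simulation-based evidence does and does not establish.
It is written for a reader who wants to judge the methods, not just call
them.

# The scientific setting

Terminally differentiated β cells keep their identity by active
chromatin maintenance. Two failure signatures track β-cell dysfunction
across mouse models and human type 2 diabetes: genes embedded in
*bivalent* Polycomb domains (H3K4me3 and H3K27me3 double-positive,
DNA-methylation-low, transcriptionally quiescent) become ectopically
active, and a small class of lineage-defining genes with exceptionally
broad active domains loses expression. Detecting either requires (i) a
genome segmentation that summarizes many chromatin marks plus DNA
methylation into discrete states, (ii) gene-level state assignments, and
(iii) expression statistics stratified by those states across single-cell
clusters, disease conditions, and a continuous glycemic trait (HbA1c).
This package implements that full intersection, with a synthetic-data
generator that makes every stage testable against known truth.

# Chromatin-state segmentation

## Signal representation

The genome is tiled into fixed 200 bp bins (`genome_bins()`), the
resolution at which promoter-scale chromatin features resolve without
fragmenting domains. Fragments are assigned to the unique bin containing
their midpoint (`bin_signal()`), which guarantees each fragment is
counted once; replicate tracks are averaged element-wise and rounded.
Rounding here and in the methylation channel is half-up
(`floor(x + 0.5)`): base R's round-half-to-even would make tie values
platform-honest but surprising in a count channel.

## The methylation channel

Per-CpG %methylation is converted to a count-like channel
(`transform_methylation()`): for each bin, the median %methylation of
CpGs in a 600 bp window centered on the bin (stepped by the 200 bp bin
size), inverted and scaled,

$$v_i = \left\lfloor s\,\frac{100 - \mathrm{median}_i}{100} + 0.5 \right\rfloor,
\qquad s = 10 .$$

Inversion makes *accessible* (lowly methylated) chromatin score high, so
the channel behaves like the mark counts it sits next to; most of a
mammalian genome is highly methylated, so most bins score 0–2. The scale
constant is a free choice (only "inverse scaling" is inherent to the
method); 10 gives integer values commensurate with per-bin mark counts at
typical sequencing depth, and it is exposed as an argument. Windows with
no CpG default to 0 — the high-methylation background — rather than to a
missing value, because CpG-free windows are overwhelmingly in methylated
intergenic space; `missing-as-median` would instead invent accessibility
where there is no evidence.

## Emission model and EM

Per-bin channel counts are overdispersed and correlated through the bin's
total occupancy. The default emission is therefore a per-state *negative
multinomial*: the channel total $t$ of a bin in state $k$ is negative
binomial with mean $\mu_k$ and dispersion $\theta_k$, and is split across
the $C$ channels multinomially with state proportions $\mathbf p_k$:

$$P(\mathbf x \mid k) \;=\; \mathrm{NB}(t;\,\mu_k,\theta_k)\,
\binom{t}{x_1\cdots x_C}\prod_c p_{kc}^{\,x_c}, \qquad t=\sum_c x_c .$$

An independent-Poisson-per-channel emission is selectable
(`emission = "poisson"`) for cheap fits and exact M-steps.

Fitting is Baum–Welch EM. The E-step uses a scaled forward–backward
recursion with per-bin stabilization of emission log-densities (long
tracks underflow otherwise; a bin impossible in all states yields the
documented `-Inf` sentinel). The M-step is closed-form for
$\pi, A, \mathbf p_k, \mu_k$; $\theta_k$ maximizes the weighted NB
likelihood by one-dimensional optimization over $\log\theta$, which keeps
the EM ascent property intact — the per-iteration log-likelihood trace is
stored and asserted non-decreasing (slack $10^{-6}$ relative) in every
test fit. Initialization is k-means on `log1p(counts)`; EM has local
optima, so three seeded restarts are run and the best kept. Convergence
is relative log-likelihood change below `tol` (default 1e-6) or
`max_iter`.

Decoding defaults to posterior mode (argmax of forward–backward
marginals): downstream statistics are per-bin (state coverage fractions),
so per-bin marginal accuracy is the right objective; Viterbi is available
when a single coherent path is wanted. Argmax ties break to the lowest
state index, for determinism. Both decoders are verified against
exhaustive path enumeration on small instances (≤ 8 bins, K ≤ 3, 1e-8).

State labels ("A" active, "M" bivalent, "S" silent) are *annotations*,
attached by the analyst from the emission summary (`emission_summary()`),
exactly because a fitted HMM's state indices are arbitrary. The
`analysis/02_segment.R` driver shows the rule used here: the
H3K4me3·H3K27me3 double-positive state is M, the H3K27ac-maximal state is
A.

# Gene-state assignment and signal features

Gene models come from GTF (1-based closed, converted to 0-based half-open
internally), filtered to the "basic" tag, biotypes
protein-coding/lincRNA/antisense, and autosomes. Each gene's state
coverage vector weights partially overlapped bins by overlap bp — without
this, short genes would inherit bin-phase artifacts. The genebody state
is the coverage argmax (ties to the lowest state index, documented and
tested on constructed 50/50 cases); the TSS state is the state of the bin
containing the TSS (minus-strand TSS = interval end − 1).

Peak breadth is the called peak's end − start; a gene's TSS-associated
breadth is the *widest* peak overlapping TSS ± 500 bp. The association
window is a package default (configurable): TSS-proximal association
needs some window, 500 bp spans the promoter-proximal nucleosomes, and
the widest-peak rule is the natural reading of "breadth" when several
peaks touch the window. Ranks are descending with ties sharing the
minimum rank, and the top-2% set takes `ceiling(0.02 n)` genes after
removing excluded names (expression outliers such as the insulin genes),
so an exclusion inside the slice pulls in the next-ranked gene.

TSS area-under-curve sums per-bp signal over TSS ± 100 nt and scales by
$10^6/\text{library size}$ (counts per million), making the quantity
invariant to joint rescaling of coverage and depth. Per-bp rather than
binned signal is used because a ±100 nt window holds only one bin.
Metagene profiles rescale each genebody to a fixed number of positions,
keep flanks in fixed bp bins, reverse minus-strand genes, and average;
genes shorter than the body grid are linearly interpolated (logged).

# Single-cell statistics

Normalization is downsampling without replacement to exactly 5,000
transcripts per cell; cells below the target are removed rather than kept
unnormalized, because entropy and geneset means are only comparable at
equal totals. The per-gene downsampled expectation is
`count × target/total` (multivariate hypergeometric), verified to ±3%
over 1,000 seeds.

The cell–cell metric is `1 − Spearman` over all retained genes
(average ranks on ties; a constant cell has no rank order, so its
distances are set to 1 with a warning). Clustering is k-medoids —
delegated to PAM (`cluster::pam`), the standard deterministic BUILD+SWAP
algorithm; because PAM is deterministic on a fixed distance matrix, the
seeded-restart scheme sketched for a randomized variant is unnecessary
and was dropped (the `seed` argument remains for interface stability).

Cluster number selection bootstraps cells with replacement, reclusters,
matches bootstrap to reference clusters by maximum overlap (exact
assignment via permutation enumeration at the small k used here), records
each reference cluster's mean Jaccard similarity, and selects the minimum
k with all clusters above 0.6, falling back to the k maximizing the
minimum Jaccard when none qualifies. A property of this rule worth
knowing: on *cleanly separated* simulated clusters, coarse merges (k
below the truth) are themselves highly reproducible under resampling —
deterministic reclustering of a bootstrap sample recreates the same
merge — so all small k pass the 0.6 bar and the minimum rule saturates at
the bottom of the range. The rule discriminates only when coarse
clusterings are genuinely unstable, which is the situation in real islet
data (where it selects k = 4) but not in well-separated synthetic blobs.
The package implements the rule as stated and reports the full per-k
Jaccard table so the analyst can see which granularities were stable.

Transcriptome entropy is $-\sum_g p_g \ln p_g$ over a cell's nonzero
gene fractions — natural log, no normalization by gene count. The
unnormalized nats form is the common "stemness" usage; ln G is the exact
upper bound (uniform cell), 0 the lower (single-gene cell), both asserted
exactly in tests. Outlier detection is out of scope by design: cluster
structure, not rare-cell discovery, is the target.

# State-stratified integration

Fig-style readouts are computed as:

- **CV per state × cluster**: each state gene's mean normalized
  expression over the cluster's cells, then sd/mean across those gene
  means (genes with zero mean in the cluster excluded and counted). The
  across-gene-means definition is the documented choice where the
  alternative (across cells) exists; it asks "how heterogeneous is this
  chromatin state's output in this cell state", which is the
  state-dysregulation question.
- **Condition differences** on log1p of normalized counts — UMI means are
  heavy-tailed and a log scale keeps single dominant genes from owning
  the statistic; antisymmetry under condition swap is tested.
- **Ortholog transfer** keeps only 1:1 pairs; 1:many and many:many pairs
  are dropped (counted), since a state label transferred through an
  ambiguous homology is not evidence.
- **Trait regression**: per-gene OLS slope of expression on the trait,
  summarized per state by the median member slope with a two-sided
  one-sample t test against zero and BH correction across states. The
  aggregation had to be chosen (only "slope and significance per state"
  is inherent); median + t test is robust to a few outlier genes while
  retaining calibrated size — the type-I error rate is verified at
  5% ± 2% over 1,000 null cohort replicates, and a slope planted only in
  bivalent-state genes at the study's cohort size (n = 62; 11
  diabetic-range and 51 normal-range trait values) is detected in that
  state only. When all member slopes are numerically identical
  (noiseless data) the t statistic is undefined; the degenerate case is
  resolved by evidence: p = 0 for a nonzero common slope, 1 otherwise.
- **Volcano counts** use strict inequalities at padj < 0.05 and
  fold change > 2 (or < 1/2); boundary genes are excluded, so a gene at
  exactly p = 0.05 never counts. The DE table itself is consumed, not
  computed — the upstream differential tests belong to dedicated tools.

# Pseudotime and SOM modules

Cells of a cluster chain are projected onto the link between their
cluster medoid and the adjacent chain medoid. The projection uses only
the distance matrix, via the law of cosines:
$t = (d_{ia}^2 + d_{ab}^2 - d_{ib}^2)/(2 d_{ab}^2)$. Reported
coordinates are clipped to [0, 1]; the *ordering* uses the raw
projection, so cells beyond a terminal medoid keep their relative order
instead of collapsing into a tie at the clip boundary. Link significance
is a permutation stand-in for the full lineage-inference scoring (which
is out of scope): the statistic is the number of cells of the link's two
endpoint clusters whose nearest inter-medoid segment is that link, and
the null shuffles cluster labels while keeping the observed
nearest-segment geometry fixed. Two design notes from building it: the
*unrestricted* nearest-segment count is useless as a statistic (the
counts partition all cells, so their total is conserved under any
relabeling), and recomputing medoids inside the permutation makes the
null degenerate (random label groups all have medoids near the data
median, producing pathological segment catchments). The conditional
endpoint-restricted count avoids both failure modes; p-values use the
add-one permutation estimator.

Genes with fewer than 3 transcripts in every cell are removed (boundary
inclusive: a single cell at 3 keeps the gene). Profiles are z-scored
across the ordered cells; constant genes are dropped with a warning.

The 1D SOM is the standard online algorithm: Gaussian neighborhood,
radius decaying linearly from n_nodes/10 to 1, learning rate 0.05 → 0.01,
`10 × n_profiles` presentations, seeded; codebooks are initialized by
linear interpolation between the two profiles at the extremes of the
first principal score, which orients the map and makes small-data fits
reproducible in substance, not just bit pattern. The full-scale analysis
uses 1,000 nodes for a ~15,000-gene transcriptome (roughly 10–20 genes
per node); the workflow and acceptance drivers scale the node count with
the simulated gene set (`n/10`, minimum 20) to keep that ratio — with
1,000 nodes over a few hundred genes, nearly every occupied node holds a
single noisy profile, pairwise correlations of node averages fall below
the merge threshold, and no module survives the size filter, which is a
statement about map granularity rather than about the data. Adjacent
occupied nodes merge when the Pearson correlation between the module's
*running average* profile and the node average exceeds 0.9 (the running
average gives chained merges a stable reference), and only modules with
strictly more than 5 member profiles are retained — a module with exactly
5 is discarded, which the tests pin down.

# The synthetic study

The generator's defaults are the study conditions, chosen once:

- **Genome**: one chromosome, 20,000 × 200 bp bins, three states
  (active A / bivalent M / silent S) with a 0.90/0.05 sticky transition
  matrix — domains of ~10 bins, long enough to hold genes. Mark means
  follow the biology (A: H3K4me3 20, H3K27ac 15, H3K36me3 10, Pol2 12;
  M: H3K4me3 15, H3K27me3 18, quiescent otherwise; S: ~1 everywhere);
  negative binomial with dispersion (size) 10, typical ChIP-seq
  overdispersion. Methylation means 20 / 5 / 85 % (bivalent domains are
  CpG-island-like and hypomethylated), CpGs Poisson-placed at 1 per
  50 bp so the 600 bp median window holds ~12 sites.
- **Genes**: 500 models, 70% placed wholly inside single-state runs
  (known truth), lengths 1–10 bins, strands random; a small fraction
  carries pseudogene biotypes or lacks the "basic" tag purely to
  exercise the loader's filters.
- **Cells**: ~300 cells, five clusters sized 30/28/18/12/12%. Clusters
  1–2 are mature (identity multiplier 1, bivalent 1), cluster 3
  intermediate (0.7 / 1.5), clusters 4–5 dedifferentiated (0.25 / 6 and
  0.2 / 8) and disease-enriched (HFD fractions 0.2/0.2/0.5/0.8/0.95).
  Each cluster also carries its own marker program (×12 on a disjoint
  slice of active-state genes, equalized baselines) — real β-cell
  sub-types are separable by distinct programs (e.g. the
  mitochondrial-high "hub" state), and without them clusters 1 and 2
  would be statistically identical and no clustering method could
  separate them. UMI counts are negative binomial (size 8) at a mean
  depth of 15,000, matching the reported per-cell transcript scale.
- **Cohort**: 62 samples, 11 with trait values above 6.5 and 51 below
  6.0 (the clinical HbA1c cutoffs), log-expression
  baseline + slope·trait + N(0, 0.5), slope 0.25 per trait unit for
  bivalent-state genes and 0 elsewhere.

What passing tests show — and what they do not: the simulation has
well-separated states and clusters, independent noise, no batch
structure, no doublets, no fragment-length or mappability artifacts, and
single-condition chromatin. Recovery there demonstrates correctness of
the computations and calibration of the tests, not performance on real
islet data, where state boundaries are soft, sub-types form a continuum,
and technical covariates exist. The cluster-number selection rule is the
clearest case: clean simulations are exactly the regime where its
minimum-k criterion saturates (see above).

# Numerical choices and degenerate inputs

Scaled probabilities are floored at 1e-300 and emission log-densities
row-stabilized before exponentiation; an all-zero track converges to a
degenerate model with a log message, not an exception. Argmax and rank
ties break deterministically (lowest index; shared minimum rank).
Internal coordinates are 0-based half-open everywhere; GTF is converted
on entry (1-based closed), bedGraph/BED are native. Problem sizes in the
tests and drivers (20,000 bins, 300–500 genes scaled to 800 for the
separability run, 1,000 null replicates) were chosen as the smallest
sizes at which the estimated quantities are stable to well within the
asserted tolerances.

# Known limitations

The HMM assumes a single chromosome per fit and homogeneous emission
parameters along the genome; multi-sample concatenated segmentation and
semi-supervised state definitions are out of scope. The link-significance
test is a documented stand-in, not the full lineage-tree scoring of
dedicated trajectory tools. The 25-state genome-scale fit of a real mouse
epigenome is beyond desk scale; the 3-state study preserves the
structure (active / bivalent / silent) that the downstream statistics
depend on.
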