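# epistate

Integrated epigenome–transcriptome analysis of chromatin-state-associated
transcriptional dysregulation, modeled on pancreatic β-cell
dedifferentiation in type 2 diabetes.

Loss of Polycomb (PRC2) silencing in β cells shows up as two coupled
signatures: ectopic activation of bivalent (H3K4me3 + H3K27me3,
DNA-methylation-low, transcriptionally quiescent) domains, and collapse of
expression at an epigenomically unusual class of broad-active-domain
lineage genes (Pdx1, Nkx6-1, Mafa, …). Testing for those signatures
requires machinery that spans three data modalities, all provided here:

- **Chromatin-state segmentation.** Binned histone-mark counts (200 bp
  bins) plus an inverse-scaled DNA-methylation channel — the median
  %methylation in a 600 bp window stepped by 200 bp, mapped to
  `round(10·(100−median)/100)` so accessible chromatin scores high — are
  modeled with a K-state hidden Markov model. Emissions are per-state
  negative multinomial: the bin's channel total is negative binomial with
  state mean μ_k and dispersion θ_k, split across channels by state
  proportions **p**_k. Fitting is Baum–Welch EM (k-means initialization,
  restarts, monotone log-likelihood); decoding is posterior-mode or
  Viterbi.
- **Gene-level features.** Genes (GTF; protein-coding/lincRNA/antisense,
  "basic" tag, autosomes) get a genebody state (maximum bp-weighted state
  coverage), a TSS state, TSS-associated peak breadth with descending
  ranks and a top-2% broad set, depth-normalized TSS ±100 nt
  area-under-curve, and strand-aware metagene profiles.
- **Single-cell statistics.** Downsampling normalization to exactly 5,000
  transcripts per cell, 1−Spearman k-medoids clustering (PAM) with
  bootstrap-Jaccard model selection (all clusters > 0.6), per-cell
  transcriptome entropy −Σ p·ln p, and geneset/cluster summaries.
- **State-stratified integration.** Per state × cluster coefficient of
  variation and disease-vs-control differences; per-state OLS regression
  of cohort expression on a continuous glycemic trait (median member-gene
  slope, one-sample t test, BH across states); volcano up/down counts at
  strict padj < 0.05 and |FC| > 2; marked-vs-unmarked fold-change shift.
- **Pseudotime modules.** Cells projected onto inter-medoid links of a
  cluster chain (law-of-cosines projection in the distance space, with a
  permutation test for link support), gene profiles z-scored along the
  ordering, a 1D self-organizing map, and modules from merging adjacent
  nodes with Pearson r > 0.9, retaining modules with more than 5 profiles.

A synthetic-data generator (`sim_spec()` and the `simulate_*()` family)
produces every input with known ground truth — hidden-state genome with
overdispersed mark counts and a methylation channel, gene models, a
five-sub-type UMI experiment with disease-enriched dedifferentiated
clusters, and a 62-donor cohort (11 diabetic-range, 51 normal-range trait
values) — so the whole pipeline is testable end to end without external
data.

## Worked example

The `analysis/` directory is the study as a numbered workflow; run the
scripts in order from the repository root (outputs land under `results/`):

```sh
Rscript analysis/01_simulate.R      # synthetic epigenome, cells, cohort
Rscript analysis/02_segment.R       # HMM segmentation + decoding
Rscript analysis/03_gene_states.R   # gene states, peak breadth, metagene
Rscript analysis/04_single_cell.R   # clustering, entropy, genesets
Rscript analysis/05_state_integration.R
Rscript analysis/06_trajectory_modules.R
```

Step 2 fits the segmentation and recovers the simulation truth:

```
EM converged after 3 iterations, logL = -270164
bin accuracy vs truth after label matching: 99.98%
  state label H3K4me3 H3K27ac H3K27me3 H3K36me3  Pol2 meth
1     1     M  15.030    2.01    17.90    0.994  2.00 9.30
2     2     S   0.998    1.00     2.00    1.002  1.02 1.80
3     3     A  20.142   14.86     1.01   10.028 11.92 7.92
```

The emission table is how states are annotated: state M is
H3K4me3/H3K27me3 double-positive with a high (= lowly methylated)
methylation channel — the bivalent signature; state A carries the active
marks; state S is quiescent and methylated.

Step 4 reproduces the disease readout at the cell level — the
dedifferentiated, HFD-enriched clusters 4–5 show higher entropy, elevated
bivalent-geneset expression and depressed identity-gene expression:

```
  cluster n_cells frac_hfd median_entropy rel_bivalent rel_identity
1       1      82    0.183           4.51        0.296        1.314
2       2      85    0.282           4.51        0.299        1.319
3       3      46    0.522           4.57        0.496        1.025
4       4      41    0.756           4.76        2.231        0.431
5       5      46    1.000           4.87        2.958        0.334
```

Step 5 localizes the trait effect to the bivalent state only
(slope 0.248 per trait unit, q ≈ 5e-116; states A and S null), counts a
strongly up-biased differential table (147 up / 0 down), and finds
Polycomb-marked genes shifted +1.16 log2 units — the loss-of-silencing
signature. Step 6 orders 218 cells along the 2-3-4-5 dedifferentiation
chain (all links significant at p < 0.05) and separates the rising
bivalent program from the falling identity program into distinct SOM
modules.

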