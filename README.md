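# regenecomp

Heart regeneration in zebrafish and tumor growth in humans share their
early transcriptional programs — proliferation, migration, altered
metabolism. `regenecomp` is an R package that implements, as tested and
reusable components, the comparative analysis such a study needs:

- **Synthetic study generator** — negative-binomial count simulation of
  a 10-timepoint cryoinjury time course (injured / sham / healthy) and
  a paired tumor–normal cohort with a repressive miRNA block, planted
  gene-set signal, ortholog map and TargetScan-like predicted-target
  table, all with recorded ground truth.
- **Count hygiene** — IQR-based ID de-duplication, CPM filtering, TMM
  normalization (via edgeR), `log2(CPM + prior)` expression, PCA QC.
- **Differential expression** — a moderated paired t on log-CPM with
  fixed-prior empirical-Bayes variance shrinkage, BH-FDR, the
  FDR < 0.01 & |log2FC| > 1 DEG rule with the <50-gene relaxation to
  FDR 0.05, and a tagwise NB dispersion fit.
- **Dynamic modeled control** — the per-timepoint reference is a blend
  of sham and healthy expression with sham weight `w(t) = exp(-t/tau)`,
  so the surgery effect decays out of the comparison.
- **Trajectory soft clustering** — fuzzy c-means (c = 5, m = 1.25,
  k-means++ restarts, monotone objective) on z-scored log2FC
  trajectories, with >70%-membership core genes.
- **Enrichment** — one-sided Fisher/hypergeometric over-representation
  for cluster cores (FDR < 0.1) and a Stouffer-combined paired
  gene-set statistic for cohorts (FDR < 0.01).
- **Term networks** — 98% gene-sharing de-duplication, 40%-sharing
  edges, `-log10 p` node sizes, GraphML/GEXF export.
- **Cross-condition comparison** — ortholog mapping (expand /
  first-match modes), up/down/ns significance matrices, Euclidean
  hierarchical clustering, concordance scores, early-vs-late tumor
  stage comparison on min–max-scaled `-log10` FDR.
- **miRNA–mRNA screen** — context-score filtering (< −0.2),
  direction-split Pearson anticorrelation (valid at ρ < −0.4,
  FDR < 0.05), hypergeometric merging of miRNAs with shared targets
  (FDR < 0.01), top-15 ranking, target-set enrichment (p < 0.01).
- **Pipeline driver** — `run_all()` executes every stage from one
  seeded configuration and writes a manifest of MD5 checksums that is
  byte-identical across reruns; a thin CLI lives in
  `inst/scripts/pipeline.R`.

The statistical core in symbols: counts are NB(μ, φ) with variance
μ + φμ²; the paired test is t = d̄ / √(s̃²/n) with
s̃² = (d₀s₀² + (n−1)s²)/(d₀ + n − 1); the modeled control mean is
w(t)·x̄_sham + (1−w(t))·x̄_healthy with w(t) = e^(−t/τ); fuzzy
memberships are u_gc = 1/Σ_k (d_gc/d_gk)^(2/(m−1)); enrichment is the
hypergeometric upper tail; and the miRNA merge edge between regulators
with a and b validated targets overlapping in k of N tested genes is
P(X ≥ k), X ~ Hypergeom(N, a, b).

## Worked example

```r
library(regenecomp)

cfg  <- sim_config(seed = 1, n_genes = 2000)   # the default study
tc   <- simulate_timecourse(cfg)
tc$counts
#> count_matrix: 2000 genes x 74 samples
#> healthy injured    sham
#>       4      40      30

cm   <- filter_low_expression(tc$counts)
fac  <- tmm_factors(cm)
traj <- timecourse_de(cm, fac, control_weights(cfg$timepoints, tau = 7))
degs <- union_degs(traj, fdr_cut = 0.01, lfc_cut = 1)
length(degs)
#> [1] 489

fit <- fuzzy_cmeans(zscore_rows(traj$log2FC[degs, ]), c = 5, m = 1.25, seed = 1)
fit
#> cluster_assignment: 489 genes, 5 clusters (m = 1.25, converged)
lengths(core_genes(fit, threshold = 0.7)$sets)
#> cluster_1 cluster_2 cluster_3 cluster_4 cluster_5
#>        95        96        96        94       100
```

489 of the 2000 genes are significant against the modeled control at
some timepoint (500 were planted); the five cluster centers recover the
five planted trajectory motifs, and 481 genes sit above the 70%
membership cutoff. The same session scales to the full pipeline:

```r
manifest <- run_all(run_config(seed = 1), "out/")
```

which writes counts, normalization factors, trajectories, memberships,
enrichment tables, the term network (GraphML/GEXF), the significance
matrix, concordance and dendrogram orders, the miRNA interaction
tables and a reproducibility manifest.

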