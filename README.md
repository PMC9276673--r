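# lumascore

Map normal breast **lu**minal single cells into a progenitor hierarchy and
**score** their differential-expression signatures against bulk breast-cancer
subtype expression profiles.

Normal breast luminal epithelium spans two anatomical sites — conducting
ducts and terminal duct lobular units (TDLUs) — and harbors a progenitor
hierarchy whose most immature, duct-enriched cells transcriptionally
resemble basal-like breast cancer. `lumascore` is a tested, reusable R
implementation of the computational pipeline behind that kind of analysis,
built for methodologists and analysts who want every stage to run and be
verified on synthetic data with planted ground truth rather than on
controlled-access patient data.

## What it computes

| Stage | Function(s) | Core method |
|---|---|---|
| Synthetic scRNA-seq | `simulate_cells()` | negative-binomial counts, planted cluster markers, donor effects, immune contaminant |
| Synthetic bulk reference | `simulate_reference()` | 6 subtype groups (n = 28/6/6/14/17/22), planted up/down signatures |
| Quality filtering | `filter_cells()` | 200–2000 detected genes, ≤ 10% mitochondrial counts |
| Normalization + PCA | `normalize_log()`, `embed_pca()` | library-size scaling, log1p, HVG PCA with fixed signs |
| Clustering + diagnostics | `cluster_cells()`, `cluster_entropy()`, `site_composition()` | Louvain on a kNN graph; normalized donor-mixing entropy; per-donor duct/TDLU contributions |
| Differential expression | `find_degs()` | one-vs-rest Wilcoxon rank-sum (tie-corrected, exact for tiny groups), Bonferroni, \|log2FC\| ≥ 0.1 and ≥ 1% expressing |
| Signature scoring | `signature_from_degs()`, `signature_from_genelist()`, `score_samples()` | inner product of log2FC (or ±1) weights with z-scored bulk expression |
| Subtype comparison | `compare_scores()`, `centroid_subtype()` | Kruskal–Wallis + Dunn's post-hoc; Spearman nearest-centroid calls |
| Trajectory | `build_mst()`, `infer_root_and_lineages()`, `fit_pseudotime()` | centroid MST, unsupervised central origin, principal-curve pseudotime |
| Orchestration | `run_pipeline()`, `report_fraction()` | end-to-end replay with one seed, TSV/MTX outputs |

The expression signature score of sample *j* for signature weights *w* is

```
s_j = sum over shared genes g of  w_g * z_gj
```

where `z_gj` is the gene's z-scored expression across reference samples; a
high log2FC together with high expression in a subtype yields a high score,
i.e. similarity between the cell population and that cancer subtype.

## Worked example

The replay pipeline simulates a luminal hierarchy (3 donors × 2 sites,
11 clusters plus a 0.7% immune contaminant), filters, clusters, scans
duct-vs-TDLU differential expression, and scores the resulting signatures
against a bulk reference in which the duct markers were planted as Basal
up-genes and the TDLU markers as LumA/LumB up-genes:

```r
library(lumascore)
m <- run_pipeline(pipeline_config(seed = 11))

m$n_significant_degs
#> [1] 410
m$min_entropy
#> [1] 0.9838
generics::glance(m$results$comparisons$duct)
#> # A tibble: 1 × 5
#>    kw_h kw_df     kw_p top_subtype n_pairs
#>   <dbl> <int>    <dbl> <chr>         <int>
#> 1  81.0     5 5.25e-16 Basal            15
round(m$results$comparisons$duct$medians, 2)
#>      Basal ClaudinLow       Her2     Normal       LumB       LumA
#>      52.20      25.87      22.90      12.59     -50.63     -51.90
```

Reading the output: 410 site-contrast genes pass the DEG thresholds
(Bonferroni-adjusted Wilcoxon p < 0.05, |log2FC| ≥ 0.1, ≥ 1% expressing);
every cluster mixes the three donors almost uniformly (minimum normalized
entropy 0.98, confirming integration); and the duct signature's scores are
highest in the Basal reference group (median 52.2, Kruskal–Wallis
p ≈ 5 × 10⁻¹⁶) and lowest in the luminal groups — the planted analogue of a
duct-progenitor/basal-like association. `autoplot(m$results$scores$duct)`
draws the per-subtype box plot, and `m$results$trajectory` holds the MST,
lineages and per-cell pseudotime.

## Documentation

The methods vignette (`vignettes/luminal-hierarchy-scoring.Rmd`) documents
the generative model, every tunable parameter with its default and
rationale, the numerical choices in the principal-curve fit, and what the
synthetic benchmarks do and do not demonstrate about real data.
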