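# neutrotime

Neutrophils do not mature through discrete subsets: single-cell
transcriptomes from bone marrow, blood and spleen order themselves along a
single chronological spectrum, from proliferating preNeu precursors to fully
mature circulating cells. **neutrotime** implements that analysis as a
tested, reusable R package: it derives the one-dimensional maturation
coordinate from droplet scRNA-seq UMI counts and extracts a closed-form gene
signature score that transfers the coordinate to any expression vector,
including bulk RNA-seq.

## The model

For QC-filtered, classifier-retained counts, `neutrotime()`:

1. selects highly variable genes (Pearson residual variance > 1.3 after
   regressing log counts on UMI count, S−G2M cell-cycle score and
   mitochondrial percentage),
2. computes 50 principal components and a cell–cell distance
   `D = 1 − Pearson` over the first 20,
3. builds a density-normalized diffusion map (local-bandwidth Gaussian
   kernel, α = 1),
4. anchors pseudotime at a preNeu root set via diffusion distance
   (components scaled by λ/(1−λ)) and rescales it to [0, 1], and
5. classes genes by Moran's I (≥ 0.2), mean expression (≥ 0.1) and Spearman
   correlation ρ with pseudotime into N₊ (ρ ≥ 0.2), N₋ (ρ ≤ −0.2) and N₀
   (|ρ| ≤ 0.1).

The signature defines the transferable score

```
neutrotime-S = ( Σ_{g∈N+} e(g) − Σ_{g∈N−} e(g) ) / Σ_{g∈N0} e(g)
```

(log-normalized expression for cells, raw counts for bulk), available as
`predict()` on the fitted object.

Around the fit, module functions cover the full published pipeline: cell and
gene QC (`compute_cell_qc`, `filter_cells`, `filter_genes`), hashtag-oligo
demultiplexing (`demux_hto`: CLR + k-means, positive quantile 0.999, seed
42), multinomial reference classification (`build_priors`,
`classify_cells`, `rollup_and_retain`), pairs cell-cycle scoring
(`train_marker_pairs`, `score_phase`), principal-curve and dip-test
trajectory diagnostics (`principal_curve`, `dip_test`), adaptive binning
(`adaptive_bins`), gene-dynamics clustering and trend smoothing
(`kmeans_gene_dynamics`, `smooth_gene_trend`), module scores
(`module_score`), Wilcoxon markers with Bonferroni gates
(`wilcoxon_markers`, `conserved_response`), moderated bulk differential
expression (`moderated_bulk_de`), and TF enrichment by Fisher's exact test
with mean-rank aggregation (`fisher_enrichment`, `mean_rank`,
`top_tf_selection`). A ground-truthed synthetic continuum generator
(`simulate_continuum`, `simulate_reference_profiles`, `simulate_hto`) makes
every stage testable without downloads.

## Worked example

```r
library(neutrotime)

cfg <- sim_config(seed = 1)                       # 2,000 cells, 500 genes
sim <- simulate_continuum(cfg)
ref <- simulate_reference_profiles(cfg)

qc  <- compute_cell_qc(sim$counts)
fc  <- filter_cells(qc)                           # 5% mito, 1st/99th pctile
counts <- sim$counts[, fc$keep]
counts <- counts[filter_genes(counts), ]          # >= 10 cells per gene

pri  <- build_priors(ref, rownames(counts))
keep <- rollup_and_retain(classify_cells(counts, pri)$assignment, pri)
counts <- counts[, keep]

expr   <- lognormalize(counts)
preneu <- module_score(expr, grep("^g_cycle", rownames(expr), value = TRUE),
                       seed = 1)
fit <- neutrotime(counts, tissue = sim$cells[colnames(counts), "tissue"],
                  root_cells = select_root(preneu, quantile = 0.99))
fit
#> Maturation continuum fit (neutrotime)
#>   1872 cells x 500 genes; 207 highly variable genes
#>   root set: 19 cells; pseudotime method: diffusion_distance
#>   signature: 62 positive / 63 negative / 23 stable genes
```

The fit recovers the simulation's latent maturation time and the
expression-space score reproduces the embedding-based coordinate:

```r
cor(fit$neutrotime, sim$cells[names(fit$neutrotime), "latent_time"],
    method = "spearman")
#> 0.977
scores <- predict(fit, expr)                      # neutrotime-S per cell
cor(scores, fit$neutrotime, method = "spearman", use = "complete.obs")
#> 0.976
dip_test(fit$neutrotime, n_boot = 2000, seed = 2)
#> dip = 0.0925, Monte-Carlo p = 5e-04    (multimodal cell density)
```

A Spearman correlation near 1 on the first line means the diffusion-map
pseudotime ordered the cells essentially as the generator made them; the
second line shows the 148-gene closed-form score carries the same ordering;
the dip test rejects a unimodal density along the axis — cells accumulate at
discrete maturation stages even though the underlying coordinate is
continuous. `plot(fit)` draws the per-tissue density curves (marrow early,
blood late, spleen broad); `coef(fit)` returns the per-gene table (ρ,
Moran's I, mean expression, class); `predict(fit, bulk, type = "bulk")`
projects bulk count profiles onto the same axis.

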