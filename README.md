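# modfinger

Module-fingerprint analysis of blood transcriptomes for disease-activity
profiling, built for studies like systemic lupus erythematosus (SLE) where
the question is not "patient vs healthy" but *active vs inactive disease*.

Whole-blood expression changes in SLE are organized into transcriptional
modules — named, co-expressed gene sets (interferon, neutrophil, plasma
cell, ribosomal, ...). Rather than interpreting a flat list of hundreds of
differentially expressed genes, the modular approach scores each module by
the **percentage of its member genes that are significantly up- or
down-regulated** between two clinical groups. The resulting fingerprint
(e.g. "97% of the interferon module up in high vs no activity") is compact,
comparable across cohorts, and robust to the noise that plagues
single-gene microarray signatures.

## What the package computes

Given a normalized, log2-transformed genes × samples matrix, group labels
and a GMT module collection:

1. **Moderated differential expression** (`moderated_t`). Per gene, the
   two-group statistic
   `t_g = (x̄_A − x̄_B) / (s̃_g √(1/n_A + 1/n_B))` with the empirical-Bayes
   posterior variance `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)` on
   `d₀ + d_g` df; the prior `(d₀, s₀²)` is estimated by the method of
   moments from the distribution of `log s²_g` across genes. Multiplicity
   is controlled by the Benjamini–Hochberg step-up rule (`bh_adjust`) at
   α = 0.05.
2. **Module fingerprints** (`module_fingerprint`, `fingerprint_grid`):
   directional significant-gene percentages per module, for one or several
   contrasts over the same module set.
3. **Minimal signatures** (`nsc_train`, `nsc_predict`, `nsc_cv`): nearest
   shrunken centroids with `d_ik = (x̄_ik − x̄_i)/(m_k(s_i + s₀))`,
   soft-thresholded at Δ; stratified cross-validation picks the Δ with the
   smallest misclassification error, fewest genes among ties.
4. **Clustering separation** (`cluster_samples`, `separation_score`):
   deterministic agglomerative clustering of samples on the DE genes
   (correlation distance, average linkage, pinned tie-breaks) and the
   "x of N activity samples separated" statistic under a k = 2 cut.
5. **Enrichment** (`hypergeometric_enrichment`): one-sided hypergeometric
   over-representation of a query list in user-supplied gene sets with
   Bonferroni (and BH) control.
6. **Synthetic cohorts** (`simulate_cohorts`, `make_paper_like_design`):
   seeded module-structured cohorts with planted truth — Gaussian log2
   noise with scaled-inverse-chi-square gene variances, per-group module
   shifts, optional batch term — so every stage above is verifiable
   offline. `run_pipeline` orchestrates all stages from one config with a
   content-hash manifest.

## Worked example

```r
library(modfinger)

sim <- simulate_cohorts(make_paper_like_design(seed = 42, n_genes = 1200))
dges <- list(
  high_vs_none       = moderated_t(sim$expr, sim$meta, c("high", "none")),
  typical_vs_healthy = moderated_t(sim$expr, sim$meta, c("typical", "healthy")))
sig <- significant_genes(dges$high_vs_none, 0.05)
length(sig$up); length(sig$down)
#> 156 up, 90 down DE genes at BH 0.05

grid_table(fingerprint_grid(dges, sim$modules, alpha = 0.05))
#>   module_id                    label high_vs_none.up high_vs_none.down
#> 1       IFN          Interferon-like              95               0.0
#> 2       NEU          Neutrophil-like              70               0.0
#> 3      RIB1         Ribosomal-like 1               0              75.0
#> 4      RIB2         Ribosomal-like 2               0              66.7
#> 5       PLA Plasma-cell-like (quiet)               0               2.5
#>   typical_vs_healthy.up typical_vs_healthy.down
#> 1                  95.0                     0.0
#> 2                  67.5                     0.0
#> 3                   0.0                    75.0
#> 4                   0.0                    66.7
#> 5                   0.0                     0.0
```

Read: 95% of the planted interferon-like module is significantly
up-regulated in both contrasts, the neutrophil-like module is up (its
planted effect is 1.2 log2 units in the activity contrast vs 0.5 in
disease-vs-healthy, but the latter's larger cohort compensates in power),
ribosomal-like modules go down, and the plasma-cell module stays quiet —
the qualitative pattern the generator plants.

```r
meta_hn <- sim$meta[sim$meta$group %in% c("high", "none"), ]
tree <- cluster_samples(sim$expr[, meta_hn$sample_id], c(sig$up, sig$down))
separation_score(tree, sim$meta, "high")
#> cluster_separation: 13 / 13 'high' samples in majority cluster 1 of 2

hypergeometric_enrichment(c(sig$up, sig$down), sim$modules,
                          rownames(sim$expr))[1:3, c(1, 3, 4, 6, 7)]
#>   set_id  p_value q_bonferroni hit_count_query hit_count_genome
#> 1    IFN 4.91e-66     2.45e-65              95              100
#> 2    NEU 2.56e-23     1.28e-22              56               80
#> 3   RIB1 1.07e-20     5.37e-20              45               60

nsc_cv(sim$expr[, meta_hn$sample_id], meta_hn, n_folds = 10, seed = 42)
#> nsc_cv: 10 folds, 30 thresholds; chosen delta = 7.742 (17 genes, 0 CV errors)
```

## Command line

```sh
inst/exec/modfinger simulate --seed 1 --out-dir sim/
inst/exec/modfinger dge --expr sim/expr.tsv --meta sim/meta.tsv \
    --contrast high,none --alpha 0.05 --out dge.tsv
inst/exec/modfinger fingerprint --dge dge.tsv --modules sim/modules.gmt \
    --out fp.tsv
inst/exec/modfinger run --config run.json
```

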