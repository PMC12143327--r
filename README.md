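# eqtlgrowth

Connecting the genetics of gene expression to the genetics of growth in a
panel of haploid yeast segregants.

In a large BY x RM yeast cross, every fully genotyped segregant has both a
baseline transcriptome (expression of thousands of genes, measured once in a
common condition) and endpoint colony growth in dozens of environmental
conditions, measured in an independent experiment. Because the two data sets
share nothing but the segregants' genotypes, a correlation between a
transcript and a growth trait across segregants — a *genetic correlation* —
reflects shared allelic effects. `eqtlgrowth` implements the statistical
pipeline that builds on this idea:

- **Genetic correlations** `r(gene, condition)` on batch/OD-corrected
  expression, with per-condition Storey q-values
  (`genetic_correlations()`, `correct_expression()`, `storey_qvalue()`);
  base-medium correction, growth-trait PCA, and panel-size downsampling.
- **QTL effect correlations**: per-locus effects on the correlation scale
  with Fisher-z CIs (`marker_effect()`), combined across a gene's eQTLs by a
  weighted Pearson coefficient with inverse CI-width-product weights
  (`weighted_pearson()`, `qtl_effect_correlations()`).
- **Trans-eQTL hotspot analysis**: forward-stepwise hotspot effect vectors
  (`stepwise_effects()`), hotspot effect correlations
  (`hotspot_effect_correlations()`), and random-marker-set nulls.
- **Interval overlap statistics** between gQTLs, local eQTLs, and hotspots
  with a random non-overlapping placement null (`count_overlaps()`,
  `random_interval_null()`, `binned_cooccurrence()`).
- **Pleiotropy versus linkage**: a bivariate one-QTL vs two-QTL scan with
  unstructured residual covariance, parametric-bootstrap p-values, and
  profile LOD curves (`pleiotropy_test()`, `candidate_pairs()`,
  `thin_markers()`). p > 0.05 means a single pleiotropic QTL cannot be
  rejected.
- **Marker-set heritability**: single-component REML on a GCTA-style
  relatedness matrix, h2 = sigma2_g/(sigma2_g + sigma2_e) profiled to a 1-D
  optimization after eigen-rotation, with parametric-bootstrap SEs
  (`build_grm()`, `reml_h2()`, `marker_set_variance_suite()`,
  `incremental_hotspot_variance()`).
- **Sources of genetic correlations**: joint regression of marker sets out
  of both expression and growth, recomputation and paired-Wilcoxon
  comparison (`regress_out()`, `recompute_correlations()`,
  `compare_correlations()`).
- **Mediation**: the linear two-equation decomposition with proportion
  mediated `alpha*gamma / (beta + alpha*gamma)` and nonparametric-bootstrap
  inference (`mediate()`, `mediation_screen()`).
- **Signed enrichment and trait clustering** (`signed_enrichment()`,
  `cluster_traits()`, `signature_means()`), with GMT gene-set input.
- **A synthetic segregant panel** with linked markers, hotspots, local
  eQTLs, nuisance covariates, and a complete ground-truth record
  (`sim_config()`, `simulate_genotypes()`, `simulate_panel()`), plus an
  orchestrated pipeline (`run_pipeline()`) writing TSV outputs and a
  checksum manifest.

## Worked example

```r
library(eqtlgrowth)

panel <- simulate_panel(sim_config(
  n_segregants = 500, n_chromosomes = 4, chr_length = 200000,
  markers_per_chrom = 40, n_genes = 100, n_conditions = 8,
  n_hotspots = 12, seed = 42))

expr <- correct_expression(panel$expression,
                           panel$covariates$batch, panel$covariates$od)
gc <- genetic_correlations(expr, panel$growth, fdr = 0.05)
head(gc[order(gc$q), ], 3)
#>         gene condition          r   n            p            q significant
#> 615 gene0015    cond07 -0.5173807 470 1.548455e-33 7.862145e-32        TRUE
#> 633 gene0033    cond07  0.5101927 470 1.643420e-32 4.172161e-31        TRUE
#> 588 gene0088    cond06 -0.4443248 480 1.210096e-24 4.204766e-23        TRUE
sum(gc$significant)
#> [1] 219
```

`gene0015` is negatively genetically correlated with growth in `cond07`
(r = -0.52 across 470 segregants with both measurements): segregants whose
RM alleles raise that transcript tend to grow worse in that condition. 219
of the 800 gene-condition pairs are significant at 5% FDR on this panel.

How much of a condition's heritable variation sits at the hotspot loci?

```r
hot <- panel$hotspots$peak_marker
suite <- marker_set_variance_suite(panel$growth, panel$genotypes, hot,
                                   n_random = 50, seed = 1)
subset(suite$estimates, condition == "cond01")
#>   condition         set        h2 se   n
#> 1    cond01 all_markers 0.2291792 NA 468
#> 9    cond01    hotspots 0.2615282 NA 468
suite$p_hotspot[["cond01"]]
#> [1] 0.22
```

All markers explain 23% of growth variance in `cond01` and the 12 hotspot
peak markers alone capture essentially all of it — but on this small panel
22% of size-matched random marker sets do as well (linkage is long), so the
hotspot signal for this single condition is not individually significant.

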