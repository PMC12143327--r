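---
title: "Integrating eQTL and growth-QTL maps in a yeast segregant panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating eQTL and growth-QTL maps in a yeast segregant panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a large cross between two budding-yeast strains (a laboratory "BY" strain
and a vineyard "RM" strain), every haploid segregant carries a mosaic of the
two parental genomes and is fully genotyped. Two kinds of quantitative-trait
maps exist for such panels: eQTLs, loci that change the expression of
individual genes measured in a common baseline culture, and gQTLs, loci that
change colony growth measured across dozens of environmental conditions.
`eqtlgrowth` provides the statistical machinery to connect the two maps: if
the same alleles move both a transcript and a growth trait, the transcriptome
measured in one experiment carries information about growth measured in
another, and the loci where those signals coincide point at regulatory
mechanisms of growth variation.

The package operates on four tabular inputs: a segregant-by-marker genotype
matrix coded BY = -1 / RM = +1 (so a positive trait-genotype correlation
always means the RM allele increases the trait), expression and growth trait
matrices, QTL tables (peak position, confidence interval, LOD), and a table
of trans-eQTL hotspots (loci whose trans effects touch dozens to thousands
of genes). A synthetic-panel generator reproduces the statistical structure
of such a cross with complete ground truth, so every stage of the pipeline is
testable without any external download.

## Genetic correlations

The elementary quantity is the **genetic correlation** between gene `g` and
condition `c`: the Pearson correlation of the (covariate-corrected)
expression of `g` with growth in `c` across segregants. Expression is first
residualized per gene on culture-batch indicator contrasts plus a linear
OD600 term; growth is used as measured. Because expression and growth come
from independent experiments on the same genotypes, shared environmental
variance is essentially excluded and the correlation is attributable to
shared alleles. Two-sided p-values use the t distribution with n - 2 degrees
of freedom on pairwise-complete observations (growth has missing values;
pairs with fewer than 3 shared segregants are skipped).

False-discovery control is per condition, with Storey q-values: pi0 is
estimated by the natural-cubic-spline smoother over the lambda grid
0.05-0.95 and the BH-style step-up is scaled by pi0. With fewer than 100
p-values, or when the smoother fails or returns a non-positive estimate, the
computation falls back to plain Benjamini-Hochberg (pi0 = 1); this keeps
small screens conservative rather than unstable.

Supporting operations mirror the rest of the correlation analysis: removal
of the base-medium component of each growth condition (simple regression of
the condition on its YNB or YPD base; conditions that *are* a base medium
are skipped rather than residualized against themselves), a growth-trait PCA
(traits measured in at least 20% of segregants, complete-case segregants,
standardized columns) to check for shared factors, and panel-size
downsampling (subsets without replacement, medians over replicates of the
number and magnitude of significant correlations).

## Effect correlations

A complementary view asks whether the *effects* of a gene's eQTLs on
expression are proportional to their effects on growth. Effects are
measured on the correlation scale at the QTL peak marker, with 95%
confidence intervals from the Fisher z-transform. For genes with at least 3
eQTLs, the two effect vectors are combined by a **weighted Pearson
correlation** with weights equal to the inverse of the product of the two
CI widths (widths floored at 1e-6), so precisely estimated loci dominate.
The p-value uses a t statistic with the unweighted number of loci minus 2 as
degrees of freedom — the conservative reading, since the weighted
correlation of n loci never carries more information than n observations.
This screen is run at a lenient 20% BH FDR per condition by default.

**Hotspot effect vectors** are built by a forward-stepwise scan over the
hotspot peak markers: at each step the residualized trait is correlated with
every unselected marker, the strongest correlation is recorded if its
p-value is below 0.05, the marker's contribution is regressed out, and the
loop stops when no marker reaches the threshold; unselected markers get
effect zero. One design choice deserves emphasis: the *selection* step uses
the ordinary correlation test on the current residual trait, but the
*recorded* effect is rescaled to the original trait's standard deviation
(`cov(residual trait, x) / (sd(original trait) sd(x))`). Successive residual
traits shrink in variance, so raw step correlations are inflated by
`1/sqrt(1 - r^2)` per preceding step and are not mutually comparable;
the common-scale effect removes that inflation and reduces exactly to the
marginal correlation when markers are orthogonal. The per-gene and
per-condition effect vectors are then correlated (unweighted Pearson over
the hotspot entries) to give the hotspot effect correlation, with BH FDR per
condition. Random marker sets of matched size provide the null reference.

## Interval overlap statistics

QTL and hotspot positions are compared as 1-based, inclusive intervals
([a,b] overlaps [c,d] iff a <= d and c <= b, the yeast annotation
convention). Significance of an overlap count uses a placement null:
intervals of the observed sizes are re-placed uniformly at random (each
entirely on one chromosome, chromosome chosen with probability proportional
to the number of valid start positions, mutually non-overlapping by
rejection sampling), and the empirical p is the fraction of replicates whose
overlap count matches or exceeds the observed one. Peak-level co-occurrence
uses fixed-width genomic bins (10 kb by default; half-open internally) and
Spearman correlation of the two genome-wide count vectors.

## Pleiotropy versus linkage

When a local eQTL and a gQTL overlap (padded confidence intervals, both
LOD >= 10), a shared causal variant is only one explanation; two distinct,
linked variants is the other. The package fits both: a **one-QTL model**
(both traits regressed on the same marker) and a **two-QTL model** (each
trait on its own marker, all ordered pairs scanned), each with an
unstructured 2x2 residual covariance estimated from residual cross-products.
Log-likelihoods are kept in log10 units, so the test statistic
`lrt = max log10 L2 - max log10 L1` is LOD-like and non-negative (the
two-QTL surface contains the one-QTL fit on its diagonal). Significance
comes from a parametric bootstrap under the fitted one-QTL model with the
`(1 + #exceedances)/(1 + n_boot)` estimator, which can never return zero. A
*large* statistic rejects the single pleiotropic QTL, so p > 0.05 is the
pleiotropy-compatible outcome; regions with fewer than 3 (thinned) markers
are reported untestable rather than given a p-value. Profile LOD curves
trace, for each trait, the two-QTL likelihood as its QTL moves with the
other trait's QTL fixed at the joint optimum, baselined at the one-QTL
maximum — a maximum profile LOD of zero means the two-QTL model found
nothing beyond the shared-QTL fit.

Markers are thinned before scanning (greedy left-to-right within
chromosome, keeping a marker only when its correlation with the last kept
marker is below 0.95) — in a one-generation cross adjacent markers are
nearly collinear and contribute nothing but run time.

The model is fixed-effects-only: no polygenic/kinship random effect is
included in the bivariate likelihood. This is the main modeling
simplification, made because the scan regions are short, the traits enter
the test already covariate-corrected, and the parametric bootstrap
calibrates the test against exactly the model that generated its null — the
package's own calibration checks (shared-cause simulations retain
pleiotropy in >= 95% of runs at nominal 5%) validate the choice on panels
with realistic linkage.

## Marker-set heritability

The fraction of growth variance explained by a marker set uses the standard
single-component mixed model `y = mu + g + e`, `g ~ N(0, sigma2_g K)`, with
the GCTA-style relatedness matrix `K = X X'/m` over standardized marker
columns. After eigendecomposition of K (restricted to observed segregants),
the restricted likelihood profiles down to a one-dimensional optimization
over `h2 = sigma2_g/(sigma2_g + sigma2_e)` on [0, 1], which is exact for one
variance component and immune to step-size issues. Standard errors come
from a parametric bootstrap run in the eigen-rotated basis. A case-resampling
bootstrap is *not* offered: with a relatedness kernel, a duplicated
segregant carries an identical phenotype together with a unit genetic
correlation, which drives every resampled fit to the h2 = 1 boundary — we
verified this empirically, and the parametric scheme also avoids one
O(n^3) eigendecomposition per resample. The study-scale setting is 5,000
bootstrap iterations; `n_boot = 0` (no SE) is the default so that large
random-set suites stay cheap.

The suite compares, per condition: all markers (total additive
heritability), the hotspot peak markers, optionally the condition's gQTL
peaks, and random marker sets matched in size to the hotspot set, from which
an empirical p (fraction of random sets reaching the hotspot h2) is
computed. The incremental analysis orders hotspots by how many genes they
affect and fits nested sets from the top two up to all hotspots; two markers
are the smallest estimable set under this scheme, each hotspot's fractional
contribution is the (floored-at-zero) increment of the curve, and the
smallest set sizes reaching 50% and 80% of the full-set h2 are reported.

## Sources of genetic correlations and mediation

To attribute genetic correlations to eQTL classes, the effects of a marker
set are removed from **both** expression and growth by one joint multiple
regression per trait (pivoted QR drops collinear columns; an empty set just
centers the trait), and correlations are recomputed on the residuals. The
comparison restricts to pairs significant before removal, reports the median
relative drop in |r| (pairs with |r| < 1e-6 before removal are excluded from
the median and counted), and tests the |r| distributions with a paired
two-sided Wilcoxon signed-rank test. Typical removed sets are each gene's
local peak(s), each gene's trans peaks, all hotspot peaks, and size-matched
random sets.

**Mediation** quantifies how much of a hotspot's growth effect flows through
one transcript, via the two-equation linear decomposition
(`mediator = alpha x + e1`; `outcome = beta x + gamma mediator + e2`), so the
total effect is `beta + alpha gamma` and the proportion mediated is
`alpha gamma / (beta + alpha gamma)`. The proportion is deliberately not
truncated to [0, 1]: suppression (out-of-range values) is reported as-is and
flagged, and the sign of the indirect effect is reported separately. The
two-sided p-value for the indirect effect comes from a nonparametric
bootstrap over segregants (`2 min(#{<=0}, #{>=0})` with +1 smoothing); when
the total effect is numerically zero the proportion is returned as NA with a
flag instead of an unstable ratio. The mediator is the batch/OD-corrected
expression — the pipeline's standard expression surface. Note the practical
floor of the smoothed bootstrap p, `2/(1 + n_boot)`: screens that must clear
a BH threshold need `n_boot` large enough for the floor to pass (the
study-scale setting of 1,000 bootstraps gives 0.002).

## Enrichment and trait clustering

Significantly correlated genes are split by correlation sign, and each gene
set is tested per direction with a one-sided hypergeometric (Fisher) test —
enrichment is the upper tail — against the background of all tested genes.
Fold enrichment is observed/expected with expected
`|list| |term in background| / |background|`. Terms passing p < 0.001 are
retained; a term significant in both directions keeps only the direction
with the larger |log2 fold|. Traits are clustered by k-means (k = 3 by
default, 50 restarts, seeded) on the conditions-by-terms matrix of signed
log2 folds with absent terms at zero; when k reaches the number of distinct
profiles each profile becomes its own cluster, the exact zero-within-SS
optimum. Signature averaging (mean correlation over externally defined gene
groups per condition) supports comparisons with published expression
signatures.

## The synthetic panel

`sim_config()` defaults describe the full-scale cross the pipeline targets:
1,000 segregants; 16 chromosomes with 720 markers each (11,520 markers at
~1 kb spacing); recombination probability 0.004 per marker interval, i.e.
adjacent-marker correlation ~0.99 (matching a dense one-generation cross in
which thinning at r < 0.95 retains roughly an eighth of the markers); 5,720
genes, half with a local eQTL; 102 hotspots; 46 conditions driven by ~30% of
hotspots plus two private loci each; 11 round-robin batches, lognormal
OD600, and unit-variance Gaussian noise. Genotypes follow a per-chromosome
Markov chain of Bernoulli crossovers (Haldane-like, no interference), which
reproduces the monotone LD decay the analyses face; crossover interference
is deliberately not modeled. Emitted QTL tables use the true causal markers
as peaks, confidence intervals of a configurable half-width, and LOD scores
computed from the realized marginal correlation as `-n log10(1 - r^2)/2`, so
LOD-threshold filters are exercisable. An optional `mediation` block routes
part of one hotspot's effect on one condition through realized transcript
levels of designated mediator genes (drawn from the hotspot's more strongly
affected targets, with effect magnitudes bounded away from zero) so that
mediation screens have a well-defined ground truth; it is off by default.

What the generator does **not** emulate: realistic regulatory networks
(hotspot targets are random gene sets), epistasis (all models here are
additive, as in the analyses themselves), sequence-level variation,
crossover interference, and heavy-tailed measurement noise. Passing tests
on this panel therefore demonstrate correctness of the estimators under the
assumed additive-Gaussian structure, not robustness to every property of
real expression data.

## Problem sizes used by the tests and the acceptance script

All checks are desk-scale by design; the sizes are the package's own
choices. Heritability recovery uses 1,000 segregants and 500 unlinked
markers with 20 (tests) or 10 (script) replicate traits per true h2 in
{0.2, 0.5, 0.8}. Null calibration uses a 250-segregant global-null panel
with 250 genes x 40 conditions (10,000 tests) for both genetic and
QTL-effect correlations, and 100 meta-replicates of the interval-placement
null at 200 placements each. Pleiotropy calibration and power use 500
segregants, one 30-marker chromosome (adjacent r ~ 0.84), 50 replicates per
scenario, 200 bootstraps. The architecture panel has 800 segregants, 160
markers on 4 chromosomes, 60 genes, 6 conditions and 16 hotspots with
strong hotspot effects; the mediation panel has 1,000 segregants, one
hotspot, 90 target genes of which 30 mediate with |gamma| in [0.4, 1.2] and
no local or private loci, so that non-mediator targets are conditionally
independent of growth given the hotspot genotype and the ground-truth FDR
measurement is uncontaminated by linkage.

## Numerical choices and degenerate inputs

Constant trait columns abort standardization with the column named;
constant markers are dropped from GRMs with a warning; a singular bivariate
residual covariance in the pleiotropy scan receives a 1e-8 ridge;
zero-width effect CIs are floored at 1e-6 before weighting; stepwise ties
in |r| resolve to the lowest marker index; the stepwise loop is asserted to
never exceed the number of markers; bootstrap p-values use +1 smoothing and
cannot be zero; REML optimization is bracketed on [0, 1 - 1e-6] with the
boundary fit at zero checked explicitly; eigenvalues are clamped at zero
with a relative PSD tolerance of 1e-6. Pipeline stages derive their seeds
from the global seed and the stage name, so inserting a stage does not
shift the random streams of the others, and identical configs reproduce
every output bit-for-bit.

## Known limitations

The pleiotropy likelihood omits a kinship random effect (see above); the
Storey smoother needs a few hundred p-values to be stable and silently
falls back to BH below 100; hotspot effect vectors depend on a relaxed
p < 0.05 entry rule and inherit its false-positive rate by design (the
hotspot list itself is assumed to come from a rigorous prior detection);
the interval-placement null does not preserve per-chromosome interval
counts (the placement text it implements makes no such promise); and the
synthetic panel's simplifications listed above bound what the recovery
tests can claim about real data.
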