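---
title: "Seascape genomics of coral metapopulations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seascape genomics of coral metapopulations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralscape)
```

`coralscape` implements a complete inference chain for seascape genomics of
reef corals: from a matrix of per-allele read counts and environmental
monitoring data to maps of putatively adaptive genetic variation, genetic
offset through time, and transplantation suitability. This vignette explains
the statistical machinery, the choices made where the design was open, and
what the synthetic test bed does and does not establish.

## The inference problem

Corals of a nominal species often comprise several *cryptic lineages* —
reproductively isolated groups indistinguishable in the field — that
partition the habitat, most conspicuously by depth. Within lineages, allele
frequencies may track environmental gradients (isolation by environment)
over and above the background correlation of genotype with geography
(isolation by distance). The analysis must therefore (i) discover the
lineages, (ii) remove clonal replicates and close kin that would distort
ordinations, (iii) quantify which environmental axes predict genetic
structure once geography and lineage admixture are controlled, and (iv)
project those associations across the seascape.

## Genetic distances and ordination

The unit of information is a `ReadCountMatrix`: per-sample, per-site counts
of the two alleles of biallelic SNPs (a hard genotype call is the special
case (2,0)/(1,1)/(0,2)). Sample and site filters follow the standard
reduced-representation conventions, with inclusive boundaries: samples need
at least a quarter of sites at 5x coverage; sites must be genotyped in at
least 75% of samples with pooled minor allele frequency at least 0.05. The
pooled frequency is the mean of per-sample allele proportions, so
high-coverage samples do not dominate it.

The identity-by-state (IBS) distance is deliberately model-free: for each
pair, one read is drawn per shared site from each sample and the distance is
the mismatch fraction. Because a heterozygous site mismatches itself with
probability 1/2, IBS has a positive floor set by heterozygosity; what
matters downstream is its between- versus within-group contrast, which is
insensitive to coverage differences. The sampling is one seeded RNG stream
with pairs processed in sorted-id order, so the distance is exactly
reproducible and replayable.

Relatedness is proxied by dosage allele sharing (mean fraction of alleles
shared per site, `1 - |g1 - g2|/2`): clones approach 1, unrelated individuals
in a balanced population sit near 0.625. This is a stated simplification —
the pruning rule only needs a similarity scale on which "more than 0.8
similar" identifies clonal or near-clonal redundancy. Pruning takes
single-linkage groups above the threshold (the automated counterpart of
inspecting a dendrogram) and keeps the highest-coverage member, ties broken
lexicographically.

Principal coordinate analysis is classical scaling of the IBS matrix; axes
with positive eigenvalues are kept and negative eigenvalues are dropped, not
corrected — the variance proportions are reported over the positive spectrum
so the omission is visible. On Euclidean-embeddable input this is an exact
isometry, which the tests verify.

## Lineage delineation

Four linkage methods (single, complete, UPGMA, Ward) compete on cophenetic
correlation with the original distances; the number of clusters is chosen by
mean silhouette width, with the membership-matrix Mantel correlation as the
second criterion. Decisions the source procedure leaves open are fixed here:
singleton silhouettes count as 0; tied silhouettes resolve to the smaller k;
Mantel permutations default to 999. Samples are assigned to lineages from
externally supplied soft assignments (admixture proportions or synthetic
truth — admixture inference itself is out of scope), at three thresholds:
hard (> 0.9), fallback (> 0.6) for boosting small lineages, and a gray class
below 0.5.

A calibration finding worth stating: when a sizable fraction of individuals
carries flat-Dirichlet three-way admixture, the Mantel criterion can
genuinely prefer k one above the planted number — it isolates the
intermediates as their own class — while the silhouette criterion stays at
the planted k. On strongly diverged lineages (the empirical regime, with
cophenetic correlations near 0.99) both criteria agree. The package's
clustering calibration experiments therefore run on discrete-lineage data,
and the admixed fraction is exercised by the assignment thresholds instead.

## Environmental layers

Station time series are summarized per time slice (defaults 1995--2007 and
2008--2021, boundaries inclusive) by the median and the 0.1--0.9
interquantile range, with linear-interpolation (type 7) quantiles — the
convention is documented and fixed rather than inferred. Bottom measurements
take precedence over surface ones for the same station and parameter.
Gridded thermal series reduce to per-cell monthly means, per-year extremes,
and across-year averages (`sst_min`, `sst_max`, `dhw_max`); degree-heating
anomalies are consumed as a provided product, not recomputed from raw SST.

Projection of station values onto the grid is a two-step procedure:
Nadaraya-Watson smoothing with a Gaussian kernel (default 5 km) at the
station locations, then ordinary kriging with a semivariogram fitted by
weighted least squares over spherical, exponential and Gaussian models,
keeping the best. The pre-smoothing regularizes the variogram — raw
monitoring data occasionally produce degenerate interpolations. A singular
kriging system falls back to inverse-distance weighting with a warning; a
constant field short-circuits exactly. Kernel width and grid resolution are
independent knobs, since the two resolutions they correspond to differ
between data products.

Collinearity among predictors is pruned by complete-linkage clustering on
`1 - |r|`, cut so that groups share pairwise `|r| >= 0.9`; the retained
member is the most central (highest mean within-group `|r|`). Complete
linkage alone cannot guarantee that representatives of *different* groups
stay below the threshold, so a greedy sweep drops offenders until no
retained pair reaches it — this makes the advertised invariant
unconditional.

## The forest engine

Genetic principal coordinates (gPCs) are first conditioned: scores are
regressed on covariates (geographic coordinates; for per-lineage analyses
also the assignment probabilities to the other lineages) and the residuals
re-rotated to principal axes, with the eigenvalue record updated. One random
regression forest per gPC then predicts scores from the environmental
predictors. Forest fit is out-of-bag R², truncated below at zero; a
predictor's importance inside a forest is its impurity-reduction share
rescaled to that R², and gPC importances combine weighted by each axis's
variance share, so summed importance equals the total variance explained to
machine precision — an invariant the tests assert at 1e-9.

The number of modeled gPCs defaults to the smaller of (a) the leading axes
covering 75% of positive-eigenvalue variance and (b) the axes with
above-average eigenvalue. Rule (b) exists because conditioned IBS ordinations
have long, flat noise tails; modeling dozens of noise axes dilutes importance
and multiplies runtime without adding signal. The end-to-end pipeline fixes
`nGpcs = 10` for the same reason, a scale chosen once for the default study
design (~260 samples).

Predictor selection exploits the `mtry` contrast: correlated proxies share
importance when few candidates compete per split (low mtry) but are
outcompeted by the true driver when most predictors compete (high mtry).
Defaults are mtry fractions 1/4 and 3/4 of the predictor count — the wide
gap maximizes the contrast. On each of 25 jackknife ordination replicates
(default 20% of samples dropped), forests are fitted at both settings with a
seeded random-normal decoy appended; a predictor is retained when its
importance does not drop from low to high mtry in at least half the
replicates and its median importance beats the decoy's. All constants are
config-exposed.

Turnover curves re-derive per-split impurity reductions by pushing the
training data back through the fitted trees (the forest library reports
split variables and thresholds but not per-split gains), rescaled so each
predictor's curve terminates exactly at its importance-table entry. The
largest step of a curve is found with a sliding window of 5% of the
predictor range; the reported threshold is the gain-weighted mean split
location in the best window. One caveat is inherent to impurity accounting:
a *linear* response concentrates gain near mid-range (the root split removes
about three quarters of the sum of squares), so turnover curves are only
"uniform" for linear gradients in a diffuse sense; sharp habitat thresholds,
by contrast, concentrate 80%+ of a predictor's importance within a bin of
the step and are localized to within the window width.

## Maps, offset, and mismatch

Prediction across the seascape never extrapolates: cells where a retained
predictor deviates beyond 10% of the sampled range outside the training
min/max are masked; values inside the margin are clamped to the training
extremes and logged. Adaptive neighborhoods come from two-step clustering —
k-means (default 30 fine clusters) on predictor rasters transformed through
their turnover curves, then Ward merging of fine-cluster centroids in
predicted-gPC space down to the requested count — which is less noisy than
clustering raw forest predictions directly. Maps are colored by min-max
scaling the first three principal axes of the predictions to RGB (any affine
choice would do; this one is documented), with environmental vectors fitted
by least squares on the two leading predicted axes.

Genetic offset is the per-cell Euclidean distance between gPC predictions
under two environmental states; it is a metric (zero iff the predictions
coincide, symmetric), and perturbing a predictor that the model does not use
leaves it identically zero. Environmental mismatch is the distance from a
focal gPC vector to every cell's prediction, scaled by the 0.90 quantile of
pairwise prediction distances (estimated from at most 2000 random cells;
with fewer valid cells the quantile is exact). The full-data model makes the
headline maps; jackknife spread is available as uncertainty but not painted
into them.

## The synthetic seascape

The generator plants every feature the pipeline is supposed to detect, under
one seed, with defaults fixed to the emulated study design: 65 sites of 4-5
colonies (~290 individuals before filtering), three lineages at
Balding-Nichols FST 0.15 with Gaussian depth niches (centers 3, 8, 18 m; sd
2, 6, 4 m — a shallow specialist, a broad shallow-biased generalist, and a
deep lineage), 3000 SNPs of which 150 carry within-lineage logit-linear
clines (slope 1.5 per sd) in a named seascape layer, spatially
autocorrelated neutral drift at 100 km scale (the isolation-by-distance
scale is a free parameter the source does not state), 5% clones, 5%
sib-like relatives, 10% Dirichlet-admixed individuals, and Poisson 10x
coverage with zero draws as missing data. The drift magnitude (logit-scale
sd 0.1) keeps within-lineage differentiation an order of magnitude below the
between-lineage signal — the regime of a cryptic-lineage system where
isolation by distance is detectable but subordinate.

Environmental layers are Gaussian random fields synthesized spectrally (FFT
on the grid torus; O(n log n), exactly seedable), standardized to mean 0 and
sd 1. Collinear groups mix a shared base field with per-member orthogonalized
noise, so realized pairwise correlations hit their targets almost exactly.
Depth combines a monotone inshore-offshore trend with short-range relief
that is deliberately large: reef bathymetry is far from a function of
long-shore position, and this keeps depth informative after geographic
coordinates are regressed out. All depths are positive (floored at 0.5 m).
Monitoring stations sample the layers with additive noise over two time
slices. Coordinates live on a flat km plane; an equirectangular lat/lon
converter is provided for real data, adequate at study-domain scales.

What passing tests show — and what they do not: the synthetic bed verifies
that each stage recovers what was planted at desk scale (lineages, clones,
FST, collinearity targets, causal drivers, habitat thresholds, offset
monotonicity). It does not emulate linkage disequilibrium, coalescent
genealogies, genotyping-error structure beyond binomial read sampling, or
the shape of real environmental covariance; conclusions about real data
still require the usual empirical caution.

## Problem sizes and numerical choices

Default experiment scales were chosen once for a single-CPU desk run: the
end-to-end pipeline uses the full study design (65 sites, ~260 retained
samples, 3000 SNPs, 20 environmental layers) and completes in a few minutes;
calibration experiments use 90-150 individuals and 2000 SNPs per dataset.
Tolerances follow from the statistics: binomial standard errors for IBS
expectations, 1e-9 for accounting identities, 1e-6 for kriging exactness on
constants. Ties are broken deterministically everywhere (smaller k, lower
threshold, lexicographic ids), and every stochastic step draws from seeds
derived deterministically from one master seed, so reruns are byte-identical.

## Known limitations

Kinship is proxied, not estimated — true half-sibs near the 0.8 boundary are
resolved by the threshold, not by likelihood. The admixture model (per-locus
mosaic with Dirichlet proportions) exercises assignment thresholds but is
not a hybrid-zone model. Kriging assumes second-order stationarity after
smoothing; strongly anisotropic seascapes would need a directional
variogram, which is not implemented. Forest importances are impurity-based
and share that family's known bias toward high-cardinality predictors —
immaterial here because all predictors are continuous, but worth remembering
if categorical layers are added.
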