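---
title: "Methods: cross-tissue coexpression analysis and blood-based classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-tissue coexpression analysis and blood-based classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodbrain)
```

## Scope and model

`bloodbrain` analyses multi-tissue bulk RNA-seq studies of chronic
intermittent ethanol (CIE) exposure in mice: the same animals are profiled
in whole blood (BLD) and up to three brain regions (prefrontal cortex PFC,
amygdala AMY, hypothalamus HYP), half exposed to ethanol vapor (CIE), half
to air, with voluntary-drinking traits (consumption in g/kg, preference)
recorded per subject. The pipeline answers three questions. Does CIE change
gene expression per tissue? Are the coexpression modules it perturbs
conserved between blood and brain? Can blood expression alone classify
dependence status?

### Normalization and differential expression

Counts are converted to log2 counts per million,
`log2((count + 0.5) / (libsize + 1) * 1e6)`; the half-count prior with
`libsize + 1` keeps values finite at zero counts and makes the transform
scale-invariant for large libraries. Heteroscedasticity of count data is
handled with voom-style precision weights: a per-gene linear model is
fitted, the lowess-smoothed trend (span 0.5; the span is configurable
because no single value suits every mean-variance profile) of the
square-root residual standard deviation versus average log2 count is
inverted at each observation's fitted log-count, and the fourth power of
the inverse trend is used as a weight.

Differential expression between CIE and Air uses the moderated
t-statistic: per-gene (weighted) least squares, then empirical-Bayes
shrinkage of residual variances toward a common prior. The prior df `d0`
and prior variance `s0^2` are estimated by moment matching of the log
residual variances against a scaled-F model (digamma/trigamma moments, with
a Newton inverse of the trigamma function). The posterior variance is
`(d0*s0^2 + d*s^2)/(d0 + d)` and the statistic is referred to a
t-distribution on `d0 + d` df. `prior_df = 0` recovers the ordinary t-test,
`prior_df = Inf` fully pools the variances; both limits are exposed because
they pin the implementation down exactly in tests (limma's `eBayes` is used
as an independent cross-check in the test suite, not as the
implementation). DEG sets use nominal p < 0.05, optionally split by fold
change direction; a Benjamini-Hochberg column is emitted but unused by
default, matching the study design this package reproduces. Sexes are
analysed separately throughout.

### Signed networks and modules

Per tissue, the signed similarity `S = (1 + cor)/2` maps Pearson
correlation into [0,1] so anti-correlated genes are maximally dissimilar;
raising it elementwise to a power beta sharpens the contrast. Beta is either
fixed per tissue (in the motivating study: males 6, 8, 7, 10 and females
5, 9, 11, 6 for PFC, AMY, HYP, blood) or chosen as the smallest candidate
whose connectivity distribution fits a power law with signed R^2 at or
above 0.8, computed over 10 logarithmic connectivity bins with empty bins
dropped (both the bin count and target are package choices; they are not
dictated by the method's definition). The topological overlap measure
`TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 - a_ij)` quantifies shared
neighbourhoods; modules are branches of the average-linkage dendrogram of
`1 - TOM` cut at height 0.99 with at least `min_module_size` members
(default 100, as in the motivating study; tests use smaller planted modules
and lower the threshold explicitly).

The deep-split refinement re-examines each accepted branch, because at
realistic sample sizes the correlation noise floor lets unrelated
subbranches merge below the 0.99 cut. It re-clusters the branch and scans
its secondary cut heights for the one revealing the most subbranches of at
least half the module size; those are the module *cores*, and a core only
counts as coherent when its mean topological overlap is at least twice the
tree-wide background overlap (the comparison is made on the overlap scale
because TOM dissimilarities crowd toward 1). Cores whose cross-core
dissimilarity is closer to their within-core level than to background are
fragments of one module and are unioned. Each remaining branch member then
joins its nearest core if its average dissimilarity to it is less than a
quarter of the way from the core's internal average to the background
level; everything else — including whole branches that have no coherent
core and sit at the background level — falls back to the unassigned label
"0", while a coreless branch that is itself coherent is kept whole.
Finished modules below the minimum size are discarded. This is a
reinterpretation of the dynamic tree cut "deep split" option built around
the same ingredients (secondary cuts, cores, straggler assignment); the
original hybrid variant's PAM-like reassignment against module eigengenes
is not implemented. The three constants (half-size core quorum, twice
background coherence, quarter-way admission) are deliberate precision
biases: planted-module recovery on the generator showed that looser rules
let background genes ride along in modules, which inflates downstream
cross-tissue overlap counts. Module eigengenes are the first right
singular vectors of the gene-standardized submatrices, unit norm, signed to
correlate non-negatively with the module mean profile. Modules whose
eigengenes cluster below dissimilarity 0.25 are merged iteratively until
stable. Zero-variance genes receive the uninformative similarity 0.5, are
flagged, and cannot seed modules.

### Linking modules to CIE and the meta-network

A module is CIE-related if it is enriched with DEGs (one-sided
hypergeometric test against the network's gene universe, p < 0.05) or its
eigengene correlates with group, consumption or preference (Pearson, t on
n-2 df, p < 0.05). Cross-tissue module overlap is tested for every module
pair with the hypergeometric tail over the intersection of the two tissues'
measured genes — the only universe on which joint membership is defined.
The meta-network has CIE modules as nodes and significant cross-tissue
overlaps (p < 0.05, configurable) as edges weighted by -log10(p); a
connected component is flagged as a blood-brain module cluster when a blood
node inside it has significant overlaps with modules from at least two
distinct brain regions, counted by region identity rather than by module
count. Node regulation direction is the sign of the more significant of
up-DEG versus down-DEG enrichment, with strength categories at p < 0.05 and
p < 1e-5.

### Blood-brain correlation analyses

Between-subject mode averages each gene across all samples (irrespective of
treatment) per tissue and reports one Spearman correlation over the shared
genes. Within-subject mode computes, per gene, the Spearman correlation of
expression across animals measured in both tissues, with Holm-Bonferroni
correction over all genes tested (m = number of genes detected in both
tissues). Spearman uses average ranks and the t-approximation for p-values;
the correlation is exactly invariant to strictly monotone transforms of
either tissue's values. Male and female correlations are compared with the
Fisher z test for independent correlations (the simplest of the cocor
family; confidence-interval variants are out of scope).

### Classification

Blood samples of one sex are classified CIE versus Air by elastic-net
logistic regression (glmnet), random forest (Gini splits, vote-fraction
scores), and PLS-DA (NIPALS PLS1 against the 0/1 label, linear-predictor
scores, class-midpoint threshold). Evaluation uses stratified 5-fold
cross-validation repeated 10 times by default; hyperparameters are selected
by an inner cross-validation on the training folds only (accuracy, with
ties broken toward the sparser or simpler model). Normalization is
leakage-safe: log-CPM is per sample, and gene-wise centering/scaling
parameters come from the training folds alone. Default grids: alpha 0 to 1
in steps of 0.1 with 50 log-spaced lambdas; mtry in {sqrt(p), p/10, p/4};
1-5 PLS components — the motivating study reports the selected values but
not its grids, so these are package choices. Accuracy, sensitivity,
specificity, FPR and MCC come from the pooled predictions of each repeat;
AUROC is averaged over folds (pooled available via `pooled_auc = TRUE`;
which convention the motivating study used is not stated). All metrics are
then averaged across repeats. Variable importance comes from a final model
fitted on all samples: |coefficients| for the elastic net, mean decrease in
Gini for the forest, and for PLS-DA the per-component absolute loading
weights summed with weights proportional to each component's reduction in
response sum of squares.

## The synthetic study generator

`generate_study()` emulates the study design at the data level: 2 balanced
groups, subjects shared across tissues, negative-binomial counts
(gamma-Poisson, dispersion 0.05 by default) with log-uniform library sizes
(5e5-2e6) so CPM normalization is genuinely exercised. Genes in a planted
module share a per-subject latent factor scaled so the expected pairwise
correlation equals the configured strength (`a = sigma0 * sqrt(r/(1-r))`
on top of log2-scale noise with sd `sigma0 = 0.5`); a module's factor can
carry an exact planted correlation with consumption (the noise component is
orthogonalized against the trait so the sample correlation is exact, not
just expected), and conserved modules reuse the same factor across tissues,
optionally sign-flipped to emulate opposite regulation directions. Planted
DEGs shift the CIE group mean by the configured log2 fold-change before
count generation. Consumption is group-shifted Gaussian (Air 8, CIE 12
g/kg, sd 2) and preference is a noisy monotone companion clipped to [0,1];
these values are chosen to be physiologically plausible for vapor-exposure
paradigms, since per-tissue dispersions and trait distributions are not
published for the motivating study.

What the generator does *not* emulate: batch effects, sequencing-depth
artefacts beyond library size, spike-ins, cell-type composition shifts, or
read-level noise. Passing recovery tests therefore demonstrates the
pipeline's correctness on its own model assumptions, not performance on
real tissue.

One consequence of count-space simulation worth knowing: planted DEGs
change library composition, so strong fold changes on many genes slightly
depress the CPM of all other genes in CIE samples. This is a real property
of relative-abundance data, and it is why trait-correlation recovery tests
use configurations without large DEG blocks.

## Numerical and design choices

* Hypergeometric tails are computed via `phyper(..., log.p = TRUE)` and
  exponentiated, stable far into the tail.
* `trigammaInverse` uses Newton iterations with the standard asymptotic
  starting point; variance moment <= 0 maps to infinite prior df (complete
  pooling).
* Eigengene sign ties (correlation exactly 0 with the module mean) keep the
  SVD's sign; in practice the planted and real modules tested never hit
  this.
* Zero training-fold standard deviations in fold normalization scale by 1
  and are flagged rather than dropped, so gene sets stay aligned across
  folds.
* `detect_modules` on fewer genes than `min_module_size` warns and returns
  all-unassigned rather than erroring, so degenerate tissues do not abort a
  multi-tissue run.
* Problem sizes in the test suite (300-2000 genes, 20 subjects, 20-seed
  recovery loops, planted modules of 50-150 genes with minimum module sizes
  of 25-100, reduced classifier grids) are the package's chosen test scale:
  large enough for the statistical assertions' tolerances, small enough to
  iterate on quickly.
* Null-calibration checks of the classifiers permute labels over expression
  with no planted signal: at n = 20 a permutation over a strong planted
  effect keeps partial alignment with the true groups by chance, so it does
  not produce a true null.

## Known limitations

* The dynamic tree cut is the conservative "tree" variant described above;
  WGCNA's hybrid PAM stage can assign more borderline genes to modules.
* Only two-group contrasts are supported in the DE stage.
* Consensus (multi-dataset) networks and block-wise approximations for very
  large gene sets are out of scope.
* The classifier stage assumes one tissue and one sex per call and refuses
  mixed input rather than attempting covariate adjustment.
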