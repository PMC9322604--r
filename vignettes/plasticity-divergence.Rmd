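---
title: "Quantifying plasticity and adaptive divergence in reciprocal transplants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plasticity and adaptive divergence in reciprocal transplants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastivec)
```

## The problem this package addresses

When two closely related taxa occupy contrasting ends of an environmental
gradient, a reciprocal transplant of cloned genotypes answers two linked
questions: do the taxa survive best in their own habitat (adaptive
divergence), and do they *respond* to the gradient differently (divergence
in plasticity)? `plastivec` implements the full quantitative chain for such
an experiment — two species, four transplant elevations, tens of clonally
replicated genotypes per species, blocks within sites — from raw leaf and
physiology measurements through to multivariate vector geometry, survival
models and expression reaction norms. A synthetic-data generator with the
same design structure stands in for field data, so every stage is testable
end to end.

## The univariate reaction-norm model

Each trait is analysed on clone means with the linear mixed model

$$ y = T_i + S_j + T_i{\times}S_j + T_i{\times}G_{k(j)} + B_{l(i)} + e $$

where $T_i$ is transplant elevation, $S_j$ species, $T_i{\times}G_{k(j)}$
a Gaussian random intercept for each genotype at each elevation (genotypes
may rank differently across sites), and $B_{l(i)}$ a random block effect
within each site. `fit_trait_model()` estimates the variance components by
REML with `lme4`. The species-by-elevation interaction — the statistical
signature of a difference in plasticity — is tested by a likelihood-ratio
test between the full and additive fixed structures, both refit under full
maximum likelihood, because REML likelihoods are not comparable across
fixed-effect structures. Across a family of traits, p values are multiplied
by the number of tests and capped at one; this deliberately simple
Bonferroni-style rule (rather than, say, Holm) mirrors common practice in
transplant studies and is what `adjust_p()` applies throughout.
`pairwise_site_tests()` compares sites within each species on estimated
marginal means (via `emmeans`, Bonferroni-adjusted) and assigns compact
letters greedily in ascending elevation order; ties in the greedy insertion
are resolved by that fixed site order so letters are reproducible.

Monte-Carlo checks in the test suite run this machinery at the scale of the
seed-propagated field experiment (21 + 25 genotypes, 3 blocks of 3 cuttings
at 4 sites): at that size the interaction LRT's null rejection rate sits at
the nominal 5%. At much smaller toy sizes the chi-square reference is
visibly anticonservative — a known finite-sample property of fixed-effect
LRTs in mixed models — which is why the calibration checks use the
field-scale design rather than a miniature.

## Derived traits

Leaf measurements are converted with `derive_leaf_traits()`: margin
complexity $= \mathrm{perimeter}^2/\mathrm{area}$ (dimensionless; entire
leaves score low, dissected leaves high), indent density
$= \mathrm{indents}/\mathrm{perimeter}$ (per mm), and specific leaf area
$= \mathrm{area}/\mathrm{dry\ mass}$ (mm²/mg; higher means thinner,
cheaper leaves). Physiology comes from `derive_physiology()`: intrinsic
water-use efficiency $A/g_s$, and the saturation-pulse partition of
absorbed light energy, for which we use the standard decomposition
$Y(II) = (F_m'-F)/F_m'$, $Y(NO) = F/F_m$, $Y(NPQ) = F/F_m' - F/F_m$, whose
three terms sum to one by construction. `pi_total()` evaluates the
standard JIP-test total performance index from the O, 300 µs, J, I and P
points of a fast fluorescence induction curve. These are the field's
standard formulas; instrument-specific variants exist, so the functions
document exactly which form they implement.

## Multivariate geometry: D matrix and angle analysis

Genotype means are first **mean-standardised** (each trait divided by its
grand mean over all species, sites and genotypes), making traits
dimensionless and directly comparable. `manova_wilks()` then tests
species, site and their interaction on the multivariate trait means with
the variation *among genotype-by-site units within cells* as the error
SSCP — the appropriate denominator when asking whether species and
elevations differ by more than genotypes do. Wilks' $\Lambda =
\det(E)/\det(H+E)$ is computed from residual-SSCP differences between
nested mean models (type-II style) and referred to Rao's F approximation.
The implementation is checked against both a brute-force SSCP oracle and
`stats::manova` on random instances.

The **D matrix** is the covariance of the species-by-site cell mean
vectors. Cells are equally weighted by default; since the supplement-level
recipe (effect-SSCP scaling, weighting) is a genuine degree of freedom, a
genotype-count-weighted variant is available via `compute_D(weighted =
TRUE)`. Eigenvectors are unit length, ordered by descending eigenvalue,
and reflected so the largest-magnitude loading on each axis is positive —
an arbitrary but fixed sign convention that makes runs reproducible.
$d_{max}$ typically separates the species; $d_2$ captures shared
elevational change.

Plasticity for a species is the difference between its mean-standardised
multivariate phenotype at two sites, reported as a unit vector plus a
magnitude (`plasticity_vector()`, native minus novel). Only the
elevational extremes enter the headline angles; intermediate sites are
descriptive. Angles between unit vectors (`vector_angle()`, degrees in
[0, 180]) quantify (i) how differently the two species respond to the same
gradient and (ii) whether plasticity is *adaptive*: in
`adaptive_alignment()` each species' plasticity is read from its home
phenotype toward the novel extreme and compared with the divergence vector
pointing from its own native phenotype to the other species' native
phenotype. Both vectors then share an origin and an orientation, so a
small angle means plasticity moves the migrant toward the resident's
phenotype. The 45° "aligned" flag is a reporting convenience, not an
inferential threshold, and is configurable.

## Survival

`km_curve()` wraps the product-limit estimator with Greenwood variance and
log-log bands. `cox_fit()` fits proportional hazards with species, site
and their interaction, Breslow tie handling by default (field mortality is
recorded on a day grid, so ties are common; Efron is available), genotype
as a gamma frailty and — because only one frailty term is supported —
block as an optional fixed adjustment; this approximates, rather than
replicates, a two-random-term hazard model, and the fit records a note
when the frailty step falls back to fixed effects. The adaptive-divergence
test is the likelihood-ratio comparison of the full against the additive
model (`survival_interaction_test()`), with early transplant-shock deaths
removable beforehand (`filter_transplant_shock()`, default 3 days). For
the Monte-Carlo calibration and the test-suite oracles the frailty is
switched off so that the partial likelihood being compared is exactly the
one a brute-force grid search evaluates.

## Expression layer

Counts are filtered with the two-stage rule: a gene with low counts
(< 5 reads) in at least half of all samples is discarded *unless* more
than 75% of those low samples come from one species — such genes are
retained because silence in one species with expression in the other is
itself a signal. The rescue rule is applied to counts (the available
proxy for per-sample mapping rates) and every decision is logged.
Normalisation uses median-of-ratios size factors. `de_test()` fits one
negative-binomial log-linear model per gene — species, site, their
interaction implicitly via per-species fits against the home site, and
genotype as a fixed covariate factor — with a per-gene method-of-moments
dispersion (floored at 1e-4, held fixed) and a Wald test referred to a t
distribution on the residual degrees of freedom; the t reference corrects
the anticonservatism of the normal approximation at typical replicate
numbers (the suite verifies null p-value uniformity by a KS check). This
is deliberately a single transparent path: no empirical-Bayes shrinkage
is applied, and numeric parity with DESeq2 or limma/voom is not claimed —
calibration and recovery on simulated data are the acceptance surface.

Per-gene home-versus-extreme fold changes in the two species feed
`quadrant_classify()`, an exhaustive partition into
opposite-direction, magnitude-divergent (|LFC difference| above 1 log2
unit by default — no published threshold exists, so the cut-off is
explicit and configurable), shared-same-direction, single-species, and
unchanged categories. `contrast_sets()` produces exact upset-style overlap
tables. `detect_modules()` replaces full weighted-network consensus module
detection with average-linkage clustering on $1-|r|$ cut at a fixed height
(default 0.5, i.e. members correlate at |r| ≳ 0.5): a documented
simplification; the eigengene layer downstream (`module_eigengene()`,
first principal component of standardised member expression, sign-anchored
to the mean member profile, correlated with elevation within each species)
follows the usual definitions exactly. `go_enrichment()` is a one-sided
Fisher exact test per term, checked against full hypergeometric
enumeration.

## The synthetic-data generator

`simulation_design()` bundles the layout and all generative parameters;
`simulate_traits()`, `simulate_survival()` and `simulate_counts()` draw
the three data layers from deterministic substreams of one master seed.
The default layout mirrors the seed-propagated transplant (21 + 25
genotypes, 4 sites at 500–2000 m, 3 blocks, 3 cuttings per genotype and
block), and the default trait surfaces echo the qualitative reaction norms
of the study system: leaf area shrinking with elevation in both species,
complexity declining only in the low-elevation species, indent density
declining only in the high-elevation species, and SLA rising at low
elevation more steeply in the high-elevation species. Survival uses
exponential event times with a log-normal genotype frailty — chosen for
closed-form checks (median $= \ln 2/\lambda$) — with censoring at
follow-up; opposite elevational hazard trends for the two species are the
default, so the species-by-elevation interaction is planted. Counts are
negative binomial (variance $\mu + \alpha\mu^2$) with log-normal library
sizes, per-gene species/elevation/interaction effects on the log2 scale,
genotype deviations, and latent module factors (one tracking elevation in
both species, one only in the second species, mirroring the asymmetric
module behaviour seen in such data).

Because no variance-component magnitudes are published for these data, the
default variances are chosen for testability rather than realism, and the
recovery fixtures are explicit about their choices. In particular
`planted_angle_design()` plants two plasticity directions at an exact
angle with site-centred deviations (so mean standardisation cannot distort
the planted geometry) and noise small enough that the Monte-Carlo error of
the recovered angle is about 0.5°, giving a four-sigma margin at the 2°
recovery check. What the generator does *not* emulate: spatial
autocorrelation within transplant grids, seasonal hazard structure
(piecewise rates are possible but off by default), sequence-level reads,
and empirical mean-dispersion trends — so passing tests demonstrate
correctness of the estimators under the stated model, not robustness to
every feature of field data.

## Numerical and design choices

* All randomness flows from one seed per run; generator substreams are
  derived deterministically, so outputs are byte-identical across runs.
* Eigenvector and MDS axis signs are fixed by the largest-magnitude
  coordinate; descending-eigenvalue order throughout.
* `vector_angle()` clips the dot product into [−1, 1] before `acos`.
* Degenerate inputs fail loudly and early: zero difference vectors, zero
  trait grand means, singular error SSCPs (fewer genotype-by-site units
  than traits), one-cell divergence, non-symmetric distance matrices,
  all-zero genes (flagged untestable rather than significant).
* Problem sizes in the test suite: the LRT calibrations use 500 null
  replicates at the field design scale; power, hazard-ratio and recovery
  checks use 50–200 replicates; DE calibration uses 600-gene matrices.
  These sizes keep the whole suite at a few minutes while leaving
  Monte-Carlo standard errors well inside the asserted bands.

## A worked example

```{r example, eval = FALSE}
library(plastivec)

design <- simulation_design(seed = 1)
cfg <- pipeline_config(design = design, seed = 1, out_dir = "results")
summary <- run_pipeline(cfg)

summary$trait_lrt            # per-trait species-by-elevation LRTs
summary$wilks_lambda         # multivariate interaction
summary$d_max_proportion     # share of divergence on the leading axis
summary$angles               # plasticity and alignment angles
summary$survival_interaction # adaptive-divergence survival test
summary$quadrant_counts      # expression reaction-norm categories
```

## Known limitations

The frailty approximation above; genotype as a fixed factor in the DE
model (a random genotype effect would match the mixed-model treatment of
traits but is not identifiable gene-by-gene at desk scale without
shrinkage); module detection is correlation clustering, not a
topological-overlap network; no phylogenetic correction or G-matrix
estimation is attempted; and printed statistics from any particular field
dataset are reproducible only with that dataset in hand — the package's
guarantees are the calibration and recovery properties its tests compute.
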