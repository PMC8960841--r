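---
title: "Methods: from OTU tables to the microbial controls of N2O emissions"
author: "denitnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from OTU tables to the microbial controls of N2O emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

denitnet implements an analysis chain for multi-site soil fertilization
trials that asks how long-term nitrogen input restructures prokaryotic
communities and, through them, the controls of nitrous oxide (N2O)
emissions. The chain runs from an OTU count table, a rooted phylogeny and
plot-level metadata to (i) an occupancy-based partition of the community,
(ii) compositional balance tests of fertilization effects, (iii)
treatment-wise co-association networks with module eigengenes, and (iv)
boosted-regression attribution of the denitrification end-product ratio
N2O/(N2O + N2) to biotic and abiotic drivers. A synthetic-study generator
with recorded ground truth backs every stage with a recovery test. This
vignette explains the models, the parameters that matter, and the design
choices made where more than one defensible option existed.

## Frequent versus rare OTUs: the index of dispersion

Core ("frequent") community members are separated from transient rare taxa
with a dispersion test on mean rarefied abundances. Counts are rarefied to
a common depth many times (default 100) and averaged (`rarefy_mean()`);
for each OTU the index

\[ I = \frac{\sigma^2}{\mu} \cdot O \]

multiplies the variance-to-mean ratio across samples by the occupancy
\(O\) (proportion of samples where the OTU occurs). Under random (Poisson)
placement \(\sigma^2/\mu \approx 1\), and the classical dispersion
statistic \(I\,(n-1)\) behaves like \(\chi^2_{n-1}\); an OTU is called
frequent when the statistic exceeds the upper \(\alpha = 0.05\) critical
value. Two interpretive choices are recorded here because the underlying
test is often cited without formulas: the degrees of freedom are
\(n - 1\) (samples minus one), and occupancy multiplies the index before
the \(\chi^2\) comparison, so a taxon absent from most samples is pulled
toward "rare" even if bursty where present. Occupancy is a proportion over
the whole dataset, making \(I\) dimensionless in the occupancy direction
while scaling linearly with abundance (a property asserted in the tests).

## Compositional transforms

Sequencing counts are compositional: only relative information is
meaningful, and log-ratio analysis requires strictly positive entries.

* `impute_zeros()` performs Bayesian-multiplicative zero replacement:
  zeros become posterior-expected proportions under a Dirichlet prior
  whose strength defaults to the square root of the sample total with
  uniform part weights, and non-zero parts are rescaled multiplicatively
  so observed ratios are untouched. Imputed proportions are capped at 65%
  of the sample's smallest observed proportion so a replacement can never
  rival a real observation. The prior family is the standard one for this
  task; the square-root strength is a configurable default, not a claim
  about the optimum.
* `clr_transform()` is the centred log-ratio: each log count minus the
  sample's log geometric mean. Rows sum to zero and the transform is
  invariant to sequencing depth.
* `philr_transform()` maps a composition onto the orthonormal balances of
  a rooted binary phylogeny. For the internal node \(v\) with child tip
  sets \(L\) (numerator) and \(R\),
  \[ b_v = \sqrt{\frac{n_L n_R}{n_L + n_R}}\,
     \ln\frac{g(x_L)}{g(x_R)}, \]
  with \(g\) the geometric mean. Positive balances mean the numerator
  clade is relatively more abundant. Two design choices: no taxon or
  branch-length weighting is applied (the unweighted basis is the
  identifiable default when weighting is not specified), and the
  numerator is the first child in the tree's edge order, recorded per
  node in the output's basis attribute so signs are interpretable.
  Balance-space Euclidean distance equals the Aitchison (CLR) distance;
  the test suite verifies this isometry to 1e-8 on random compositions
  over three tree shapes, and verifies a worked four-tip example by hand
  computation.

Polytomies in input trees are resolved by deterministic random
bifurcation with zero-length inserted branches (`read_tree(resolve =
TRUE)`), since the balance basis requires a binary tree and an arbitrary
but reproducible resolution only introduces zero-variance balances.

## Community statistics

Diversity is Shannon's \(H'\) (natural log), richness, and Faith's
phylogenetic diversity (vegan and picante). Community-level treatment
effects are tested by perMANOVA on balance-space Euclidean distances with
permutations restricted to within sites (vegan's `adonis2` with permute
blocks): in a multi-site design the site signal dwarfs the treatment
signal, and free permutation under a site-confounded null badly inflates
the type-I error while within-site permutation stays at or below the
nominal level — the test suite demonstrates both rates by
simulation.

Per-balance fertilization effects use the linear mixed model
`balance ~ treatment + (1 | site)`, with the treatment F-ratio evaluated
at Kenward-Roger denominator degrees of freedom when pbkrtest is
available (Satterthwaite otherwise; the method is recorded per fit). A
singular fit (site variance estimated at zero) falls back to the pooled
fixed-effects ANOVA, which is the same F in that limit. Families of
balance tests are corrected by Benjamini-Hochberg FDR; the discovery
threshold used downstream is q < 0.01. Balances that pass are then
correlated (Spearman) with the end-product ratio.

## Co-association networks by random-matrix thresholding

Within each treatment, Pearson correlations between CLR-transformed
frequent OTUs are computed across all sites. The network threshold is not
hand-picked: `rmt_threshold()` scans a grid (default 0.50–0.98, step
0.01), zeroes sub-threshold entries, and examines the nearest-neighbour
spacing distribution (NNSD) of the unfolded eigenvalue spectrum. Dense
noisy correlation matrices show Gaussian-orthogonal-ensemble level
repulsion; once noise correlations are removed the spectrum decomposes
into independent blocks and the spacings become exponential (Poisson).
The chosen threshold is the first whose Kolmogorov-Smirnov test against
Exp(1) is non-significant (p > 0.05); a histogram-versus-exponential SSE
curve is emitted alongside for goodness-of-fit inspection.

Numerical choices: the spectrum is unfolded through a smooth monotone
cubic spline fitted to the empirical cumulative eigenvalue density on
(default 10) quantile knots; eigenvalues degenerate within 1e-10 are
merged before spacings are computed, because exact ties (for example the
eigenvalue 1 of every isolated variable) would otherwise dominate the
NNSD; the diagonal is retained throughout, which shifts the spectrum
uniformly and leaves spacings unchanged. Scans with fewer than about a
dozen distinct eigenvalues are not evaluated at that threshold, and a
scan in which no threshold passes returns an explicit "no transition"
result rather than a guess. Spacing statistics are weak below roughly
50 x 50 matrices (a warning is issued); the planted-module recovery
checks therefore use 120 variables with four planted blocks, which gives
about 60 informative spacings and a well-calibrated KS test.

Edges keep their signed correlation as weight; graph construction also
computes t-distribution p-values for all pairs and drops any edge whose
BH-adjusted q is not below 0.001 (at realistic thresholds and sample
sizes this removes nothing, and removals are logged). Isolated nodes are
removed. Topology metrics — node and edge counts, diameter and average
path length (largest component, flagged if disconnected), mean degree,
transitivity, modularity, connectance, and the per-node average Jaccard
neighbourhood similarity — are computed on the positive-edge subgraph,
matching the convention of comparing networks of positive associations.
Their significance is assessed against 1000 Erdos-Renyi G(n, m) graphs
with two-tailed empirical p-values floored at 1/reps.

Modules come from Girvan-Newman edge-betweenness clustering (igraph) on
the unweighted positive graph, cut at maximum modularity; modules with at
least 5 nodes are retained. Each module is summarized by its eigengene:
the unit-norm first principal component of the members' standardized
abundances (CLR scale by default, configurable), oriented to correlate
positively with the members' mean standardized abundance, with variance
explained reported. The orientation makes the sign deterministic; note
that negating every member column flips both the component and the
orientation reference, so the oriented eigengene flips as a whole — the
spanned direction and variance explained are what is invariant.

## Comparing networks

`diff_edges()` classifies edges (by unordered node pair) as common or
unique to either network. `rewiring_scores()` quantifies per-node change:
a node's incident positive edges in each network become a \(|r|\)-weight
vector over the union neighbourhood, both vectors are normalized to unit
length, and the score is the mean squared distance to their centroid
(equivalently \(\lVert v_A - v_B\rVert^2/4\)): 0 for identical incidence,
0.5 for fully disjoint neighbourhoods, with a degree-corrected variant
dividing by the union-neighbourhood size. Dynamic-network tools of this
kind differ in their variance normalization; the centroid form above is
the implemented contract and nodes present in only one network receive
the disjoint-neighbourhood maximum, flagged. Module correspondence maps
each module to its maximum-Jaccard counterpart; the mapping is
deliberately many-to-one so a module that splits in the other network
maps both halves to the same counterpart (a one-to-one assignment would
hide exactly the splits of interest).

## Attributing the end-product ratio

The ratio of potential N2O production (assay without acetylene) to
potential denitrification (with acetylene, which blocks N2O reduction) is
modelled per treatment by gradient-boosted regression trees behind a
pluggable fit/predict estimator (xgboost backend, single-threaded and
deterministic). Hyperparameters — trees {500, 1000, 2000}, shrinkage
{0.01, 0.05, 0.1}, interaction depth 1–3, minimum node size {5, 10} —
are tuned by 10-fold cross-validated RMSE with ties broken toward fewer
trees then smaller depth. Predictor attribution uses permutation
importance (default 500 permutations; median RMSE increase, floored at
zero, normalized to percent, top set above 5%), with an independent RNG
stream per predictor so results do not depend on column order. Effect
shapes come from first-order accumulated local effects on 10 quantile
bins, centred by the observation-weighted mean; unlike partial
dependence, ALE remains valid under correlated predictors, which gene
abundances and their ratios always are.

Recovery tests use studies where the ratio is generated as
logistic(a·pH + b·module + c·nosZ:nir + noise) and ask that these three
drivers occupy the top importance ranks. The recovery predictor set pairs
the drivers with covariates that are conditionally independent of the
ratio; the individual nir and nosZ gene abundances are excluded there
because they are constituents of the nosZ:nir driver and would absorb
its credit — a property of correlated-predictor attribution, not a
failure of the procedure.

## Gas kinetics and site-level statistics

Bottle N2O accumulation (six points, 0–2.5 h at 0.5-h steps) is fitted
either linearly or with the saturating form \(c(t) = c_0 + A(1 -
e^{-kt})\) (Levenberg-Marquardt), whose initial slope \(A k\) is the
rate; `auto` picks by small-sample corrected AIC and a non-convergent
nonlinear fit falls back to linear, flagged. Rates are floored at zero.
Fertilization responses are summarized per site (percent change of
site-mean values, so the test's n equals the number of trials) and tested
with a two-sided exact Wilcoxon signed-rank test: the full conditional
null distribution of the rank sum is computed by convolution over doubled
mid-ranks, which stays exact under ties and is verified against complete
enumeration of all \(2^{14}\) sign assignments. ANCOVA
(`response ~ covariate * group`) tests whether a covariate's slope
differs between treatments and reports standardized within-group slopes;
an exactly parallel configuration has a 0/0 interaction F, reported as 0.

## The synthetic-study generator

`generate_study()` emulates the assumed data-generating structure: 14
sites x 2 treatments x 2–6 plots (default 4); frequent OTUs from a
multivariate log-normal with a site offset component (sd 0.75), a plot
component (sd 0.5) and a log-normal abundance distribution (sd 1.2,
chosen so the labelled frequent class sits above the detection floor at
the default 4e4 mean depth); planted equicorrelated modules whose
correlation can differ between treatments (rewiring); fertilization
effects applied to whole clades of the frequent-OTU subtree (default 0.5
natural-log units); rare OTUs with occupancy drawn below 25% and
Poisson-scale counts; counts drawn multinomially at log-normal depth so
compositional coupling is preserved; a Kingman coalescent phylogeny; and
covariates, gene abundances and activities generated with known
dependencies, the end-product ratio through a logistic link (coefficients
recorded in the returned truth object). What the generator does not
emulate: taxonomic correlation between phylogeny and abundance niches,
overdispersion beyond log-normality, spatial structure within sites, or
measurement error in qPCR ratios — so passing recovery tests show the
procedures work under the stated model, not that field data satisfy it.

## Problem sizes and determinism

All randomness flows from per-stage seeds derived deterministically from
one master seed, so any stage subset reproduces the full run's numbers;
the pipeline's tabular outputs are byte-identical across reruns of the
same configuration. The recovery checks run at deliberate, moderate scales:
20-seed RMT scans on 120-variable matrices; a 1000-balance null study
and ten 120-OTU studies for mixed-model FDR and power; 1000 perMANOVA
simulations at 199 permutations; twenty 56-sample boosted models with
500-permutation importance; eigengene limits at n = 3000. These sizes
are the package's own choices for stable Monte-Carlo estimates of the
properties being checked.
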