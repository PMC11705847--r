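---
title: "Models and methods in phyllonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phyllonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phyllonet implements the statistical chain commonly used to characterize
phyllosphere (and other host-associated) fungal communities from an OTU
count table, a sample metadata table, and a rooted phylogeny: diversity and
ordination, thresholded co-occurrence networks with keystone-role
classification, the Sloan neutral community model, and phylogenetic null
models that partition community assembly into five ecological processes.
This vignette records the models, their assumptions, the tunable parameters
that matter, and the design decisions taken where the methodology was
genuinely open.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Input model and preprocessing

The substrate of every analysis is an `otu_table`: a taxa-by-samples matrix
of non-negative integer read counts.  Counts are stored as integers and
relative abundances are always derived views — this prevents silent double
normalization.  Taxon rows with zero total are dropped at construction.

`filter_otus()` reproduces the standard amplicon cleaning step: singletons
(total count 1) and taxa whose *total* relative abundance falls below
0.005% are removed.  The threshold denominator is the pre-filter grand
total across the whole data set, the common reading in amplicon practice
when the denominator is unstated.  Filtering precedes normalization, the
order implied by a typical bioinformatic methods sequence; both removal
counts are reported.  Normalization defaults to rarefaction (subsampling
without replacement) to the minimum retained depth, with total-sum scaling
available as an explicit alternative; rarefaction keeps the count model
intact for the occupancy-based analyses downstream.

## Diversity, ordination and group tests

Alpha diversity is the Shannon index with natural logarithm, the
convention of the vegan toolchain.  Beta diversity uses the robust
Aitchison distance: per sample, a centered log-ratio over the *nonzero*
counts only (zeros treated as missing, not imputed), with the pairwise
Euclidean distance computed over the taxa nonzero in both samples and
rescaled by `sqrt(n_total / n_shared)` to correct for varying overlap.
This is deliberately the deterministic shared-support estimator rather
than the matrix-completion (RPCA) one: it needs no optimization, is exactly
scale-invariant per sample, and degrades explicitly (a pair sharing fewer
than two taxa is reported missing) instead of implicitly.  Principal
coordinates are classical metric MDS on the double-centered squared
distances; negative eigenvalues are zeroed and excluded from the variance
denominator, and their count is reported.

PERMANOVA uses the one-factor pseudo-F from Gower-centered sums of squares
with whole-sample label permutation; the p-value is
`(1 + #(F_perm >= F_obs)) / (1 + n_perm)`, so its smallest attainable value
is `1/(n_perm + 1)`.  Its type-I error is calibrated by simulation in the
acceptance suite.  SIMPER decomposes each between-group Bray-Curtis
dissimilarity (on relative abundances) into per-taxon contributions that
sum to the pair's dissimilarity exactly, then averages over all
between-group pairs.  Levins niche breadth is `B = 1 / sum(P^2)` over the
distribution of a taxon's reads across samples.  Group comparisons are
nonparametric throughout: Wilcoxon rank-sum for two groups,
Kruskal-Wallis plus Dunn's post hoc z-tests for three or more.  Dunn
p-values are Bonferroni-adjusted by default (Benjamini-Hochberg available);
the multiplicity correction was an open choice and conservatism was
preferred.

## Co-occurrence networks

Networks are built from all-pairs Spearman correlations (mid-rank ties) on
relative abundances, with an edge kept when `|rho| >= 0.6` and the
two-sided p-value (t approximation) is below 0.01.  Three decisions were
open and are fixed as follows: correlations use relative abundances (the
count/proportion choice is unstated in common protocols); edge p-values are
*not* multiplicity-corrected by default, matching the raw `P < 0.01`
convention of the protocol this mirrors (a BH flag exists); and module
detection runs on the unsigned graph with edge sign retained as an
attribute.  Sub-networks per sample group are induced on the taxa present
in the group — never re-thresholded — so their topology is comparable to
the parent network.

Modules come from Louvain modularity maximization (seeded, deterministic).
Node roles use the within-module degree z-score `Zi` and participation
coefficient `Pi = 1 - sum_t (k_it/k_i)^2`: network hubs (`Zi > 2.5`,
`Pi > 0.62`), module hubs (`Zi > 2.5`, `Pi <= 0.62`), connectors
(`Zi <= 2.5`, `Pi > 0.62`), peripherals otherwise.  The boundary cases
(`Zi` exactly 2.5, `Pi` exactly 0.62) fall to the connector/peripheral
side, following the threshold wording literally; this is unit-tested at
machine-epsilon offsets.  A module with zero degree spread yields `Zi = 0`;
an isolated node yields `Pi = 0`.

## The Sloan neutral community model

For each OTU the model relates its mean relative abundance `p` to its
detection frequency across samples via
`F(p; m) = 1 - BetaCDF(d; N m p, N m (1 - p))`, with `N` the mean sample
depth, `m` the migration probability, and `d` the detection limit.  `m` is
the single free parameter, estimated by bounded least squares on
`(1e-6, 1)`; `R^2 = 1 - SSE/SST` may be negative.

Two numerical choices deserve note.  First, the detection limit defaults
to `d = log(2)/N` rather than the conventional `1/N`.  For count-sampled
data, detection of a taxon with latent frequency `pi` is binomial,
`1 - (1 - pi)^N`; approximating that smooth curve by a hard threshold is
best done at the frequency where detection probability is one half,
`log(2)/N`.  With `1/N` the migration estimate carries a systematic upward
bias of roughly +30% at typical depths — large enough to break recovery of
a known generative `m` — while `log(2)/N` recovers it; `1/N` remains
available through `detection_limit`.  Second, the 95% band used to label
OTUs as above/within/below the neutral expectation is the *binomial
quantile band* of the predicted detection probability at `n` samples: it
is a prediction band for an observed frequency, so an OTU whose predicted
frequency is 1 is never flagged merely because a parameter CI cannot reach
1.  The OTU-resampling bootstrap (default 1,000 repetitions) provides
percentile CIs for `m`, `Nm`, `R^2` and the fitted curve; residuals are
unweighted, matching the common implementation lineage.

## Assembly-process null models

Phylogenetic turnover is the abundance-weighted beta mean nearest taxon
distance (beta-MNTD); its null is built by shuffling taxon labels across
the tips of the tree pruned to the analyzed taxa (the "taxa.labels"
convention), 999 randomizations by default with a fast mode of 199.
`beta-NTI` standardizes the observed value against this null per community
pair.  Pairs with a zero-variance null (possible on perfectly symmetric
trees) are reported missing rather than zero.  Taxonomic turnover uses the
Raup-Crick metric on Bray-Curtis: each null community keeps its observed
richness (taxa drawn with probability proportional to regional occupancy)
and its observed total reads (filled with probability proportional to
regional relative abundance), and
`RC = ((#null < obs + 0.5 #null = obs)/n_null - 0.5) * 2`.  Null tables
are drawn once per randomization for all samples and compared pairwise —
the per-pair marginal distribution is identical to per-pair redraws at a
fraction of the cost.

The five-process classification follows the strict inequalities:
`beta-NTI > +2` heterogeneous selection, `< -2` homogeneous selection;
otherwise `RC > +0.95` dispersal limitation, `< -0.95` homogenizing
dispersal, else drift.  Values exactly at a threshold therefore fall to
the non-selection / drift side.  Fractions are reported overall and per
within-group stratum.  Process fractions are computed at the
whole-community-pair level; a per-phylogenetic-bin decomposition (as in
binning frameworks such as iCAMP) is intentionally out of scope.

pNST — the phylogenetic normalized stochasticity ratio — uses beta-MNTD
with the same tip-shuffle null.  The exact formula varies across the NST
literature; this package implements the per-pair normalized (MST-type)
ratio: dissimilarities are scaled to [0, 1] by the global maximum over
observed and null values, and with observed `D` and null mean `E` the
ratio is `D/E` when `D <= E` and `(1-D)/(1-E)` otherwise, clamped to
[0, 1].  A value of 1 means the observation equals the null expectation
(fully stochastic), 0 means maximal departure (fully deterministic); group
pNST is the mean over within-group pairs and the variant name is recorded
in the result object.

## The synthetic-data generators and what a green test establishes

Every estimator ships with a generative inverse, and the four recovery
loops are the package's acceptance backbone:

* `simulate_neutral()` is the stationary Sloan scheme itself — geometric
  metacommunity rank curve (decay 0.96, spanning the abundance range from
  always-detected to near the detection limit at the default depths),
  per-sample latent compositions from `Beta(Nm p, Nm (1-p))`, multinomial
  counts.  Because generator and estimator share the model, `fit_ncm()`
  must recover `m = Nm/depth`; this is asserted at +/-20% at the stated
  sizes (500 taxa, 60 samples, depth 5,000, Nm = 1,000).
* `simulate_selection()` evolves niche optima by Brownian motion on the
  tree (standardized to sd = a quarter of the environmental span),
  multiplies a Gaussian niche filter by a geometric base rank-abundance
  curve assigned independently of the phylogeny, and adds a per-sample
  lognormal abundance lottery (sd 1.5).  The base curve and the lottery
  are not decoration: without abundance unevenness, deep sequencing puts
  every taxon in every sample and the nearest-taxon null degenerates, and
  without the lottery, replicate samples share all their taxa and no
  within-group turnover exists for the null models to judge.
* `simulate_dispersal_limited()` drifts blocks multiplicatively
  (lognormal, sd = `drift_strength`) from a shared ancestral composition,
  with small within-block jitter — no selection and no phylogenetic
  signal, so between-block pairs must classify as dispersal limitation and
  within-block pairs as homogenizing dispersal.
* `simulate_modular_network_data()` plants correlation blocks through
  shared latent Gaussian factors; the compositional closure makes
  across-module correlations mildly negative, which is itself asserted
  (planted structure must not leak across modules).

Known limitations of this stated world, so that a green suite is not
over-read.  The simulations do not mimic any real taxon composition; they
are statistical stand-ins.  On a 200-tip Yule tree, cophenetic distances
are close to bimodal (small within a clade, about twice the tree height
across clades), so the tip-shuffle null of a nearest-taxon statistic has a
coefficient of variation near one and beta-NTI is effectively bounded
below around -1: *homogeneous* selection cannot reach its -2 threshold in
these simulations no matter how deterministic the generator is, while
heterogeneous selection (unbounded above) reaches +5 to +25.  The tests
therefore assert the attainable directional signatures for the convergent
side (within-group mean beta-NTI below zero; selection pNST below matched
neutral pNST) and the full threshold signatures everywhere else.  Real
phylogenies, with hundreds to thousands of tips and smoother depth
distributions, do not share this floor to the same degree.

## Reproducibility machinery

Every stochastic operation takes an explicit integer seed and is
byte-reproducible under it.  `run_pipeline()` takes one global seed and
splits it deterministically into per-stage seeds; the full configuration
is serialized into the output directory next to a log that echoes package
version, seeds and parameters, so any run is re-creatable from its own
artifacts.  A run without a tree executes everything except the assembly
stage, which is skipped with an explicit notice.  `scripts/acceptance.R`
recomputes the two paper-anchored acceptance targets (mean pNST and mean
|beta-NTI| under the neutral scenario) from scratch at every invocation.
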