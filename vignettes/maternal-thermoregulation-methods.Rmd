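---
title: "Models and methods: maternal thermoregulation and transitions to live birth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: maternal thermoregulation and transitions to live birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Egg-laying (oviparous) lizards and snakes often prefer body temperatures that
are harmful to their embryos, whose hatching success peaks at a lower
incubation temperature. Prolonged egg retention at maternal temperatures
should therefore be costly, yet live birth (viviparity) has evolved from
oviparous ancestors many times in squamates. `gravitherm` implements the
comparative machinery needed to ask whether gravid females behaviourally shift
their body temperature toward the embryonic optimum, whether that plasticity
differs between reproductive modes, and whether it was already present in the
oviparous ancestors of live-bearing lineages.

Three species-level quantities are involved, all in degrees Celsius except the
effect size:

* `P_bt` — preferred body temperature of non-gravid females;
* `T_opt` — incubation temperature maximising hatching success, defined as
  the vertex of a concave quadratic on the logit scale;
* Hedges' *g* — the standardized mean difference between gravid and
  non-gravid preferred body temperature (positive = gravid warmer).

# Effect sizes

`hedges_g()` uses the heteroscedastic standardized mean difference (SMDH):
the standardizer is the unweighted average of the two group variances,
`s*^2 = (sd_g^2 + sd_ng^2)/2`, not the df-weighted pooled variance, because
gravid and non-gravid temperature variances routinely differ. The
small-sample factor uses the exact gamma-function form of J with
`m = n_g + n_ng - 2` degrees of freedom, and the large-sample variance is the
standard SMDH expression. These are the same equations the `metafor` package
documents for `escalc(measure = "SMDH")`, and the test suite checks our
implementation against `metafor` as an independent oracle.

Species with several studies are combined by fixed-effect inverse-variance
pooling (`pool_effects()`). This is the simplest defensible rule; the
laboratory-versus-field verification model (`labfield_check()`) instead keeps
per-study records and absorbs within-species repetition with an iid species
random effect, so both representations of multi-study species are exercised.

# The Bayesian phylogenetic mixed model

`bpmm()` is the package core: a Gibbs sampler for single- and multi-response
mixed models whose species random effects covary as Brownian motion on a
phylogeny. The phylogenetic covariance matrix (shared root-to-ancestor path
lengths, `phylo_covariance()`) is rescaled to unit mean diagonal inside the
sampler, so variance components are on the trait scale and phylogenetic
heritability is simply `H^2 = V_phylo / (V_phylo + V_resid)` (plus the iid
species variance when that term is modelled).

Two designs are implemented:

* **Trait design** (one row per species, k Gaussian responses): unstructured
  k-by-k phylogenetic and residual covariance matrices, optionally split into
  separate matrices per group (the reproductive-mode analysis), known
  per-datum sampling variances ("mev") entering as fixed-variance latent
  effects, and conditional-normal augmentation of missing responses. The
  phylogenetic-effect update exploits the eigendecomposition of the tree
  covariance plus a joint diagonalisation of the k-by-k precision pair, so a
  full sweep is a handful of dense matrix products regardless of k.
* **General design** (single response, repeated rows): phylogenetic random
  intercepts and optional random slopes with an unstructured covariance
  across terms, an optional iid species intercept, Gaussian or
  binomial-logit family. Binomial rows carry a latent Gaussian liability
  updated by adaptive random-walk Metropolis; its residual variance is fixed
  at 1 by default because a latent residual variance is only weakly
  identified in binomial models (an option estimates it).

Covariance blocks get inverse-Wishart updates under the prior
parameterisation common in animal-model MCMC software (scale `V * nu`,
degrees of freedom `nu`); the default is `V = diag(k)`, `nu = k - 1 + 0.002`.
Parameter expansion (working scale parameters with a wide Gaussian prior,
`prior_block(..., alpha_mu = , alpha_V = )`) is available for the trait
design, where the prior-sensitivity checks run; the sensitivity harness in
the test suite refits a model under the default, a nu-scaled, and an
expanded prior and checks that the credible intervals overlap.

Summaries follow the reporting conventions of the field: posterior modes via
Gaussian kernel density (Silverman bandwidth), 95% highest-posterior-density
intervals, and `pMCMC` as the minority tail mass (single-tail, not doubled;
`pmcmc(doubled = TRUE)` gives the other convention). HPD intervals were
chosen over quantile intervals because reported intervals of this kind of
analysis are conventionally HPD; the difference is negligible for the nearly
symmetric posteriors involved.

## Chained sampling across imputations and trees

Missing sampling variances and sample sizes are imputed by predictive mean
matching (`pmm_impute()`, 20 completed datasets by default, donor pool k = 5,
Bayesian parameter draws per copy so copies differ, sample sizes imputed on
the log scale and rounded to integers of at least 2). Phylogeny is excluded
from the imputation model; missingness in these housekeeping columns is not
expected to carry phylogenetic signal.

`bpmm_chained()` propagates imputation and phylogenetic uncertainty the way
the multiple-imputation animal-model literature does: the model runs as a
sequence of short sampling events, each warm-started from the previous
event's final state, cycling through the imputed datasets and through a
sample of trees, keeping one draw per event and discarding the first third as
burn-in. With identical inputs this is distributionally equivalent to one
long chain, which the test suite checks directly.

# Thermal optima from hatching curves

`fit_hatching_model()` fits hatched/set counts with fixed linear and
quadratic temperature effects and phylogenetic random intercepts and slopes
for both terms (3-by-3 unstructured covariance). Temperature is centred and
scaled internally to decorrelate the linear and quadratic columns — a purely
numerical choice; everything is back-transformed to degrees Celsius.
`derive_topt()` computes, per posterior draw, the vertex
`-(beta_f + beta_sp) / (2 (gamma_f + gamma_sp))`. Draws with non-negative
total curvature have no interior optimum; they are excluded and counted, and
a species' estimate is only reported when at least 95% of its draws are
concave. The threshold is a package choice: it keeps the vertex distribution
well defined while flagging species whose curvature is genuinely uncertain.
Species must have at least three distinct incubation temperatures (the
inclusion rule of the data the model is meant for); duplicate
species-temperature rows from different sources are kept separate so the
latent residual can absorb overdispersion.

# Ancestral reconstruction

Reproductive mode (oviparous/viviparous) is modelled with hidden-rate Markov
models: composite states pair the observed state with an unobserved rate
category, observed-state change and category switching cannot happen
simultaneously, and within-category rates plus adjacent-category switch rates
are free parameters (`hmm_rate_matrix()`). The likelihood is Felsenstein
pruning with matrix-exponential branch probabilities (one eigendecomposition
of Q per evaluation); the test suite proves it equal to exhaustive
enumeration on all trees up to six tips. Rates are optimised on the log
scale with box constraints (1e-9 to 100 per unit branch length) and random
restarts, plus a structured restart that splits a one-category fit into
slow/fast copies — hidden-rate likelihood surfaces are multimodal and this
start finds the heterogeneous optimum far more reliably. `fit_hmm()` reports
AIC; `select_rate_categories()` picks the category count by AIC minimum. The
root prior is uniform over composite states by default.

Marginal node probabilities (`marginal_states()`) use the standard two-pass
inside-outside computation with hidden categories summed out. Node states for
transition classification are argmax marginals; each internal node is
classified from its own state and its immediate descendants' states into
O→O, V→V, O→V, or V→O, per tree, and nodes are matched across a tree sample
by their descendant-tip bipartition, taking the most frequent category (ties
break deterministically O→O > V→V > O→V > V→O and are flagged).

Ancestral values of the continuous traits come from the three-trait model's
posterior: per draw, internal-node effects are sampled from their
Brownian-bridge conditional normal given the tip-level phylogenetic effects
and that draw's trait covariance. A node's thermal mismatch label compares
the 95% HPD interval of `P_bt - T_opt` with zero, and the alignment question
("does viviparity arise more often where optima align?") is a Pearson
chi-squared test on aligned/mismatched counts of O→O versus O→V nodes,
without continuity correction by default.

# The synthetic scenario and what it does (not) show

`sim_scenario()` generates the study conditions with known truth:

* a 224-tip pure-birth tree scaled to unit height, plus a sample of trees
  with lognormally jittered branch lengths (topology held fixed so nodes
  stay identifiable across the sample);
* three traits simulated as correlated Brownian motion with phylogenetic
  heritability 0.9 each, phylogenetic correlation -0.8 between `P_bt` and
  the gravid shift, weak (+0.3) `P_bt`-`T_opt` coupling; trait scales
  (`P_bt` sd 4, `T_opt` sd 2, g sd 1 across species) match the spread of the
  published species tables;
* reproductive mode evolving under two strongly separated rate regimes: a
  conserved background (rates 0.15 and 0.02 per unit tree height, so a few
  persistent viviparous clades arise and are retained) and three painted
  labile clades of 25-60 tips evolving at rates 5 and 6, giving a viviparous
  share of roughly a third of species. Painting the regime onto clades
  reproduces the empirical description of the system — a couple of clades in
  which transitions are concentrated — and gives AIC-based detection of the
  second rate category realistic power at 224 tips, which freely
  Markov-switching regimes do not (fast episodes then scatter into patches
  too small to detect);
* observed subsets sized like the study data (163 species with `P_bt`, 52
  with hatching data, 52 with gravid-shift studies, group splits aimed at
  the published mode ratios), with the observed `P_bt` and `T_opt` values
  affinely calibrated per mode to the published group means and SDs
  (32.41 +/- 4.15 and 29.5 +/- 4.06 for oviparous/viviparous `P_bt`;
  27.15 +/- 1.92 and 26.0 +/- 2.23 for `T_opt`). Calibration is an affine
  map per group, so ordering and correlation structure of the simulated
  values survive; it pins the data summaries to the study's printed values
  while recovery tests keep using the uncalibrated generating truth;
* hatching records at a latent-scale curvature of -0.15 (a +/-4 degree
  excursion roughly halves hatching success) with the number of temperature
  treatments per species drawn around 7.6 +/- 4.3, and gravid/non-gravid
  study records whose group summaries imply the species' true g;
* missingness injected completely at random (rate 0.3) into the sampling
  variance and sample-size columns — the columns the imputation stage fills.

Because missingness is MCAR and the residual structure is exactly the model's
own, passing recovery tests demonstrates the estimation machinery is
correct under its assumptions; it does not show robustness to informative
missingness, non-Brownian evolution, or model misspecification, none of
which the generator emulates.

# Problem sizes and numerical choices

Desk-scale defaults (`analysis_config()`) run the full pipeline in minutes on
one CPU: 11,000 iterations with 1,000 burn-in and thinning 10 for single
runs, 160 chained events of 60 iterations over 20 imputations and 10 trees,
and 3 optimizer restarts per hidden-rate fit. The `profile = "full"`
settings reproduce the full-scale protocol (1.1 million iterations, burn-in
100,000, thinning 500; 1,500 events of 2,000 iterations over 1,000 trees).
The test suite uses smaller trees (35-224 tips) and shorter chains chosen so
that each check still has the Monte-Carlo resolution its tolerance needs.

Degenerate inputs are handled explicitly: zero-length branches are allowed
(covariances stay well defined; eigenvalues are floored at 1e-10), constant
discrete characters are flagged and their rates driven to the lower bound,
species with all-convex hatching curves are withheld from `T_opt` tables,
empty contingency margins withhold the chi-squared test while still
returning counts, and the imputation donor pool shrinks with a warning when
fewer than k donors exist.

# Known limitations

* The binomial liability sampler is Metropolis-within-Gibbs; very sparse
  binomial data mix more slowly than the Gaussian components.
* Hidden-rate detection by AIC at 224 tips has limited power by nature;
  the scenario's regime was chosen (clade-painted, strongly separated) so
  that the question is answerable at all at this tree size.
* Fixed-effect priors are flat; there is no prior option for them.
* The chained sampler assumes the tree sample shares one topology when node
  identity matters downstream; with conflicting topologies, bipartition
  matching silently restricts summaries to the trees containing each node,
  which is the intended behaviour but reduces per-node tree counts.
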