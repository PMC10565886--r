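# gravitherm

Comparative phylogenetic analysis of maternal behavioural thermoregulation
and the evolution of live birth in squamate reptiles.

Gravid lizards and snakes face a conflict: adult females often prefer body
temperatures well above the incubation temperature that maximises their
embryos' hatching success. `gravitherm` implements the statistical machinery
to quantify that mismatch across a phylogeny and to ask whether gravid
females resolve it behaviourally — and whether that plasticity predates
evolutionary transitions from egg laying (oviparity, O) to live birth
(viviparity, V).

## What it computes

* **Effect sizes** — Hedges' *g* with heteroscedastic variances (SMDH):
  `g = J (m_g - m_ng) / s*`, `s*^2 = (sd_g^2 + sd_ng^2)/2`, with the exact
  small-sample factor `J` and its large-sample variance (`hedges_g()`,
  `pool_effects()`).
* **Bayesian phylogenetic mixed models** — a Gibbs sampler (`bpmm()`) for
  single- and multi-response models with species random effects covarying as
  Brownian motion on a tree: unstructured phylogenetic (`G`) and residual
  (`R`) covariances, group-split blocks, measurement-error weighting,
  missing-response augmentation, Gaussian and binomial-logit families, and
  random slopes. Phylogenetic heritability `H^2 = V_phylo/(V_phylo +
  V_resid)`, phylogenetic/residual correlations, posterior modes, 95% HPD
  intervals and pMCMC. Chained runs over imputed datasets and tree samples
  (`bpmm_chained()`), convergence diagnostics (`gelman_rubin()`).
* **Embryonic thermal optima** — binomial hatching-success curves with fixed
  and phylogenetic random linear/quadratic temperature terms; per-draw vertex
  `T_opt = -(beta_f + beta_sp) / (2 (gamma_f + gamma_sp))` with a concavity
  rule (`fit_hatching_model()`, `derive_topt()`).
* **Imputation** — predictive mean matching for missing sampling variances
  and sample sizes (`pmm_impute()`).
* **Ancestral reconstruction** — hidden-rate Markov models with AIC
  rate-category selection and marginal ancestral states (`fit_hmm()`,
  `select_rate_categories()`, `marginal_states()`); transition
  classification (O→O, V→V, O→V, V→O) aggregated over a tree sample by
  bipartition (`classify_transitions()`); Brownian-bridge ancestral values of
  the continuous traits (`ancestral_continuous()`); node-level thermal
  mismatch calls and the alignment chi-squared test (`mismatch_call()`,
  `transition_mismatch_test()`).
* **Synthetic data with known truth** — `sim_scenario()` and the `sim_*`
  generators reproduce the study's data shape (species counts, group
  moments, phylogenetic signal, correlation structure, clade-concentrated
  rate heterogeneity, patchy missingness) so every estimator is validated by
  recovery tests.

## Worked example

```r
library(gravitherm)

sc <- sim_scenario(n_tips = 64, n_trees = 4, n_pbt = 48, n_topt = 20,
                   n_g = 20, seed = 31)
cfg <- analysis_config(seed = 31, nitt = 2100, burnin = 600, thin = 10,
                       m_imputations = 3, events = 150,
                       iters_per_event = 12, n_trees = 4)
report <- run_full_analysis(sc, cfg)
report
```

```
Comparative analysis report
  H2 P_bt: PM 0.89 [0.59, 0.98]   H2 T_opt: PM 0.93 [0.65, 0.97]
  phylo cor(P_bt, T_opt): PM 0.97 [0.81, 0.99]
  phylo cor(P_bt, g): PM -0.92 [-0.98, -0.46]
  per-mode cor(P_bt, g): O PM -0.92 [-0.99, 0.49] | V PM -0.93 [-0.99, 0.26]
  mode contrast (V - O): PM -0.20 [-1.69, 0.51]
  hatching H2: PM 0.59 [0.30, 0.78]  mean drop at P_bt: PM 0.65 [0.61, 0.68]
  hidden-rate categories: 1
  alignment test: chi2 = 6.23  p = 0.0125
  max PSRF: 1.038  max |lag-1 autocorrelation|: 0.865
```

(Numbers vary with the seed and problem size; the generating truth here is
`H^2 = 0.9` per trait and phylogenetic `cor(P_bt, g) = -0.8`.) Reading the
report: both `P_bt` and `T_opt` evolve slowly (high phylogenetic
heritability); species with warm-running females shift their temperature
down most when gravid (negative `P_bt`-g correlation) in both reproductive
modes; the gravid shift does not differ between modes (contrast interval
spans zero); and holding embryos at maternal preferred temperatures would
cost roughly two thirds of hatching success in this simulated clade. At this
reduced tree size (64 tips) AIC keeps one rate category for reproductive
mode; the 224-tip default scenario has the power to detect the second
regime, as the acceptance run shows.

## Package layout

`R/trees.R` (Newick I/O, covariances, bipartitions), `R/simulate.R` +
`R/scenario.R` (generators with ground truth), `R/effects.R` (SMDH),
`R/impute.R` (PMM), `R/bpmm.R` + `R/bpmm-methods.R` + `R/chained.R` (the
MCMC engine), `R/topt.R` (hatching curves), `R/hmm.R` + `R/transitions.R`
(ancestral machinery), `R/pipeline.R` (orchestration). The methods vignette
(`vignettes/maternal-thermoregulation-methods.Rmd`) documents the models,
priors, numerical choices and the scenario's design in detail.
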