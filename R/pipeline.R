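#' Build and validate an analysis configuration
#'
#' Settings for [run_full_analysis()]. Defaults are desk-scale (minutes on one
#' CPU); `profile = "full"` switches the MCMC settings to the full-scale
#' profile (1,100,000 iterations, 100,000 burn-in, thinning 500, and
#' 20-dataset/1,500-event chained runs).
#'
#' @param seed master seed; every stage derives its stream from it.
#' @param nitt,burnin,thin MCMC settings for single-run models.
#' @param m_imputations completed datasets for the imputation stage.
#' @param events,iters_per_event chained-run settings (events must be
#'   divisible by `m_imputations`).
#' @param n_trees how many trees of the sample to use.
#' @param hmm_rmax largest number of hidden rate categories tried.
#' @param hmm_restarts optimizer restarts per hidden-rate fit.
#' @param hmm_refit_per_tree refit the hidden-rate model on every tree
#'   (`FALSE` reuses the rates fitted on the primary tree and only recomputes
#'   marginals per tree).
#' @param n_chains independent chains for convergence diagnostics.
#' @param profile `"desk"` or `"full"`.
#' @return list of class `"gravitherm_config"`.
#' @export
analysis_config <- function(seed = 1L, nitt = 11000L, burnin = 1000L,
                            thin = 10L, m_imputations = 20L, events = 160L,
                            iters_per_event = 60L, n_trees = 10L,
                            hmm_rmax = 2L, hmm_restarts = 3L,
                            hmm_refit_per_tree = FALSE, n_chains = 2L,
                            profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    nitt <- 1100000L; burnin <- 100000L; thin <- 500L
    m_imputations <- 20L; events <- 1500L; iters_per_event <- 2000L
    n_trees <- 1000L; hmm_refit_per_tree <- TRUE; hmm_restarts <- 10L
    n_chains <- 3L
  }
  stopifnot(nitt > burnin, n_trees >= 1L)
  if (events %% m_imputations != 0L)
    stop("events (", events, ") must be divisible by m_imputations (",
         m_imputations, ")")
  structure(list(seed = seed, nitt = nitt, burnin = burnin, thin = thin,
                 m_imputations = m_imputations, events = events,
                 iters_per_event = iters_per_event, n_trees = n_trees,
                 hmm_rmax = hmm_rmax, hmm_restarts = hmm_restarts,
                 hmm_refit_per_tree = hmm_refit_per_tree,
                 n_chains = n_chains, profile = profile),
            class = "gravitherm_config")
}

#' Contrast of the gravid shift between reproductive modes
#'
#' Fits Hedges' g on reproductive mode (fixed effect) with a phylogenetic
#' random intercept and returns the viviparous-minus-oviparous contrast.
#'
#' @param effects species-level effect table (`species`, `g`, `vi`) with a
#'   `mode` column (`"O"`/`"V"`).
#' @param tree `"phylo"`.
#' @param nitt,burnin,thin,seed MCMC settings.
#' @return list: `summary` ([posterior_summary()] of the contrast), `draws`,
#'   `fit`.
#' @export
mode_contrast <- function(effects, tree, nitt = 11000L, burnin = 1000L,
                          thin = 10L, seed = NULL) {
  tab <- table(effects$mode[!is.na(effects$g)])
  if (length(tab) < 2L || any(tab < 2L))
    stop("need at least two species with effect sizes per reproductive mode")
  effects$mode <- factor(effects$mode, levels = c("O", "V"))
  fit <- bpmm(g ~ mode, data = effects, tree = tree, mev = c(g = "vi"),
              nitt = nitt, burnin = burnin, thin = thin, seed = seed)
  draws <- fit$samples$b[, "modeV"]
  list(summary = posterior_summary(draws), draws = draws, fit = fit)
}

#' Laboratory vs. field check for the gravid shift
#'
#' Per reproductive mode, fits per-study Hedges' g on study type with both a
#' phylogenetic and an iid species random intercept (species can contribute
#' several studies) and returns the laboratory-minus-field contrast.
#'
#' @param study_effects per-study effect table (`species`, `g`, `vi`,
#'   `study_type`, `mode`).
#' @param tree `"phylo"`.
#' @param nitt,burnin,thin,seed MCMC settings.
#' @return named list (one element per mode): `summary`, `draws`, `fit`.
#' @export
labfield_check <- function(study_effects, tree, nitt = 11000L,
                           burnin = 1000L, thin = 10L, seed = NULL) {
  out <- list()
  for (mo in unique(study_effects$mode)) {
    d <- study_effects[study_effects$mode == mo, , drop = FALSE]
    if (length(unique(d$study_type)) < 2L)
      stop("mode ", mo, ": both study types must be present")
    d$study_type <- factor(d$study_type, levels = c("field", "laboratory"))
    fit <- bpmm(g ~ study_type, data = d, tree = prune_to_taxa(tree, d$species),
                mev = "vi", species_effect = TRUE,
                nitt = nitt, burnin = burnin, thin = thin, seed = seed)
    draws <- fit$samples$b[, "study_typelaboratory"]
    out[[mo]] <- list(summary = posterior_summary(draws), draws = draws,
                      fit = fit)
  }
  out
}

#' Relative drop in hatching success at the mothers' preferred temperature
#'
#' Per species with both a fitted hatching curve and a P_bt value, the
#' posterior of `1 - p(P_bt) / p(T_opt)`; species are averaged within each
#' draw and the across-species mean drop is summarised.
#'
#' @param fit hatching-model `"bpmm"` ([fit_hatching_model()]).
#' @param pbt_table data frame `species`, `pbt`.
#' @param min_concave concavity threshold for usable optima.
#' @return list: `per_species` (data frame of posterior mean drops),
#'   `mean_drop` ([posterior_summary()] of the across-species average),
#'   `draws`.
#' @export
hatching_drop_report <- function(fit, pbt_table, min_concave = 0.95) {
  sp <- intersect(fit$meta$species,
                  pbt_table$species[!is.na(pbt_table$pbt)])
  if (length(sp) == 0L) stop("no species overlap between fit and P_bt table")
  sc <- fit$meta$temp_scaling
  drops <- sapply(sp, function(s) {
    cf <- topt_coefs(fit, s)
    ok <- cf$gamma < 0
    if (mean(ok) < min_concave) return(rep(NA_real_, length(cf$u)))
    pbt <- pbt_table$pbt[match(s, pbt_table$species)]
    ts_pbt <- (pbt - sc["center"]) / sc["scale"]
    ts_opt <- -cf$beta / (2 * cf$gamma)
    p_pbt <- stats::plogis(cf$u + cf$beta * ts_pbt + cf$gamma * ts_pbt^2)
    p_opt <- stats::plogis(cf$u + cf$beta * ts_opt + cf$gamma * ts_opt^2)
    out <- 1 - p_pbt / p_opt
    out[!ok] <- NA
    out
  })
  keep <- colSums(!is.na(drops)) > 0L
  drops <- drops[, keep, drop = FALSE]
  draw_mean <- rowMeans(drops, na.rm = TRUE)
  list(per_species = data.frame(species = colnames(drops),
                                drop = colMeans(drops, na.rm = TRUE)),
       mean_drop = posterior_summary(draw_mean),
       draws = draw_mean)
}

#' Run the full comparative analysis
#'
#' Executes the pipeline on a scenario-shaped dataset: effect sizes ->
#' imputation -> chained multi-response models (P_bt/T_opt; P_bt/g; per-mode
#' split) -> mode contrast -> hatching model and thermal optima -> three-trait
#' ancestral model with node mismatch calls -> hidden-rate ancestral states,
#' transition classification and the alignment chi-squared test -> convergence
#' diagnostics.
#'
#' @param data a `"gravitherm_scenario"` (or a list with the same elements:
#'   `tree`, `trees`, `traits`, `gravid_studies`, `hatching`, `tip_states`).
#' @param config a `"gravitherm_config"` from [analysis_config()].
#' @param verbose print stage progress.
#' @return list of class `"gravitherm_report"`.
#' @export
run_full_analysis <- function(data, config = analysis_config(),
                              verbose = FALSE) {
  for (el in c("tree", "trees", "traits", "gravid_studies", "hatching",
               "tip_states"))
    if (is.null(data[[el]])) stop("data is missing element '", el, "'")
  cfg <- config
  set.seed(cfg$seed)
  say <- function(...) if (verbose) message("[stage] ", ...)
  tree <- data$tree
  trees <- data$trees[seq_len(min(cfg$n_trees, length(data$trees)))]
  traits <- data$traits

  # --- effect sizes -------------------------------------------------------
  say("effect sizes")
  study_eff <- hedges_g(data$gravid_studies)
  study_eff$mode <- traits$mode[match(study_eff$species, traits$species)]
  species_eff <- pool_effects(study_eff)
  traits$g <- species_eff$g[match(traits$species, species_eff$species)]
  traits$g_vi <- species_eff$vi[match(traits$species, species_eff$species)]

  # --- imputation of sampling variances / sizes ---------------------------
  say("imputation (predictive mean matching)")
  imp <- pmm_impute(traits,
                    targets = c("pbt_vi", "pbt_n", "topt_vi"),
                    predictors = c("pbt", "topt", "g"),
                    m = cfg$m_imputations, integer_cols = "pbt_n",
                    seed = cfg$seed + 1L)
  # vi for species without the trait itself stays irrelevant; zero it
  imps <- lapply(imp$imputations, function(d) {
    d$pbt_vi[is.na(d$pbt)] <- 0
    d$topt_vi[is.na(d$topt)] <- 0
    d$g_vi[is.na(d$g_vi)] <- 0
    d
  })

  # --- M1.1: P_bt / T_opt -------------------------------------------------
  say("M1.1 (P_bt, T_opt)")
  m1 <- bpmm_chained(imps, trees, cbind(pbt, topt) ~ 1,
                     species = "species",
                     mev = c(pbt = "pbt_vi", topt = "topt_vi"),
                     events = cfg$events,
                     iters_per_event = cfg$iters_per_event,
                     seed = cfg$seed + 2L)
  m1_stats <- list(
    h2_pbt = phylo_heritability(m1, "pbt")$summary,
    h2_topt = phylo_heritability(m1, "topt")$summary,
    cor_phylo = phylo_correlation(m1, c("pbt", "topt"))$summary,
    cor_resid = phylo_correlation(m1, c("pbt", "topt"), "residual")$summary)

  # --- M2.1: P_bt / Hedges' g --------------------------------------------
  say("M2.1 (P_bt, g)")
  m2 <- bpmm_chained(imps, trees, cbind(pbt, g) ~ 1,
                     species = "species",
                     mev = c(pbt = "pbt_vi", g = "g_vi"),
                     events = cfg$events,
                     iters_per_event = cfg$iters_per_event,
                     seed = cfg$seed + 3L)
  m2_stats <- list(
    h2_pbt = phylo_heritability(m2, "pbt")$summary,
    h2_g = phylo_heritability(m2, "g")$summary,
    cor_phylo = phylo_correlation(m2, c("pbt", "g"))$summary)

  # --- M3.1: mode contrast ------------------------------------------------
  say("M3.1 (mode contrast)")
  eff_mode <- species_eff
  eff_mode$mode <- traits$mode[match(eff_mode$species, traits$species)]
  m3 <- mode_contrast(eff_mode, prune_to_taxa(tree, eff_mode$species),
                      nitt = cfg$nitt, burnin = cfg$burnin, thin = cfg$thin,
                      seed = cfg$seed + 4L)

  # --- M4.1: per-mode covariance split ------------------------------------
  say("M4.1 (per-mode P_bt/g correlations)")
  m4 <- bpmm(cbind(pbt, g) ~ 0 + trait:mode, data = traits,
             tree = tree, groups = "mode",
             mev = c(pbt = "pbt_vi", g = "g_vi"),
             nitt = cfg$nitt, burnin = cfg$burnin, thin = cfg$thin,
             seed = cfg$seed + 5L)
  m4_stats <- list(
    cor_O = phylo_correlation(m4, c("pbt", "g"), group = "O")$summary,
    cor_V = phylo_correlation(m4, c("pbt", "g"), group = "V")$summary)

  # --- hatching model and thermal optima ----------------------------------
  say("hatching model / T_opt")
  hatch_tree <- prune_to_taxa(tree, unique(data$hatching$species))
  mh <- fit_hatching_model(data$hatching, hatch_tree,
                           nitt = cfg$nitt, burnin = cfg$burnin,
                           thin = cfg$thin, seed = cfg$seed + 6L)
  topt_tab <- topt_table(mh)
  h2_hatch <- phylo_heritability(mh, "(Intercept)")$summary
  drop_rep <- hatching_drop_report(mh, traits[, c("species", "pbt")])

  # --- M5.1: three-trait ancestral model ----------------------------------
  say("M5.1 (ancestral P_bt, T_opt, g)")
  m5 <- bpmm(cbind(pbt, topt, g) ~ 1, data = traits, tree = tree,
             mev = c(pbt = "pbt_vi", topt = "topt_vi", g = "g_vi"),
             nitt = cfg$nitt, burnin = cfg$burnin, thin = cfg$thin,
             seed = cfg$seed + 7L)
  anc <- ancestral_continuous(m5)
  node_mismatch <- lapply(seq_along(anc$keys), function(i)
    mismatch_call(anc$draws[i, "pbt", ], anc$draws[i, "topt", ]))
  mismatch_label <- vapply(node_mismatch, `[[`, character(1L), "label")

  # --- hidden-rate reconstruction and transitions -------------------------
  say("hidden-rate ancestral states")
  sel <- select_rate_categories(tree, data$tip_states, R_max = cfg$hmm_rmax,
                                n_restarts = cfg$hmm_restarts,
                                seed = cfg$seed + 8L)
  states_list <- lapply(trees, function(tr) {
    mod <- if (cfg$hmm_refit_per_tree)
      fit_hmm(tr, data$tip_states, R = sel$R,
              n_restarts = cfg$hmm_restarts)
    else sel$best
    marginal_states(tr, data$tip_states, mod)
  })
  calls <- classify_transitions(trees, states_list)
  calls$label <- mismatch_label[match(calls$key, anc$keys)]
  chi <- transition_mismatch_test(calls[!is.na(calls$label), ])

  # verification: reconstruction robustness to missing tip data (30% dropped)
  keep <- sample(tree$tip.label, round(0.7 * length(tree$tip.label)))
  sub_tree <- prune_to_taxa(tree, keep)
  sub_fit <- fit_hmm(sub_tree, data$tip_states[keep], R = sel$R,
                     n_restarts = cfg$hmm_restarts, seed = cfg$seed + 9L)
  n_full <- length(tree$tip.label)
  full_marg <- marginal_states(tree, data$tip_states, sel$best)
  sub_marg <- marginal_states(sub_tree, data$tip_states[keep], sub_fit)
  agreement <- state_agreement(
    node_keys(tree),
    full_marg[(n_full + 1L):(n_full + tree$Nnode), , drop = FALSE],
    node_keys(sub_tree),
    sub_marg[(length(keep) + 1L):(length(keep) + sub_tree$Nnode), ,
             drop = FALSE])

  # verification: laboratory vs field studies (per mode, where both present)
  lf <- NULL
  se <- study_eff[!is.na(study_eff$mode), , drop = FALSE]
  both <- vapply(split(se$study_type, se$mode),
                 function(x) length(unique(x)) >= 2L, logical(1L))
  if (length(both) && all(both)) {
    lf <- labfield_check(se, tree, nitt = cfg$nitt, burnin = cfg$burnin,
                         thin = cfg$thin, seed = cfg$seed + 10L)
    lf <- lapply(lf, function(x) x$summary)
  }

  # ancestral gravid shift by transition category (O->O vs O->V)
  g_by_cat <- lapply(c("O->O", "O->V"), function(ct) {
    ix <- which(anc$keys %in% calls$key[calls$category == ct])
    if (length(ix) == 0L) return(NULL)
    posterior_summary(colMeans(matrix(anc$draws[ix, "g", ],
                                      nrow = length(ix))))
  })
  names(g_by_cat) <- c("O->O", "O->V")

  # --- convergence diagnostics (independent chains of M2.1 design) --------
  say("diagnostics")
  diag_chains <- lapply(seq_len(cfg$n_chains), function(ch)
    bpmm(cbind(pbt, g) ~ 1, data = imps[[1L]], tree = tree,
         mev = c(pbt = "pbt_vi", g = "g_vi"),
         nitt = cfg$nitt, burnin = cfg$burnin, thin = cfg$thin,
         seed = cfg$seed + 100L + ch))
  psrf <- vapply(colnames(diag_chains[[1L]]$samples$b), function(pm)
    gelman_rubin(lapply(diag_chains, function(f) f$samples$b[, pm])),
    numeric(1L))
  ac1 <- vapply(colnames(diag_chains[[1L]]$samples$b), function(pm)
    chain_autocorrelation(diag_chains[[1L]]$samples$b[, pm], 1L),
    numeric(1L))

  structure(list(
    effects = species_eff, study_effects = study_eff,
    imputation = imp[c("cells", "m", "k")],
    m1 = m1_stats, m2 = m2_stats,
    m3 = list(contrast = m3$summary),
    m4 = m4_stats,
    hatching = list(h2 = h2_hatch, topt = topt_tab,
                    drop = drop_rep$mean_drop,
                    drop_per_species = drop_rep$per_species),
    ancestral = list(keys = anc$keys, mismatch = mismatch_label,
                     g_by_category = g_by_cat),
    hmm = list(R = sel$R, table = sel$table,
               missing_tip_agreement = agreement),
    labfield = lf,
    transitions = list(calls = calls[, c("key", "category", "label")],
                       chi2 = chi),
    diagnostics = list(psrf = psrf, autocorrelation = ac1),
    config = cfg), class = "gravitherm_report")
}

#' @export
print.gravitherm_report <- function(x, ...) {
  f <- function(s) sprintf("PM %.2f [%.2f, %.2f]", s$mode, s$ci[1L], s$ci[2L])
  cat("Comparative analysis report\n")
  cat("  H2 P_bt:", f(x$m1$h2_pbt), "  H2 T_opt:", f(x$m1$h2_topt), "\n")
  cat("  phylo cor(P_bt, T_opt):", f(x$m1$cor_phylo), "\n")
  cat("  phylo cor(P_bt, g):", f(x$m2$cor_phylo), "\n")
  cat("  per-mode cor(P_bt, g): O", f(x$m4$cor_O), "| V", f(x$m4$cor_V), "\n")
  cat("  mode contrast (V - O):", f(x$m3$contrast), "\n")
  cat("  hatching H2:", f(x$hatching$h2),
      " mean drop at P_bt:", f(x$hatching$drop), "\n")
  cat("  hidden-rate categories:", x$hmm$R, "\n")
  ch <- x$transitions$chi2
  cat("  alignment test: chi2 =",
      if (is.na(ch$statistic)) "withheld" else round(ch$statistic, 2),
      " p =", if (is.na(ch$p_value)) "-" else signif(ch$p_value, 3), "\n")
  cat("  max PSRF:", round(max(x$diagnostics$psrf), 3),
      " max |lag-1 autocorrelation|:",
      round(max(abs(x$diagnostics$autocorrelation)), 3), "\n")
  invisible(x)
}

#' Write a report as JSON
#'
#' Serialises the numeric content of a report (summaries flattened to
#' mode/CI/pMCMC) for machine consumption.
#'
#' @param report a `"gravitherm_report"`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  flat <- function(s) if (inherits(s, "bpmm_summary_stat"))
    list(mode = s$mode, ci = s$ci, pmcmc = s$pmcmc) else s
  out <- list(
    m1 = lapply(report$m1, flat), m2 = lapply(report$m2, flat),
    m3 = lapply(report$m3, flat), m4 = lapply(report$m4, flat),
    hatching = list(h2 = flat(report$hatching$h2),
                    drop = flat(report$hatching$drop)),
    hmm = list(R = report$hmm$R, table = report$hmm$table),
    chi2 = report$transitions$chi2[c("statistic", "df", "p_value")],
    diagnostics = report$diagnostics,
    seed = report$config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
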