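#' Default synthetic study scenario
#'
#' Generates a complete synthetic dataset with the statistical shape of the
#' squamate maternal-thermoregulation study, with full ground truth for
#' recovery tests:
#' \itemize{
#' \item a 224-tip ultrametric tree (unit height) plus a sample of trees with
#'   jittered branch lengths over the same topology;
#' \item reproductive mode evolving under a two-rate-category hidden Markov
#'   process (two clades switch to a fast regime), root state oviparous;
#' \item three phylogenetically correlated traits (P_bt, T_opt, Hedges' g)
#'   with H^2 = 0.9, phylogenetic cor(P_bt, g) = -0.8 and weak P_bt-T_opt
#'   coupling;
#' \item observed subsets sized like the study data (163 species with P_bt,
#'   52 with T_opt, 52 with gravid-shift studies), with observed P_bt and
#'   T_opt affinely calibrated per reproductive mode to the study's printed
#'   group means and SDs;
#' \item per-species hatching-success records (binomial counts over
#'   constant-temperature treatments) and gravid vs. non-gravid study records
#'   generating the effect sizes;
#' \item patchy missingness in sampling variances and sample sizes (the
#'   columns the imputation stage fills in).
#' }
#'
#' @param n_tips tips on the tree (default 224).
#' @param n_trees size of the jittered tree sample (default 50).
#' @param n_pbt,n_topt,n_g observed-species counts (defaults 163, 52, 52).
#' @param h2 phylogenetic heritability of the traits (default 0.9).
#' @param cor_pbt_g phylogenetic correlation between P_bt and the gravid
#'   shift (default -0.8).
#' @param cor_pbt_topt weak P_bt-T_opt phylogenetic coupling (default 0.3).
#' @param calibrate affinely match observed per-mode P_bt / T_opt moments to
#'   the printed study values (default TRUE).
#' @param miss_rate missingness rate for sampling-variance / sample-size
#'   columns (default 0.3).
#' @param seed integer master seed.
#' @return list of class `"gravitherm_scenario"`: `tree`, `trees`, `traits`
#'   (species table), `gravid_studies`, `hatching`, `tip_states`, `truth`,
#'   `config`.
#' @export
sim_scenario <- function(n_tips = 224L, n_trees = 50L, n_pbt = 163L,
                         n_topt = 52L, n_g = 52L, h2 = 0.9,
                         cor_pbt_g = -0.8, cor_pbt_topt = 0.3,
                         calibrate = TRUE, miss_rate = 0.3, seed = 1L) {
  set.seed(seed)
  stopifnot(n_pbt <= n_tips, n_topt <= n_tips, n_g <= n_tips)
  # printed study calibration targets: per-mode mean/SD of P_bt and T_opt
  targets <- list(
    pbt = list(O = c(32.41, 4.15), V = c(29.5, 4.06)),
    topt = list(O = c(27.15, 1.92), V = c(26.0, 2.23)))

  tree <- sim_tree(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / max(node_depths(tree))
  trees <- lapply(seq_len(n_trees), function(i) {
    tr <- tree
    tr$edge.length <- tr$edge.length *
      stats::rlnorm(length(tr$edge.length), 0, 0.1)
    tr
  })
  class(trees) <- "multiPhylo"

  # reproductive mode: slow conserved background plus a few labile clades
  # (two-category rate heterogeneity in the form the study describes);
  # oviparous root; rates per unit tree height
  clades <- pick_disjoint_clades(tree, k = 3L,
                                 lo = max(4L, round(n_tips * 25 / 224)),
                                 hi = max(8L, round(n_tips * 60 / 224)))
  disc <- sim_discrete_painted(tree, slow = c(0.15, 0.02), fast = c(5, 6),
                               clades = clades, root_state = 1L)
  mode <- ifelse(disc$tip_states == 1L, "O", "V")

  # traits on the unit-height tree: variances scaled so H^2 = h2
  sds <- c(pbt = 4, topt = 2, g = 1)
  corG <- matrix(c(1, cor_pbt_topt, cor_pbt_g,
                   cor_pbt_topt, 1, -0.2,
                   cor_pbt_g, -0.2, 1), 3L, 3L)
  G <- diag(sds * sqrt(h2)) %*% corG %*% diag(sds * sqrt(h2))
  R <- diag(sds^2 * (1 - h2))
  dimnames(G) <- dimnames(R) <- list(names(sds), names(sds))
  bm <- sim_correlated_bm(tree, means = c(pbt = 31, topt = 27, g = 0),
                          G = G, R = R)
  true_vals <- bm$tips

  # observed subsets: P_bt aims at the study's 103 oviparous / 61 viviparous
  # split, T_opt at 47/5, g at 20/32 (filled from the other mode if a group
  # runs short on the simulated character)
  pick_split <- function(n_o, n_v) {
    o <- which(mode == "O"); v <- which(mode == "V")
    ko <- min(n_o, length(o)); kv <- min(n_v, length(v))
    sel <- c(sample(o, ko), sample(v, kv))
    short <- (n_o + n_v) - length(sel)
    if (short > 0) sel <- c(sel, sample(setdiff(seq_len(n_tips), sel), short))
    sort(sel)
  }
  i_pbt <- pick_split(round(n_pbt * 103 / 164), n_pbt - round(n_pbt * 103 / 164))
  i_topt <- pick_split(round(n_topt * 47 / 52), n_topt - round(n_topt * 47 / 52))
  i_g <- pick_split(round(n_g * 20 / 52), n_g - round(n_g * 20 / 52))

  sp <- tree$tip.label
  traits <- data.frame(species = sp, mode = mode, stringsAsFactors = FALSE)

  # measured P_bt: species truth + study sampling error, then per-mode affine
  # calibration of the observed values to the printed moments
  pbt_sd <- stats::runif(n_tips, 1.5, 3)
  pbt_n <- sample(5:40, n_tips, replace = TRUE)
  pbt_vi <- pbt_sd^2 / pbt_n
  pbt_obs <- true_vals$pbt + stats::rnorm(n_tips, 0, sqrt(pbt_vi))
  traits$pbt <- NA_real_
  traits$pbt[i_pbt] <- pbt_obs[i_pbt]
  if (calibrate)
    traits$pbt <- calibrate_groups(traits$pbt, mode, targets$pbt)
  traits$pbt_vi <- ifelse(seq_len(n_tips) %in% i_pbt, pbt_vi, NA_real_)
  traits$pbt_n <- ifelse(seq_len(n_tips) %in% i_pbt, pbt_n, NA_real_)

  # T_opt dataset (the estimates table): truth + estimation error, calibrated
  topt_vi <- stats::runif(n_tips, 0.1, 0.8)
  topt_obs <- true_vals$topt + stats::rnorm(n_tips, 0, sqrt(topt_vi))
  traits$topt <- NA_real_
  traits$topt[i_topt] <- topt_obs[i_topt]
  if (calibrate)
    traits$topt <- calibrate_groups(traits$topt, mode, targets$topt)
  traits$topt_vi <- ifelse(seq_len(n_tips) %in% i_topt, topt_vi, NA_real_)

  # hatching records generated at the (calibrated) T_opt values
  topt_for_hatch <- traits$topt[i_topt]
  names(topt_for_hatch) <- sp[i_topt]
  hatching <- do.call(rbind, lapply(seq_along(topt_for_hatch), function(j) {
    nt <- max(3L, round(stats::rnorm(1L, 7.62, 4.29)))
    to <- topt_for_hatch[j]
    temps <- round(seq(to - 8, to + 8, length.out = nt), 1)
    sim_hatching(topt_for_hatch[j], curvature = -0.15, max_success = 0.9,
                 temps = temps,
                 eggs_per_temp = sample(10:40, 1L))
  }))
  rownames(hatching) <- NULL

  # gravid vs non-gravid studies: shift implied by the species' true g
  n_lab <- round(n_g * 37 / 73)
  gravid <- do.call(rbind, lapply(seq_along(i_g), function(j) {
    i <- i_g[j]
    wsd <- stats::runif(1L, 1.2, 3)
    sim_gravid_study(pbt_ng = true_vals$pbt[i],
                     shift = true_vals$g[i] * wsd, sd = wsd,
                     n_g = sample(5:30, 1L), n_ng = sample(5:30, 1L),
                     study_type = if (j <= n_lab) "laboratory" else "field",
                     species = sp[i])
  }))

  # patchy missingness in the error/sample-size columns (what gets imputed)
  inj <- inject_missing(traits[, c("pbt_vi", "pbt_n", "topt_vi")],
                        rates = c(pbt_vi = miss_rate, pbt_n = miss_rate,
                                  topt_vi = miss_rate))
  traits[, c("pbt_vi", "pbt_n", "topt_vi")] <- inj$table
  # a missing vi only makes sense where the trait itself is observed
  traits$pbt_vi[is.na(traits$pbt)] <- NA
  traits$pbt_n[is.na(traits$pbt)] <- NA
  traits$topt_vi[is.na(traits$topt)] <- NA

  rownames(traits) <- NULL
  structure(list(
    tree = tree, trees = trees, traits = traits,
    gravid_studies = gravid, hatching = hatching,
    tip_states = disc$tip_states,
    truth = list(node_values = bm$truth$node_values, G = G, R = R,
                 regimes = disc[c("slow", "fast", "clades", "category")],
                 node_states = disc$node_states,
                 species_values = true_vals, seed = seed),
    config = list(n_tips = n_tips, n_trees = n_trees, n_pbt = n_pbt,
                  n_topt = n_topt, n_g = n_g, h2 = h2,
                  cor_pbt_g = cor_pbt_g, cor_pbt_topt = cor_pbt_topt,
                  calibrate = calibrate, miss_rate = miss_rate,
                  seed = seed)),
    class = "gravitherm_scenario")
}

# affine per-group calibration of the observed entries of x to target
# c(mean, sd); preserves ordering and within-group correlation structure
calibrate_groups <- function(x, group, targets) {
  for (g in names(targets)) {
    i <- which(!is.na(x) & group == g)
    if (length(i) < 2L) next
    mu <- mean(x[i]); s <- stats::sd(x[i])
    if (s == 0) next
    x[i] <- targets[[g]][1L] + (x[i] - mu) * targets[[g]][2L] / s
  }
  x
}

#' @export
print.gravitherm_scenario <- function(x, ...) {
  cat("Synthetic maternal-thermoregulation scenario\n")
  cat("  tips:", length(x$tree$tip.label),
      " trees:", length(x$trees), "\n")
  cat("  observed: P_bt", sum(!is.na(x$traits$pbt)),
      "| T_opt", sum(!is.na(x$traits$topt)),
      "| gravid-shift species",
      length(unique(x$gravid_studies$species)), "\n")
  cat("  reproductive mode:", sum(x$traits$mode == "O"), "oviparous,",
      sum(x$traits$mode == "V"), "viviparous\n")
  invisible(x)
}
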