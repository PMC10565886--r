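#' Simulate an ultrametric birth-death tree
#'
#' Wrapper around [ape::rphylo()] (conditioned on the number of extant tips),
#' used to generate the phylogenies on which all recovery tests run.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth,death speciation and extinction rates; `birth > death >= 0`.
#' @param seed integer seed; simulations are bit-reproducible under it.
#' @return an ultrametric `"phylo"` with tips `t1..tn`.
#' @export
sim_tree <- function(n_tips, birth = 1, death = 0, seed = NULL) {
  stopifnot(n_tips >= 2, birth > death, death >= 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = death)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

# rows of Q must sum to 0, off-diagonals >= 0
validate_rate_matrix <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be square")
  offd <- Q; diag(offd) <- 0
  if (any(offd < 0)) stop("negative off-diagonal rate in Q")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("rows of Q must sum to 0")
  invisible(Q)
}

#' Simulate a discrete character down a tree
#'
#' States evolve by a continuous-time Markov chain: each node's state is drawn
#' from the matrix-exponential transition probabilities `expm(Q * t)` along its
#' parent branch. With a hidden-rate `Q` (see [hmm_rate_matrix()]) the composite
#' state carries both the observed state and the rate category; the returned tip
#' states are the observed part, and the full composite states at every node are
#' recorded as ground truth.
#'
#' @param tree a `"phylo"`.
#' @param Q rate matrix (rows sum to 0, off-diagonals >= 0). For hidden-rate
#'   models the dimension is `n_obs * n_categories` with states ordered
#'   (state 1, cat 1), (state 2, cat 1), (state 1, cat 2), ...
#' @param root_state composite root state index.
#' @param n_obs number of observed states encoded in `Q` (default 2).
#' @param seed integer seed.
#' @return list with `tip_states` (observed, integer, named by tip label),
#'   `node_states` (composite index for every node, tips included) and `Q`.
#' @export
sim_discrete <- function(tree, Q, root_state = 1L, n_obs = 2L, seed = NULL) {
  validate_rate_matrix(Q)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  k <- nrow(Q)
  state <- rep(NA_integer_, nn)
  state[n + 1L] <- as.integer(root_state)
  ord <- ape::reorder.phylo(tree, "postorder")
  e <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  el <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  # transition matrices per unique branch length
  ul <- unique(el)
  Pl <- lapply(ul, function(t) ctmc_prob(Q, t))
  idx <- match(el, ul)
  for (i in seq_len(nrow(e))) {
    p <- Pl[[idx[i]]][state[e[i, 1L]], ]
    state[e[i, 2L]] <- sample.int(k, 1L, prob = p)
  }
  tips <- ((state[seq_len(n)] - 1L) %% n_obs) + 1L
  names(tips) <- tree$tip.label
  list(tip_states = tips, node_states = state, Q = Q)
}

# exp(Q t) via eigendecomposition, with clipping of round-off negatives.
ctmc_prob <- function(Q, t) {
  if (t == 0) return(diag(nrow(Q)))
  eg <- eigen(Q)
  P <- eg$vectors %*% diag(exp(eg$values * t), nrow(Q)) %*% solve(eg$vectors)
  P <- Re(P)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate a binary character under clade-painted rate regimes
#'
#' Two-rate-category evolution in the form comparative studies describe it: a
#' slow background regime over most of the tree and designated clades evolving
#' under a fast regime. Each branch uses the 2-state transition probabilities
#' of its regime (`expm(Q_cat * t)`); the rate category of a branch is fixed by
#' the painting. This is the generating process behind the default scenario's
#' reproductive-mode character: lineages in a few labile clades gain and lose
#' live birth at much higher rates than the conserved background.
#'
#' @param tree a `"phylo"`.
#' @param slow,fast length-2 rates `c(1 -> 2, 2 -> 1)` for the background and
#'   painted regimes.
#' @param clades internal node numbers whose descendants (branches below the
#'   node) evolve under the fast regime.
#' @param root_state observed root state (1 or 2).
#' @param seed integer seed.
#' @return list: `tip_states` (observed, named), `node_states` (all nodes),
#'   `category` (per-node regime, 1 = slow / 2 = fast), `slow`, `fast`,
#'   `clades`.
#' @export
sim_discrete_painted <- function(tree, slow, fast, clades, root_state = 1L,
                                 seed = NULL) {
  stopifnot(length(slow) == 2L, length(fast) == 2L, all(slow >= 0),
            all(fast >= 0))
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  desc <- descendant_tips(tree)
  cat_of <- rep(1L, nn)
  for (cl in clades) {
    inside <- vapply(seq_len(nn), function(v)
      all(desc[[v]] %in% desc[[cl]]), logical(1L))
    cat_of[inside] <- 2L
    cat_of[cl] <- 2L
  }
  Qs <- list(
    matrix(c(-slow[1L], slow[1L], slow[2L], -slow[2L]), 2L, byrow = TRUE),
    matrix(c(-fast[1L], fast[1L], fast[2L], -fast[2L]), 2L, byrow = TRUE))
  st <- rep(NA_integer_, nn)
  st[n + 1L] <- as.integer(root_state)
  ord <- ape::reorder.phylo(tree, "postorder")
  e <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  el <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  for (i in seq_len(nrow(e))) {
    P <- ctmc_prob(Qs[[cat_of[e[i, 2L]]]], el[i])
    st[e[i, 2L]] <- sample.int(2L, 1L, prob = P[st[e[i, 1L]], ])
  }
  tips <- st[seq_len(n)]
  names(tips) <- tree$tip.label
  list(tip_states = tips, node_states = st, category = cat_of,
       slow = slow, fast = fast, clades = clades)
}

#' Pick disjoint clades of a given size band
#'
#' Utility for regime painting: returns up to `k` non-overlapping internal
#' nodes whose clades contain between `lo` and `hi` tips, preferring the first
#' found in node order.
#'
#' @param tree a `"phylo"`.
#' @param k how many clades.
#' @param lo,hi clade-size band (tips).
#' @return integer vector of internal node numbers (possibly shorter than `k`).
#' @export
pick_disjoint_clades <- function(tree, k = 3L, lo = 25L, hi = 60L) {
  n <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  internal <- (n + 1L):(n + tree$Nnode)
  sizes <- lengths(desc[internal])
  cand <- internal[sizes >= lo & sizes <= hi]
  sel <- integer()
  for (v in cand) {
    if (all(vapply(sel, function(u)
      length(intersect(desc[[u]], desc[[v]])) == 0L, logical(1L))))
      sel <- c(sel, v)
    if (length(sel) == k) break
  }
  sel
}

#' Simulate phylogenetically correlated traits (multivariate Brownian motion)
#'
#' Tip value = trait mean + Brownian deviation (covariance `G` scaled by shared
#' branch lengths) + independent residual (covariance `R`). True values at every
#' internal node are drawn jointly from the same process and returned as ground
#' truth, which is what ancestral-reconstruction recovery tests compare against.
#'
#' @param tree a `"phylo"`.
#' @param means numeric vector of trait means (root values).
#' @param G among-trait phylogenetic covariance (k x k, PSD).
#' @param R among-trait residual covariance (k x k, PSD).
#' @param seed integer seed.
#' @param empirical_groups optional list for per-group moment calibration (see
#'   [sim_scenario()]); not used directly here.
#' @return list with `tips` (data frame species x traits) and `truth` (list:
#'   `node_values` matrix (all nodes x traits, phylogenetic component + mean),
#'   `G`, `R`, `means`).
#' @export
sim_correlated_bm <- function(tree, means, G, R = diag(0, length(means)),
                              seed = NULL) {
  k <- length(means)
  G <- as.matrix(G); R <- as.matrix(R)
  if (!all(dim(G) == k) || !all(dim(R) == k))
    stop("dimension mismatch between means, G and R")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  C <- phylo_covariance_full(tree)   # all nodes
  nn <- nrow(C)
  # vec over nodes within trait, traits stacked: cov = G kron C
  L_C <- chol_psd(C)
  L_G <- chol_psd(G)
  Zm <- matrix(stats::rnorm(nn * k), nn, k)
  A <- L_C %*% Zm %*% t(L_G)                     # nodes x traits, cov G (x) C
  node_values <- sweep(A, 2L, means, "+")
  E <- matrix(stats::rnorm(n * k), n, k) %*% chol_psd(R)
  tips <- node_values[seq_len(n), , drop = FALSE] + E
  rownames(tips) <- tree$tip.label
  colnames(tips) <- names(means) %||% paste0("trait", seq_len(k))
  colnames(node_values) <- colnames(tips)
  list(tips = as.data.frame(tips),
       truth = list(node_values = node_values, G = G, R = R, means = means))
}

# lower-triangular factor of a PSD matrix (pivoted-safe via eigen)
chol_psd <- function(M) {
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  v <- pmax(eg$values, 0)
  eg$vectors %*% diag(sqrt(v), length(v)) %*% t(eg$vectors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate hatching-success records for one or more species
#'
#' Hatching counts are binomial with success probability following a concave
#' quadratic on the logit scale with vertex at the species' thermal optimum:
#' `logit(p) = logit(max_success) + curvature * (T - T_opt)^2`.
#'
#' @param species_topt named numeric vector of true thermal optima (degrees C).
#' @param curvature latent-scale quadratic coefficient (< 0). The default
#'   -0.15 makes a +/-4 degree excursion roughly halve hatching success, the
#'   regime reported for squamates.
#' @param max_success peak hatching probability at the vertex.
#' @param temps incubation temperatures (degrees C) used for every species.
#' @param eggs_per_temp clutch size per temperature treatment.
#' @param seed integer seed.
#' @return data frame: `species`, `temperature`, `n_eggs`, `n_hatched`,
#'   `source`.
#' @export
sim_hatching <- function(species_topt, curvature = -0.15, max_success = 0.9,
                         temps = seq(20, 36, by = 4), eggs_per_temp = 30,
                         seed = NULL) {
  stopifnot(curvature < 0, length(temps) >= 1, eggs_per_temp >= 1)
  if (!is.null(seed)) set.seed(seed)
  sp <- names(species_topt) %||% paste0("sp", seq_along(species_topt))
  out <- do.call(rbind, lapply(seq_along(species_topt), function(i) {
    eta <- stats::qlogis(max_success) + curvature * (temps - species_topt[i])^2
    p <- stats::plogis(eta)
    data.frame(species = sp[i], temperature = temps,
               n_eggs = eggs_per_temp,
               n_hatched = stats::rbinom(length(temps), eggs_per_temp, p),
               source = "sim", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a gravid vs. non-gravid body-temperature study
#'
#' Two normal samples (gravid mean `pbt_ng + shift`, non-gravid mean `pbt_ng`,
#' common SD) summarised the way comparative studies report them: group means,
#' SDs and sample sizes.
#'
#' @param pbt_ng non-gravid preferred body temperature (degrees C).
#' @param shift gravid minus non-gravid mean shift (degrees C).
#' @param sd within-group SD (> 0).
#' @param n_g,n_ng group sample sizes (>= 2).
#' @param study_type `"laboratory"` or `"field"`.
#' @param species species label.
#' @param seed integer seed.
#' @return one-row data frame with the study record.
#' @export
sim_gravid_study <- function(pbt_ng, shift, sd = 2, n_g = 15, n_ng = 15,
                             study_type = "laboratory", species = "sp",
                             seed = NULL) {
  stopifnot(sd > 0, n_g >= 2, n_ng >= 2)
  if (!is.null(seed)) set.seed(seed)
  xg <- stats::rnorm(n_g, pbt_ng + shift, sd)
  xn <- stats::rnorm(n_ng, pbt_ng, sd)
  data.frame(species = species,
             mean_g = mean(xg), sd_g = stats::sd(xg), n_g = n_g,
             mean_ng = mean(xn), sd_ng = stats::sd(xn), n_ng = n_ng,
             study_type = study_type, source = "sim",
             stringsAsFactors = FALSE)
}

#' Mask table cells completely at random
#'
#' @param table data frame.
#' @param rates named numeric vector of per-column missingness rates in `[0,1]`.
#' @param seed integer seed.
#' @return list `table` (masked copy) and `mask` (logical data frame, TRUE where
#'   masked); the caller keeps the original as ground truth.
#' @export
inject_missing <- function(table, rates, seed = NULL) {
  stopifnot(all(rates >= 0), all(rates <= 1))
  if (!is.null(seed)) set.seed(seed)
  mask <- as.data.frame(matrix(FALSE, nrow(table), ncol(table)),
                        row.names = rownames(table))
  names(mask) <- names(table)
  for (col in names(rates)) {
    m <- stats::runif(nrow(table)) < rates[[col]]
    table[[col]][m] <- NA
    mask[[col]] <- m
  }
  list(table = table, mask = mask)
}
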