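#' Build a hidden-rate rate matrix
#'
#' Composite states are (observed state, rate category) pairs ordered
#' (1,cat1), (2,cat1), (1,cat2), (2,cat2), ... For a binary character the
#' observed states are 1 = oviparous, 2 = viviparous. Within category `c` the
#' observed character changes at rates `obs_rates[c, 1]` (1 -> 2) and
#' `obs_rates[c, 2]` (2 -> 1); categories switch between neighbours at rates
#' `switch_rates[c, 1]` (c -> c+1) and `switch_rates[c, 2]` (c+1 -> c),
#' identical for both observed states. Entries that would change observed state
#' and category simultaneously are zero (the standard hidden-rates
#' construction).
#'
#' @param obs_rates matrix `R x 2` of within-category transition rates.
#' @param switch_rates matrix `(R-1) x 2` of category switching rates (ignored
#'   when `R = 1`; may be `NULL` then).
#' @return composite rate matrix of dimension `2R x 2R` (rows sum to zero).
#' @export
hmm_rate_matrix <- function(obs_rates, switch_rates = NULL) {
  obs_rates <- matrix(obs_rates, ncol = 2L)
  R <- nrow(obs_rates)
  if (R > 1L) {
    switch_rates <- matrix(switch_rates, ncol = 2L)
    stopifnot(nrow(switch_rates) == R - 1L)
  }
  k <- 2L * R
  Q <- matrix(0, k, k)
  idx <- function(o, c) (c - 1L) * 2L + o
  for (c in seq_len(R)) {
    Q[idx(1L, c), idx(2L, c)] <- obs_rates[c, 1L]
    Q[idx(2L, c), idx(1L, c)] <- obs_rates[c, 2L]
    if (c < R) {
      for (o in 1:2) {
        Q[idx(o, c), idx(o, c + 1L)] <- switch_rates[c, 1L]
        Q[idx(o, c + 1L), idx(o, c)] <- switch_rates[c, 2L]
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# number of free rates for R categories of a binary character
hmm_n_params <- function(R) 2L * R + 2L * (R - 1L)

hmm_pack <- function(Q, R) {
  idx <- function(o, c) (c - 1L) * 2L + o
  obs <- t(vapply(seq_len(R), function(c)
    c(Q[idx(1L, c), idx(2L, c)], Q[idx(2L, c), idx(1L, c)]), numeric(2L)))
  sw <- if (R > 1L) t(vapply(seq_len(R - 1L), function(c)
    c(Q[idx(1L, c), idx(1L, c + 1L)], Q[idx(1L, c + 1L), idx(1L, c)]),
    numeric(2L))) else NULL
  c(t(obs), if (!is.null(sw)) t(sw))
}

hmm_unpack <- function(par, R) {
  obs <- matrix(par[seq_len(2L * R)], ncol = 2L, byrow = TRUE)
  sw <- if (R > 1L)
    matrix(par[2L * R + seq_len(2L * (R - 1L))], ncol = 2L, byrow = TRUE)
  else NULL
  hmm_rate_matrix(obs, sw)
}

# per-edge transition matrices: one eigendecomposition of Q, then
# P(t) = V exp(diag(lambda) t) V^-1 for every branch length at once
edge_probs <- function(Q, lens) {
  eg <- eigen(Q)
  V <- eg$vectors
  Vi <- solve(V)
  ul <- unique(lens)
  E <- exp(outer(ul, eg$values))
  Pl <- lapply(seq_along(ul), function(i) {
    P <- Re(V %*% (E[i, ] * Vi))
    P[P < 0] <- 0
    P / rowSums(P)
  })
  Pl[match(lens, ul)]
}

# tip partial likelihoods: 1 on every composite state whose observed part
# matches; the hidden category is unobserved.
tip_partials <- function(tree, tip_states, k, n_obs = 2L) {
  n <- length(tree$tip.label)
  st <- tip_states[tree$tip.label]
  if (anyNA(st)) stop("tip states missing for: ",
                      paste(tree$tip.label[is.na(st)], collapse = ", "))
  if (!all(st %in% seq_len(n_obs))) stop("unknown state code in tip states")
  Fm <- matrix(0, n, k)
  obs_of <- ((seq_len(k) - 1L) %% n_obs) + 1L
  for (i in seq_len(n)) Fm[i, obs_of == st[i]] <- 1
  Fm
}

# Felsenstein pruning pass. Returns list with per-node partials (scaled),
# per-node log scale factors, and the total log-likelihood.
pruning_pass <- function(tree, tip_states, Q, root_prior = NULL,
                         n_obs = 2L) {
  k <- nrow(Q)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  ord <- ape::reorder.phylo(tree, "postorder")
  P <- edge_probs(Q, ord$edge.length)
  Fm <- matrix(0, nn, k)
  Fm[seq_len(n), ] <- tip_partials(tree, tip_states, k, n_obs)
  logscale <- numeric(nn)
  seen <- logical(nn)
  seen[seq_len(n)] <- TRUE
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    msg <- as.vector(P[[i]] %*% Fm[ch, ])
    if (!seen[p]) {
      Fm[p, ] <- msg
      seen[p] <- TRUE
    } else {
      Fm[p, ] <- Fm[p, ] * msg
    }
    logscale[p] <- logscale[p] + logscale[ch]
    mx <- max(Fm[p, ])
    if (mx > 0 && (mx > 1e12 || mx < 1e-12)) {
      Fm[p, ] <- Fm[p, ] / mx
      logscale[p] <- logscale[p] + log(mx)
    }
  }
  root <- n + 1L
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  lik <- sum(root_prior * Fm[root, ])
  list(partials = Fm, logscale = logscale, P = P, order = ord,
       root_prior = root_prior,
       loglik = if (lik > 0) log(lik) + logscale[root] else -Inf)
}

#' Log-likelihood of tip states under a (hidden-rate) Markov model
#'
#' Felsenstein pruning with matrix-exponential branch transition probabilities.
#' Hidden categories are summed out at the tips; the root uses `root_prior`
#' (equal probability over all composite states by default).
#'
#' @param tree a `"phylo"`.
#' @param tip_states named integer vector (1 = oviparous, 2 = viviparous),
#'   names covering every tip.
#' @param Q composite rate matrix, e.g. from [hmm_rate_matrix()].
#' @param root_prior optional probability vector over composite states.
#' @return log-likelihood (scalar).
#' @export
mk_likelihood <- function(tree, tip_states, Q, root_prior = NULL) {
  validate_rate_matrix(Q)
  pruning_pass(tree, tip_states, Q, root_prior)$loglik
}

#' Fit a hidden-rate Markov model by maximum likelihood
#'
#' Rates are optimised on the log scale with box constraints and multiple
#' random restarts (the likelihood surface is multimodal for hidden-rate
#' models).
#'
#' @param tree a `"phylo"`.
#' @param tip_states named integer vector of observed states (1/2).
#' @param R number of rate categories (>= 1).
#' @param n_restarts random restarts (default 10).
#' @param rate_bounds lower/upper bounds on rates per unit branch length.
#' @param root_prior optional root prior over composite states.
#' @param seed integer seed for restart draws.
#' @return object of class `"hmm_fit"`: `Q`, `rates` (named vector), `R`,
#'   `loglik`, `n_params`, `AIC`, `convergence`, `degenerate` flag.
#' @export
fit_hmm <- function(tree, tip_states, R = 1L, n_restarts = 10L,
                    rate_bounds = c(1e-9, 100), root_prior = NULL,
                    seed = NULL) {
  stopifnot(R >= 1L)
  if (!is.null(seed)) set.seed(seed)
  st <- tip_states[tree$tip.label]
  constant <- length(unique(st)) == 1L
  np <- hmm_n_params(R)
  lb <- log(rate_bounds[1L]); ub <- log(rate_bounds[2L])
  nll <- function(logpar) {
    Q <- hmm_unpack(exp(logpar), R)
    ll <- mk_likelihood(tree, st, Q, root_prior)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # data-informed central start: parsimony-flavoured rate guess
  depth <- max(node_depths(tree))
  base <- max(length(unique(st)) - 1, 0.5) / depth
  starts <- list(log(rep(base, np)))
  if (R > 1L) {
    # structured start: split a one-category quick fit into slow/fast copies
    f1 <- fit_hmm(tree, st, R = 1L, n_restarts = 2L,
                  rate_bounds = rate_bounds, root_prior = root_prior)
    obs1 <- pmin(pmax(f1$rates, rate_bounds[1L] * 10), rate_bounds[2L] / 10)
    spl <- as.vector(vapply(seq_len(R), function(c)
      obs1 * 10^(c - (R + 1) / 2), numeric(2L)))
    starts[[2L]] <- pmin(pmax(log(c(spl, rep(base, 2L * (R - 1L)))), lb), ub)
  }
  while (length(starts) < n_restarts)
    starts[[length(starts) + 1L]] <-
      pmin(pmax(log(base) + stats::rnorm(np, 0, 1.5), lb), ub)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::nlminb(s, nll, lower = lb, upper = ub,
                    control = list(iter.max = 500L, eval.max = 1200L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("optimizer failed to converge from every restart")
  rates <- exp(best$par)
  Q <- hmm_unpack(rates, R)
  ll <- -best$objective
  structure(list(Q = Q, rates = rates, R = R, loglik = ll, n_params = np,
                 AIC = 2 * np - 2 * ll, convergence = best$convergence,
                 degenerate = constant,
                 root_prior = root_prior), class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Hidden-rate Markov model: ", x$R, " rate categor",
      if (x$R == 1L) "y" else "ies", "\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 6),
      "  AIC:", format(x$AIC, digits = 6), "\n")
  if (x$degenerate) cat("  note: constant character (degenerate fit)\n")
  invisible(x)
}

#' Choose the number of hidden rate categories by AIC
#'
#' Fits models with `R = 1..R_max` categories and returns the AIC-minimising
#' one along with the model table.
#'
#' @inheritParams fit_hmm
#' @param R_max largest number of categories to try.
#' @return list: `R` (chosen), `table` (data frame R/loglik/n_params/AIC),
#'   `fits` (list of `"hmm_fit"`), `best` (the chosen fit).
#' @export
select_rate_categories <- function(tree, tip_states, R_max = 2L,
                                   n_restarts = 10L, seed = NULL, ...) {
  stopifnot(R_max >= 1L)
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(seq_len(R_max), function(R)
    fit_hmm(tree, tip_states, R = R, n_restarts = n_restarts, ...))
  tab <- data.frame(R = seq_len(R_max),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    n_params = vapply(fits, `[[`, integer(1), "n_params"),
                    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  best <- which.min(tab$AIC)
  list(R = tab$R[best], table = tab, fits = fits, best = fits[[best]])
}

#' Marginal ancestral state probabilities
#'
#' Standard two-pass computation: a post-order (pruning) pass and a pre-order
#' (outside) pass; the node marginal is the normalised product of inside and
#' outside partials, with hidden categories summed out to observed-state
#' probabilities.
#'
#' @param tree a `"phylo"`.
#' @param tip_states named integer vector of observed states (1/2).
#' @param model an `"hmm_fit"` or a rate matrix `Q`.
#' @param root_prior optional prior over composite states.
#' @return matrix (all nodes x 2 observed states) of marginal probabilities;
#'   tip rows are their observed states. Rows sum to one.
#' @export
marginal_states <- function(tree, tip_states, model, root_prior = NULL) {
  Q <- if (inherits(model, "hmm_fit")) model$Q else model
  if (is.null(root_prior) && inherits(model, "hmm_fit"))
    root_prior <- model$root_prior
  up <- pruning_pass(tree, tip_states, Q, root_prior)
  k <- nrow(Q)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  root <- n + 1L
  e <- up$order$edge
  Gm <- matrix(0, nn, k)
  Gm[root, ] <- up$root_prior
  # messages M_child = P %*% F_child for every edge (postorder order)
  M <- matrix(0, nrow(e), k)
  for (i in seq_len(nrow(e)))
    M[i, ] <- as.vector(up$P[[i]] %*% up$partials[e[i, 2L], ])
  # pre-order: parents before children
  for (i in rev(seq_len(nrow(e)))) {
    p <- e[i, 1L]; ch <- e[i, 2L]
    sib <- which(e[, 1L] == p)
    sib <- sib[sib != i]
    S <- Gm[p, ]
    for (j in sib) S <- S * M[j, ]
    g <- as.vector(t(up$P[[i]]) %*% S)
    tot <- sum(g)
    Gm[ch, ] <- if (tot > 0) g / tot else g
  }
  marg <- up$partials * Gm
  obs_of <- ((seq_len(k) - 1L) %% 2L) + 1L
  out <- cbind(rowSums(marg[, obs_of == 1L, drop = FALSE]),
               rowSums(marg[, obs_of == 2L, drop = FALSE]))
  out <- out / rowSums(out)
  colnames(out) <- c("state1", "state2")
  out
}
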