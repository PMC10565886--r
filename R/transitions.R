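#' Classify reproductive-mode transitions at internal nodes
#'
#' Per tree, each internal node's state is the argmax of its marginal
#' probabilities and the node is placed in one of four categories from its own
#' state and its immediate descendants' states: oviparous with only oviparous
#' descendants (`"O->O"`), viviparous with only viviparous descendants
#' (`"V->V"`), oviparous with at least one viviparous descendant (`"O->V"`) and
#' viviparous with at least one oviparous descendant (`"V->O"`). Nodes are
#' matched across trees by descendant-tip bipartition and each bipartition gets
#' the most frequent category over the trees that contain it; ties are broken
#' by the fixed priority O->O > V->V > O->V > V->O and flagged.
#'
#' @param trees a `"multiPhylo"` (or list) of trees over one tip set.
#' @param states_list list of marginal-state matrices, one per tree, as
#'   returned by [marginal_states()] (rows = all nodes of that tree).
#' @return data frame keyed by bipartition: `key`, `category`, per-category
#'   counts, `n_trees`, `tie` flag.
#' @export
classify_transitions <- function(trees, states_list) {
  stopifnot(length(trees) == length(states_list))
  cats <- c("O->O", "V->V", "O->V", "V->O")
  acc <- new.env(parent = emptyenv())
  for (j in seq_along(trees)) {
    tr <- trees[[j]]
    marg <- states_list[[j]]
    n <- length(tr$tip.label)
    state <- ifelse(marg[, 2L] > marg[, 1L], 2L, 1L)  # all nodes
    keys <- node_keys(tr)
    for (nd in (n + 1L):(n + tr$Nnode)) {
      ch <- tr$edge[tr$edge[, 1L] == nd, 2L]
      own <- state[nd]
      chst <- state[ch]
      cat_nd <- if (own == 1L) {
        if (any(chst == 2L)) "O->V" else "O->O"
      } else {
        if (any(chst == 1L)) "V->O" else "V->V"
      }
      key <- keys[[as.character(nd)]]
      cur <- if (!is.null(acc[[key]])) acc[[key]] else
        stats::setNames(integer(4L), cats)
      cur[cat_nd] <- cur[cat_nd] + 1L
      acc[[key]] <- cur
    }
  }
  keys <- ls(acc)
  counts <- t(vapply(keys, function(k) acc[[k]], integer(4L)))
  colnames(counts) <- cats
  best <- apply(counts, 1L, function(x) {
    mx <- max(x)
    cats[which(x == mx)[1L]]  # cats ordered by tie priority
  })
  tie <- apply(counts, 1L, function(x) sum(x == max(x)) > 1L)
  if (any(tie))
    message(sum(tie), " node(s) had tied transition categories; ",
            "priority order O->O > V->V > O->V > V->O applied")
  out <- data.frame(key = keys, category = best, counts,
                    n_trees = rowSums(counts), tie = tie,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Thermal-mismatch call from joint node posteriors
#'
#' Labels a node by the 95% HPD interval of the posterior of `P_bt - T_opt`:
#' `"aligned"` if the interval spans 0, `"T_opt-lower"` if entirely positive
#' (embryo optimum below adult preference), `"T_opt-higher"` if entirely
#' negative.
#'
#' @param pbt,topt numeric vectors of joint posterior draws (>= 100).
#' @param prob interval mass (default 0.95).
#' @return list: `label`, `interval`, `mean_diff`, `draws` (count).
#' @export
mismatch_call <- function(pbt, topt, prob = 0.95) {
  stopifnot(length(pbt) == length(topt), length(pbt) >= 100)
  d <- pbt - topt
  ci <- hpd_interval(d, prob)
  label <- if (ci[1L] > 0) "T_opt-lower"
  else if (ci[2L] < 0) "T_opt-higher"
  else "aligned"
  list(label = label, interval = ci, mean_diff = mean(d), draws = length(d))
}

#' Do mismatches differ between stationary and transition nodes?
#'
#' Pearson chi-squared test (df = 1, no continuity correction by default) of
#' aligned vs. mismatched counts for oviparous nodes with only oviparous
#' descendants against oviparous nodes with at least one viviparous descendant.
#'
#' @param node_calls data frame with columns `category` (`"O->O"`/`"O->V"`;
#'   other categories are dropped) and `label` (from [mismatch_call()]).
#' @param correct logical; apply Yates continuity correction.
#' @return list: `table` (2x2 counts), `statistic`, `df`, `p_value`, `status`.
#' @export
transition_mismatch_test <- function(node_calls, correct = FALSE) {
  d <- node_calls[node_calls$category %in% c("O->O", "O->V"), , drop = FALSE]
  aligned <- factor(ifelse(d$label == "aligned", "aligned", "mismatched"),
                    levels = c("aligned", "mismatched"))
  category <- factor(d$category, levels = c("O->O", "O->V"))
  tab <- table(category, aligned)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    return(list(table = tab, statistic = NA_real_, df = 1L,
                p_value = NA_real_,
                status = "withheld: empty margin in contingency table"))
  # small expected counts are routine here; the statistic is still reported
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(table = tab, statistic = unname(ht$statistic), df = 1L,
       p_value = ht$p.value, status = "ok")
}

#' Percentage of shared nodes reconstructed in the same state
#'
#' Compares argmax observed states of two reconstructions over the bipartitions
#' they share (reconstructions may come from different trees or tip subsets).
#'
#' @param keys_ref,keys_cmp character vectors of bipartition keys.
#' @param states_ref,states_cmp marginal matrices (internal nodes in the same
#'   order as the key vectors).
#' @return percentage (0-100) of shared keys with identical argmax state.
#' @export
state_agreement <- function(keys_ref, states_ref, keys_cmp, states_cmp) {
  shared <- intersect(keys_ref, keys_cmp)
  if (length(shared) == 0L) stop("no shared bipartitions")
  i <- match(shared, keys_ref)
  j <- match(shared, keys_cmp)
  a_ref <- max.col(states_ref[i, , drop = FALSE])
  a_cmp <- max.col(states_cmp[j, , drop = FALSE])
  100 * mean(a_ref == a_cmp)
}

#' Ancestral values of continuous traits from a fitted model
#'
#' For each posterior draw of a multi-response phylogenetic model, internal-node
#' trait values are drawn from their Brownian-bridge conditional normal given
#' that draw's tip-level phylogenetic effects and trait covariance matrix:
#' node effects `a_N | a_T ~ N(C_NT C_TT^-1 a_T, G (x) S)` with
#' `S = C_NN - C_NT C_TT^-1 C_TN`, plus the draw's trait intercepts.
#'
#' @param fit a `"bpmm"` fitted with per-trait intercepts (the default
#'   multi-response design) on species matching the tree tips.
#' @param tree the phylogeny used for the fit (defaults to the one stored in
#'   the fit).
#' @return list: `draws` (array internal nodes x traits x samples of node trait
#'   values), `keys` (bipartition keys, one per internal node), `traits`.
#' @export
ancestral_continuous <- function(fit, tree = fit$meta$tree) {
  stopifnot(inherits(fit, "bpmm"))
  if (fit$meta$path != "traits")
    stop("ancestral prediction requires the multi-response trait model")
  sp <- fit$meta$species
  traits <- fit$meta$traits
  k <- length(traits)
  n <- length(tree$tip.label)
  if (!setequal(sp, tree$tip.label))
    stop("fit species and tree tips differ")
  C <- phylo_covariance_full(tree)
  tipi <- seq_len(n)[match(sp, tree$tip.label)]
  nodei <- n + seq_len(tree$Nnode)
  Ctt <- C[tipi, tipi, drop = FALSE]
  Cnt <- C[nodei, tipi, drop = FALSE]
  M <- Cnt %*% solve(Ctt)
  S <- C[nodei, nodei, drop = FALSE] - M %*% t(Cnt)
  Ls <- chol_psd(S)
  A <- fit$samples$A[[1L]]            # species x traits x draws (single group)
  if (is.null(A)) stop("fit does not store phylogenetic effects")
  G <- fit$samples$G[[1L]]
  b <- fit$samples$b
  int_cols <- match(paste0("trait", traits), colnames(b))
  if (k == 1L && anyNA(int_cols))
    int_cols <- match("(Intercept)", colnames(b))
  if (anyNA(int_cols))
    stop("ancestral prediction needs per-trait intercepts in the fixed design")
  nS <- dim(A)[3L]
  nnode <- length(nodei)
  draws <- array(NA_real_, c(nnode, k, nS),
                 dimnames = list(NULL, traits, NULL))
  for (s in seq_len(nS)) {
    mu <- M %*% A[, , s]
    noise <- Ls %*% matrix(stats::rnorm(nnode * k), nnode, k) %*%
      chol_psd(G[, , s])
    draws[, , s] <- sweep(mu + noise, 2L, b[s, int_cols], "+")
  }
  list(draws = draws, keys = unname(node_keys(tree)), traits = traits)
}
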