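# shared fixtures, built in code at test time

# small ultrametric tree rescaled to unit height
unit_tree <- function(n, seed = 1) {
  tr <- sim_tree(n, seed = seed)
  tr$edge.length <- tr$edge.length / max(gravitherm:::node_depths(tr))
  tr
}

# brute-force phylogenetic covariance: per-pair MRCA depth via root paths
brute_vcv <- function(tree) {
  n <- length(tree$tip.label)
  paths <- lapply(seq_len(n), function(i) {
    nd <- i; out <- i
    repeat {
      e <- which(tree$edge[, 2L] == nd)
      if (length(e) == 0L) break
      nd <- tree$edge[e, 1L]
      out <- c(out, nd)
    }
    out
  })
  depth <- gravitherm:::node_depths(tree)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mrca <- max(intersect(paths[[i]], paths[[j]]))
    shared <- intersect(paths[[i]], paths[[j]])
    # deepest shared node = the one with max depth
    V[i, j] <- max(depth[shared])
  }
  V
}

# exhaustive-enumeration likelihood for (hidden-rate) Markov models
enum_likelihood <- function(tree, tip_states, Q, root_prior = NULL) {
  k <- nrow(Q)
  n <- length(tree$tip.label)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  obs_of <- ((seq_len(k) - 1L) %% 2L) + 1L
  P <- lapply(seq_len(nrow(tree$edge)), function(i)
    gravitherm:::ctmc_prob(Q, tree$edge.length[i]))
  internal <- (n + 1L):(n + tree$Nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  st <- tip_states[tree$tip.label]
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    lik <- root_prior[a[1L]]
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
      lik <- lik * if (ch <= n) sum(P[[i]][a[p - n], obs_of == st[ch]])
      else P[[i]][a[p - n], a[ch - n]]
    }
    tot <- tot + lik
  }
  log(tot)
}

# enumeration-based marginal observed-state probabilities at internal nodes
enum_marginals <- function(tree, tip_states, Q) {
  k <- nrow(Q)
  n <- length(tree$tip.label)
  rp <- rep(1 / k, k)
  obs_of <- ((seq_len(k) - 1L) %% 2L) + 1L
  P <- lapply(seq_len(nrow(tree$edge)), function(i)
    gravitherm:::ctmc_prob(Q, tree$edge.length[i]))
  internal <- (n + 1L):(n + tree$Nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  st <- tip_states[tree$tip.label]
  w <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    lik <- rp[a[1L]]
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
      lik <- lik * if (ch <= n) sum(P[[i]][a[p - n], obs_of == st[ch]])
      else P[[i]][a[p - n], a[ch - n]]
    }
    w[r] <- lik
  }
  m <- t(sapply(seq_along(internal), function(j)
    sapply(1:2, function(o) sum(w[obs_of[grid[, j]] == o]))))
  m / sum(w)
}
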