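test_that("rate-matrix construction enforces the hidden-rates structure", {
  Q <- hmm_rate_matrix(rbind(c(1, 2), c(5, 6)), rbind(c(0.3, 0.4)))
  expect_equal(dim(Q), c(4L, 4L))
  expect_equal(unname(rowSums(Q)), rep(0, 4))
  # no simultaneous observed-state + category jumps
  expect_equal(Q[1, 4], 0)
  expect_equal(Q[2, 3], 0)
  expect_equal(Q[1, 2], 1)   # O->V in slow category
  expect_equal(Q[3, 4], 5)   # O->V in fast category
  expect_equal(Q[1, 3], 0.3) # slow->fast
})

test_that("pruning likelihood equals exhaustive enumeration (<= 6 tips)", {
  set.seed(1)
  for (rep in 1:8) {
    ntip <- sample(3:6, 1)
    tr <- sim_tree(ntip, seed = 100 + rep)
    st <- setNames(sample(1:2, ntip, replace = TRUE), tr$tip.label)
    for (R in 1:2) {
      obs <- matrix(runif(2 * R, 0.05, 2), R, 2)
      sw <- if (R > 1) matrix(runif(2, 0.05, 1), 1, 2) else NULL
      Q <- hmm_rate_matrix(obs, sw)
      ll <- mk_likelihood(tr, st, Q)
      oracle <- enum_likelihood(tr, st, Q)
      expect_lt(abs(ll - oracle) / abs(oracle), 1e-10)
    }
  }
})

test_that("single-tip tree with zero rates returns the root prior mass", {
  one <- read_newick("(A:1);")
  Q <- matrix(0, 2, 2)
  st <- c(A = 1L)
  expect_equal(mk_likelihood(one, st, Q), log(0.5))
  expect_equal(mk_likelihood(one, st, Q, root_prior = c(1, 0)), log(1))
})

test_that("likelihood is invariant to hidden-category relabeling", {
  tr <- sim_tree(8, seed = 3)
  st <- setNames(rep(c(1L, 2L), 4), tr$tip.label)
  obs <- rbind(c(0.4, 0.2), c(3, 1))
  sw <- rbind(c(0.3, 0.5))
  Q1 <- hmm_rate_matrix(obs, sw)
  Q2 <- hmm_rate_matrix(obs[2:1, ], sw[, 2:1, drop = FALSE])
  expect_equal(mk_likelihood(tr, st, Q1), mk_likelihood(tr, st, Q2),
               tolerance = 1e-10)
})

test_that("unknown state codes and missing tips are rejected", {
  tr <- sim_tree(4, seed = 4)
  Q <- hmm_rate_matrix(rbind(c(1, 1)))
  st_bad <- setNames(c(1L, 2L, 3L, 1L), tr$tip.label)
  expect_error(mk_likelihood(tr, st_bad, Q), "unknown state")
  st_missing <- setNames(c(1L, 2L), tr$tip.label[1:2])
  expect_error(mk_likelihood(tr, st_missing, Q), "missing")
})

test_that("maximum-likelihood rates are recovered within a factor of two", {
  tr <- unit_tree(150, seed = 5)
  truth <- 1.2
  set.seed(6)
  ratios <- replicate(5, {
    d <- sim_discrete(tr, hmm_rate_matrix(rbind(c(truth, truth))))
    f <- fit_hmm(tr, d$tip_states, R = 1, n_restarts = 3)
    mean(f$rates) / truth
  })
  expect_gt(mean(ratios > 0.5 & ratios < 2), 0.7)
})

test_that("constant characters are flagged degenerate with floored rates", {
  tr <- sim_tree(20, seed = 7)
  st <- setNames(rep(1L, 20), tr$tip.label)
  f <- fit_hmm(tr, st, R = 1, n_restarts = 2, seed = 8)
  expect_true(f$degenerate)
  expect_lt(min(f$rates), 1e-6)
})

test_that("AIC arithmetic and trivial category selection", {
  f <- structure(list(loglik = -100, n_params = 2L), class = "hmm_fit")
  expect_equal(2 * f$n_params - 2 * f$loglik, 204)
  tr <- sim_tree(12, seed = 9)
  d <- sim_discrete(tr, hmm_rate_matrix(rbind(c(1, 1))), seed = 10)
  sel <- select_rate_categories(tr, d$tip_states, R_max = 1,
                                n_restarts = 2, seed = 11)
  expect_equal(sel$R, 1L)
  expect_equal(nrow(sel$table), 1L)
  expect_equal(sel$table$AIC,
               2 * sel$table$n_params - 2 * sel$table$loglik)
})

test_that("marginal reconstructions match enumeration and sum to one", {
  set.seed(12)
  tr <- sim_tree(5, seed = 13)
  st <- setNames(c(1L, 2L, 1L, 2L, 1L), tr$tip.label)
  Q <- hmm_rate_matrix(rbind(c(0.3, 0.2), c(1.5, 0.8)), rbind(c(0.3, 0.4)))
  m <- marginal_states(tr, st, Q)
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-12)
  oracle <- enum_marginals(tr, st, Q)
  expect_equal(unname(m[6:9, ]), unname(oracle), tolerance = 1e-10)

  # short branches, both tips in one state: root follows
  cherry <- read_newick("(A:0.001,B:0.001);")
  mc <- marginal_states(cherry, c(A = 2L, B = 2L),
                        hmm_rate_matrix(rbind(c(0.5, 0.5))))
  expect_gt(mc[3, 2], 0.99)
})
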