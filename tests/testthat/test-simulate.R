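test_that("sim_tree is reproducible, ultrametric and right-sized", {
  t1 <- sim_tree(2, seed = 1)
  d <- gravitherm:::node_depths(t1)
  expect_equal(d[1L], d[2L])             # cherry: equal depths

  a <- sim_tree(20, birth = 1, death = 0.3, seed = 5)
  b <- sim_tree(20, birth = 1, death = 0.3, seed = 5)
  expect_identical(write_newick(a), write_newick(b))
  expect_equal(length(a$tip.label), 20L)
  expect_true(ape::is.ultrametric(a, tol = 1e-8))
  expect_error(sim_tree(5, birth = 0.2, death = 0.5))
})

test_that("sim_discrete follows the Markov process", {
  tr <- unit_tree(20, seed = 2)
  # zero rates: everything inherits the root state
  Q0 <- matrix(0, 2, 2)
  d0 <- sim_discrete(tr, Q0, root_state = 2L, seed = 1)
  expect_true(all(d0$tip_states == 2L))
  expect_true(all(d0$node_states == 2L))

  # huge symmetric rates: stationary 50/50 at the tips
  Qbig <- hmm_rate_matrix(rbind(c(500, 500)))
  frac <- mean(replicate(60, {
    mean(sim_discrete(tr, Qbig)$tip_states == 1L)
  }))
  expect_lt(abs(frac - 0.5), 0.05)

  expect_error(sim_discrete(tr, matrix(c(-1, 0.5, 0.2, -0.5), 2)), "sum to 0")

  # single-branch distribution equals matrix-exponential transition row
  one <- read_newick("(A:0.7);")
  Q <- hmm_rate_matrix(rbind(c(0.8, 0.3)))
  P <- gravitherm:::ctmc_prob(Q, 0.7)
  sims <- replicate(4000, sim_discrete(one, Q, root_state = 1L)$tip_states[[1L]])
  p1 <- mean(sims == 1L)
  se <- sqrt(P[1, 1] * (1 - P[1, 1]) / 4000)
  expect_lt(abs(p1 - P[1, 1]), 4 * se + 1e-12)
})

test_that("correlated Brownian simulation has the advertised covariance", {
  tr <- unit_tree(10, seed = 3)
  # zero covariance: all species equal the means
  z <- sim_correlated_bm(tr, c(a = 3, b = -1), diag(0, 2), diag(0, 2),
                         seed = 1)
  expect_true(all(z$tips$a == 3) && all(z$tips$b == -1))
  expect_error(sim_correlated_bm(tr, c(1, 2, 3), diag(2), diag(2)),
               "dimension")

  # empirical tip covariance over replicates ~ G kron C + R kron I
  G <- matrix(c(1, -0.8, -0.8, 1), 2)
  R <- diag(0.1, 2)
  C <- phylo_covariance(tr)
  nrep <- 500
  X <- array(NA_real_, c(10, 2, nrep))
  set.seed(42)
  for (r in seq_len(nrep))
    X[, , r] <- as.matrix(sim_correlated_bm(tr, c(x = 0, y = 0), G, R)$tips)
  emp11 <- stats::cov(t(X[, 1, ]))            # trait 1 across species
  emp12 <- stats::cov(t(X[, 1, ]), t(X[, 2, ]))
  th11 <- G[1, 1] * C + R[1, 1] * diag(10)
  th12 <- G[1, 2] * C + R[1, 2] * diag(10)
  mc_se <- sqrt(2 / nrep)  # rough MC scale for unit-variance entries
  expect_lt(max(abs(emp11 - th11)), 3 * mc_se * max(diag(th11)) + 0.05)
  expect_lt(max(abs(emp12 - th12)), 3 * mc_se * max(abs(th12)) + 0.05)

  # realized heritability ~ 0.9 for G = 0.9, R = 0.1 (GLS variance
  # decomposition: phylogenetic variance from the eigen-whitened deviations)
  e <- eigen(C, symmetric = TRUE)
  h2 <- replicate(200, {
    s <- sim_correlated_bm(tr, c(x = 0), matrix(0.9), matrix(0.1))
    phy <- s$truth$node_values[seq_len(10), 1] - 0
    res <- s$tips$x - s$truth$node_values[seq_len(10), 1]
    Ghat <- mean(crossprod(e$vectors, phy)^2 / e$values)
    Rhat <- mean(res^2)
    Ghat / (Ghat + Rhat)
  })
  expect_lt(abs(mean(h2) - 0.9), 0.05)
})

test_that("hatching simulator peaks at the optimum", {
  expect_error(sim_hatching(c(a = 28), curvature = 0.1), "curvature")
  # at the vertex the expected proportion is max_success
  r <- sim_hatching(c(sp1 = 28), temps = 28, eggs_per_temp = 4000,
                    max_success = 0.8, seed = 1)
  expect_lt(abs(r$n_hatched / r$n_eggs - 0.8), 0.03)
  # extreme curvature: nothing hatches off-vertex
  r2 <- sim_hatching(c(sp1 = 28), curvature = -50,
                     temps = c(20, 28, 36), eggs_per_temp = 200, seed = 2)
  expect_equal(r2$n_hatched[c(1, 3)], c(0L, 0L))
  expect_gt(r2$n_hatched[2L], 150L)

  # ML vertex of a per-replicate quadratic logistic fit is unbiased
  set.seed(3)
  verts <- replicate(150, {
    d <- sim_hatching(c(sp = 28), temps = c(20, 24, 28, 32, 36),
                      eggs_per_temp = 50)
    f <- suppressWarnings(
      glm(cbind(n_hatched, n_eggs - n_hatched) ~ temperature +
            I(temperature^2), binomial, d))
    -coef(f)[2L] / (2 * coef(f)[3L])
  })
  expect_lt(abs(mean(verts) - 28), 3 * sd(verts) / sqrt(length(verts)) + 0.05)
})

test_that("gravid-study simulator produces the target effect size", {
  r <- sim_gravid_study(31, shift = 0, sd = 1, n_g = 4000, n_ng = 4000,
                        seed = 1)
  g0 <- hedges_g(r)$g
  expect_lt(abs(g0), 0.1)

  r2 <- sim_gravid_study(31, shift = -2, sd = 1, n_g = 1000, n_ng = 1000,
                         seed = 2)
  expect_lt(abs(hedges_g(r2)$g - (-2)), 0.15)

  # small-sample replicate mean of g ~ shift/sd once bias-corrected
  set.seed(4)
  gs <- replicate(2000, {
    hedges_g(sim_gravid_study(31, shift = -1, sd = 2, n_g = 15,
                              n_ng = 15))$g
  })
  expect_lt(abs(mean(gs) - (-0.5)), 3 * sd(gs) / sqrt(length(gs)))
})

test_that("missingness injection masks at the stated rates", {
  tab <- data.frame(a = rnorm(163), b = rnorm(163))
  same <- inject_missing(tab, c(a = 0), seed = 1)
  expect_identical(same$table, tab)
  all_gone <- inject_missing(tab, c(b = 1), seed = 1)
  expect_true(all(is.na(all_gone$table$b)))
  half <- inject_missing(tab, c(a = 0.5), seed = 2)
  n_missing <- sum(is.na(half$table$a))
  expect_true(n_missing >= qbinom(0.005, 163, 0.5) &&
                n_missing <= qbinom(0.995, 163, 0.5))
})

test_that("simulators are bit-reproducible under a fixed seed", {
  tr <- unit_tree(8, seed = 1)
  Q <- hmm_rate_matrix(rbind(c(1, 0.5)))
  expect_identical(sim_discrete(tr, Q, seed = 7),
                   sim_discrete(tr, Q, seed = 7))
  G <- diag(2); R <- diag(0.1, 2)
  expect_identical(sim_correlated_bm(tr, c(x = 0, y = 1), G, R, seed = 8),
                   sim_correlated_bm(tr, c(x = 0, y = 1), G, R, seed = 8))
  expect_identical(sim_hatching(c(a = 27), seed = 9),
                   sim_hatching(c(a = 27), seed = 9))
  expect_identical(sim_scenario(n_tips = 40, n_trees = 3, n_pbt = 30,
                                n_topt = 12, n_g = 12, seed = 5)$traits,
                   sim_scenario(n_tips = 40, n_trees = 3, n_pbt = 30,
                                n_topt = 12, n_g = 12, seed = 5)$traits)
})
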