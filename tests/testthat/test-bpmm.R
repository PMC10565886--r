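test_that("one Gibbs sweep's fixed-effect conditional mean is the GLS solution", {
  set.seed(1)
  n <- 25; k <- 2
  X1 <- cbind(1, rnorm(n))                 # per-trait designs
  X <- rbind(cbind(X1, 0 * X1), cbind(0 * X1, X1))  # trait-major block design
  Y <- matrix(rnorm(n * k), n, k)
  R <- matrix(c(1.3, 0.4, 0.4, 0.8), 2)
  cond <- gravitherm:::fixef_conditional(Xg = list(X), Yg = list(Y),
                                         Rinvg = list(solve(R)))
  # independent closed form: naive kronecker GLS
  Sig_inv <- kronecker(solve(R), diag(n))
  beta_gls <- solve(t(X) %*% Sig_inv %*% X, t(X) %*% Sig_inv %*% as.vector(Y))
  expect_equal(cond$mean, as.vector(beta_gls), tolerance = 1e-6)
})

test_that("without random effects the posterior mean matches OLS", {
  set.seed(2)
  tr <- unit_tree(40, seed = 3)
  d <- data.frame(species = tr$tip.label, x = rnorm(40))
  d$y <- 1.5 + 2 * d$x + rnorm(40, 0, 0.7)
  fit <- bpmm(y ~ x, data = d, tree = tr, phylo = FALSE,
              nitt = 4000, burnin = 500, thin = 2, seed = 4)
  ols <- coef(lm(y ~ x, d))
  post <- coef(fit)
  mcse <- apply(fit$samples$b, 2, sd) / sqrt(nrow(fit$samples$b) / 10)
  expect_lt(abs(post[1] - ols[1]), 3 * mcse[1] + 0.02)
  expect_lt(abs(post[2] - ols[2]), 3 * mcse[2] + 0.02)
})

test_that("a constant response concentrates the intercept on the constant", {
  tr <- unit_tree(25, seed = 5)
  d <- data.frame(species = tr$tip.label, y = 7)
  fit <- bpmm(y ~ 1, data = d, tree = tr, nitt = 1500, burnin = 500,
              thin = 2, seed = 6)
  expect_lt(abs(mean(fit$samples$b) - 7), 0.05)
})

test_that("heritability and correlation arithmetic on chains is exact", {
  k <- 2; nS <- 200
  fake <- structure(list(
    samples = list(
      G = list(all = array(rep(c(3, 0.5, 0.5, 2), nS), c(k, k, nS),
                           dimnames = list(c("a", "b"), c("a", "b"), NULL))),
      R = list(all = array(rep(diag(1, k), nS), c(k, k, nS)))),
    meta = list(path = "traits", traits = c("a", "b"), groups = "all")),
    class = "bpmm")
  h <- phylo_heritability(fake, "a")
  expect_true(all(h$draws == 0.75))
  r <- phylo_correlation(fake, c("a", "b"))
  expect_equal(unique(r$draws), 0.5 / sqrt(6))
  rres <- phylo_correlation(fake, c("a", "b"), "residual")
  expect_true(all(rres$draws == 0))

  fake$samples$G$all[] <- 0
  fake$samples$G$all[1, 1, ] <- 0  # V_phylo = 0 => H2 = 0
  expect_true(all(phylo_heritability(fake, "a")$draws == 0))

  perfect <- array(rep(c(1, 1, 1, 1), nS), c(k, k, nS),
                   dimnames = list(c("a", "b"), c("a", "b"), NULL))
  fake$samples$G$all <- perfect
  expect_true(all(phylo_correlation(fake, c("a", "b"))$draws == 1))
})

test_that("posterior summaries implement the stated conventions", {
  set.seed(7)
  x <- rnorm(10000, 1, 1)
  s <- posterior_summary(x)
  expect_equal(s$pmcmc, pnorm(-1), tolerance = 0.02)    # N(1,1) tail
  expect_lt(abs(s$mode - 1), 0.1)
  expect_lt(abs(s$ci[1] - (1 - 1.96)), 0.1)
  expect_lt(abs(s$ci[2] - (1 + 1.96)), 0.1)

  expect_equal(posterior_summary(abs(rnorm(500)) + 0.1)$pmcmc, 0)
  sym <- c(rnorm(5000), -rnorm(5000))
  expect_lt(abs(posterior_summary(sym)$pmcmc - 0.5), 0.02)
  expect_equal(pmcmc(c(-1, rep(1, 9))), 0.1)
  expect_equal(pmcmc(c(-1, rep(1, 9)), doubled = TRUE), 0.2)
})

test_that("convergence diagnostics behave on known chains", {
  set.seed(8)
  c1 <- rnorm(2000); c2 <- rnorm(2000)
  expect_lt(gelman_rubin(list(c1, c2)), 1.05)
  expect_gt(gelman_rubin(list(rnorm(500), rnorm(500) + 50)), 10)
  expect_equal(gelman_rubin(list(c1, c1)),
               sqrt((2000 - 1) / 2000), tolerance = 1e-12)
  expect_error(gelman_rubin(list(c1)), "two chains")

  expect_lt(abs(chain_autocorrelation(rnorm(2000), 1)), 0.1)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 4000))
  expect_lt(abs(chain_autocorrelation(ar, 1) - 0.9), 0.05)
  expect_warning(out <- chain_autocorrelation(rep(1, 50), 1), "constant")
  expect_true(is.na(out))
})

test_that("inverse-Wishart prior machinery has the right moments", {
  set.seed(9)
  # k = 1: IW(scale s, df v) mean = s / (v - 2)
  draws <- replicate(4000, gravitherm:::riwish(6, matrix(2)))
  expect_lt(abs(mean(draws) - 2 / 4), 3 * sd(draws) / sqrt(4000))
  # k = 2
  S <- matrix(c(3, 1, 1, 2), 2)
  d2 <- replicate(4000, gravitherm:::riwish(8, S))
  expect_lt(max(abs(apply(d2, c(1, 2), mean) - S / (8 - 2 - 1))), 0.1)
})

test_that("missing responses are recovered through the phylogenetic correlation", {
  set.seed(10)
  tr <- unit_tree(60, seed = 11)
  G <- matrix(c(1, 0.9, 0.9, 1), 2)
  sim <- sim_correlated_bm(tr, c(x = 0, y = 0), G, diag(0.05, 2), seed = 12)
  d <- cbind(species = rownames(sim$tips), sim$tips)
  truth_y <- d$y
  mask <- sample(60, 18)
  d$y[mask] <- NA
  fit <- bpmm(cbind(x, y) ~ 1, data = d, tree = tr,
              nitt = 2500, burnin = 500, thin = 4, seed = 13)
  obs <- !is.na(as.matrix(d[, c("x", "y")]))
  pred <- colMeans(fit$samples$Ymis)
  # Ymis columns follow column-major order of the trait matrix
  y_cols <- which(!obs) > 60
  expect_gt(cor(pred[y_cols], truth_y[sort(mask)]), 0.8)
})

test_that("estimates are insensitive to the prior specification", {
  set.seed(14)
  tr <- unit_tree(50, seed = 15)
  sim <- sim_correlated_bm(tr, c(x = 0), matrix(0.8), matrix(0.2), seed = 16)
  d <- cbind(species = rownames(sim$tips), sim$tips)
  priors <- list(
    default = NULL,
    nu2 = list(G = prior_block(1, 2), R = prior_block(1, 2)),
    expanded = list(G = prior_block(1, 1, alpha_mu = 0, alpha_V = 1000),
                    R = prior_block(1, 0.002)))
  h2 <- lapply(priors, function(p) {
    f <- bpmm(x ~ 1, data = d, tree = tr, prior = p,
              nitt = 3000, burnin = 1000, thin = 4, seed = 17)
    phylo_heritability(f, "x")
  })
  cis <- sapply(h2, function(h) h$summary$ci)
  # every pair of credible intervals overlaps
  expect_lt(max(cis[1, ]), min(cis[2, ]))
})

test_that("binomial intercept model recovers the success probability", {
  tr <- unit_tree(20, seed = 18)
  set.seed(19)
  d <- data.frame(species = tr$tip.label, succ = rbinom(20, 50, 0.75))
  d$fail <- 50 - d$succ
  fit <- bpmm(cbind(succ, fail) ~ 1, data = d, tree = tr,
              family = "binomial", nitt = 3000, burnin = 1000, thin = 4,
              seed = 20)
  p_hat <- mean(plogis(fit$samples$b[, 1]))
  expect_lt(abs(p_hat - 0.75), 0.08)
})

test_that("chained runs cycle datasets, warm start, and match one long chain", {
  set.seed(21)
  tr <- unit_tree(35, seed = 22)
  sim <- sim_correlated_bm(tr, c(x = 0, y = 0),
                           matrix(c(0.8, -0.5, -0.5, 0.8), 2),
                           diag(0.2, 2), seed = 23)
  d <- cbind(species = rownames(sim$tips), sim$tips)

  ch <- bpmm_chained(list(d, d), tr, cbind(x, y) ~ 1,
                     events = 4, iters_per_event = 25, burn_events = 0,
                     seed = 24)
  expect_equal(ch$meta$event_dataset, c(1L, 2L, 1L, 2L))
  expect_equal(nrow(ch$samples$b), 4L)
  # warm start: sample e equals the recorded final state of event e
  expect_equal(unname(ch$samples$b[2, ]),
               unname(ch$meta$event_state[[2]]$b))

  long <- bpmm(cbind(x, y) ~ 1, data = d, tree = tr,
               nitt = 4500, burnin = 1500, thin = 10, seed = 25)
  chained <- bpmm_chained(list(d), tr, cbind(x, y) ~ 1,
                          events = 300, iters_per_event = 10,
                          burn_events = 100, seed = 26)
  r1 <- phylo_correlation(long, c("x", "y"))$draws
  r2 <- phylo_correlation(chained, c("x", "y"))$draws
  expect_lt(abs(mean(r1) - mean(r2)),
            3 * sqrt(var(r1) / 30 + var(r2) / 30) + 0.05)
  h1 <- phylo_heritability(long, "x")$draws
  h2 <- phylo_heritability(chained, "x")$draws
  expect_lt(abs(mean(h1) - mean(h2)),
            3 * sqrt(var(h1) / 30 + var(h2) / 30) + 0.05)
})
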