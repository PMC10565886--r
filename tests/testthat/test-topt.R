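make_topt_fit <- function() {
  tr <- unit_tree(12, seed = 1)
  topt <- setNames(rnorm(12, 28, 1), tr$tip.label)
  recs <- sim_hatching(topt, curvature = -0.15, temps = seq(20, 36, 2),
                       eggs_per_temp = 25, seed = 2)
  fit <- fit_hatching_model(recs, tr, nitt = 2200, burnin = 600, thin = 4,
                            seed = 3)
  list(fit = fit, truth = topt, recs = recs)
}

test_that("inclusion rule rejects species with fewer than 3 temperatures", {
  tr <- unit_tree(3, seed = 4)
  recs <- rbind(
    sim_hatching(setNames(27, tr$tip.label[1]), temps = c(24, 26, 28),
                 seed = 5),
    sim_hatching(setNames(27, tr$tip.label[2]), temps = c(24, 28), seed = 6),
    sim_hatching(setNames(27, tr$tip.label[3]), temps = c(24, 26, 28),
                 seed = 7))
  expect_error(fit_hatching_model(recs, tr), tr$tip.label[2])
})

test_that("the vertex formula and concavity rule are applied per draw", {
  # hand-built chain: beta_tot = 2.8, gamma_tot = -0.05 on the raw scale
  nS <- 200
  fake <- structure(list(
    samples = list(
      b = cbind(`(Intercept)` = rep(1, nS), temp_s = rep(2.8, nS),
                `I(temp_s^2)` = rep(-0.05, nS)),
      A = list(all = array(0, c(1, 3, nS), dimnames = list("sp", NULL, NULL)))),
    meta = list(path = "general", species = "sp",
                temp_scaling = c(center = 0, scale = 1))), class = "bpmm")
  tp <- derive_topt(fake, "sp")
  expect_equal(tp$estimate, 28)
  expect_equal(tp$vi, 0)
  expect_true(tp$concave)

  # 20% convex draws: estimate withheld
  fake$samples$b[1:40, "I(temp_s^2)"] <- 0.02
  tp2 <- derive_topt(fake, "sp")
  expect_false(tp2$concave)
  expect_true(is.na(tp2$estimate))
  expect_equal(tp2$prop_concave, 0.8)
})

test_that("T_opt is invariant to the intercept", {
  m <- make_topt_fit()
  t1 <- derive_topt(m$fit, m$fit$meta$species[1])
  shifted <- m$fit
  shifted$samples$b[, "(Intercept)"] <- shifted$samples$b[, "(Intercept)"] + 5
  t2 <- derive_topt(shifted, m$fit$meta$species[1])
  expect_equal(t1$draws, t2$draws)
})

test_that("species optima are recovered with phylogenetic pooling", {
  m <- make_topt_fit()
  tab <- topt_table(m$fit)
  expect_true(all(tab$concave))
  expect_gt(cor(tab$topt, m$truth[tab$species]), 0.8)
  expect_lt(mean(abs(tab$topt - m$truth[tab$species])), 0.8)
})

test_that("predicted success evaluates the latent curve correctly", {
  nS <- 150
  fake <- structure(list(
    samples = list(
      b = cbind(`(Intercept)` = rep(2.2, nS), temp_s = rep(0, nS),
                `I(temp_s^2)` = rep(-0.15, nS)),
      A = list(all = array(0, c(1, 3, nS), dimnames = list("sp", NULL, NULL)))),
    meta = list(path = "general", species = "sp",
                temp_scaling = c(center = 28, scale = 1))), class = "bpmm")
  # at the vertex: plogis(2.2); hand-computed off-vertex value at T = 34
  expect_equal(unique(predicted_success_at(fake, "sp", 28)), plogis(2.2))
  expect_equal(unique(predicted_success_at(fake, "sp", 34)),
               plogis(2.2 - 0.15 * 36))
  # parabola symmetry on the latent scale
  expect_equal(predicted_success_at(fake, "sp", 25),
               predicted_success_at(fake, "sp", 31))
})

test_that("all-hatched data leave the quadratic term unidentified", {
  tr <- unit_tree(6, seed = 8)
  recs <- expand.grid(species = tr$tip.label,
                      temperature = seq(22, 34, 3),
                      stringsAsFactors = FALSE)
  recs$n_eggs <- 30L
  recs$n_hatched <- 30L
  fit <- fit_hatching_model(recs, tr, nitt = 1600, burnin = 400, thin = 4,
                            seed = 9)
  quad <- fit$samples$b[, "I(temp_s^2)"]
  expect_gt(pmcmc(quad), 0.05)    # posterior overlaps zero
})
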