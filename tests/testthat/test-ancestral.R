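test_that("transition categories follow the four definitions and majority vote", {
  # hand-built tree: root with an O cherry and a V cherry
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  st <- c(A = 1L, B = 1L, C = 2L, D = 2L)
  hard <- function(states) {
    m <- matrix(0, 7, 2)
    m[cbind(1:7, states)] <- 1
    m
  }
  # node states: root O, left node O, right node V
  marg <- hard(c(st, 1L, 1L, 2L))
  calls <- classify_transitions(structure(list(tr), class = "multiPhylo"),
                                list(marg))
  expect_setequal(calls$category, c("O->V", "O->O", "V->V"))
  root_key <- paste(sort(c("A", "B", "C", "D")), collapse = "|")
  expect_equal(calls$category[calls$key == root_key], "O->V")

  # majority over trees: 2 trees say O->O at the left cherry, 1 says O->V
  marg2 <- hard(c(st, 1L, 1L, 2L))
  marg3 <- hard(c(st, 1L, 2L, 2L))  # left cherry node called V
  calls2 <- classify_transitions(
    structure(list(tr, tr, tr), class = "multiPhylo"),
    list(marg2, marg2, marg3))
  left_key <- "A|B"
  expect_equal(calls2$category[calls2$key == left_key], "O->O")
  expect_equal(unname(as.matrix(
    calls2[calls2$key == left_key, c("O->O", "V->V", "O->V", "V->O")])[1, ]),
    c(2L, 0L, 0L, 1L))
})

test_that("ties break by the fixed category priority and are reported", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  st <- c(A = 1L, B = 1L, C = 2L, D = 2L)
  hard <- function(states) {
    m <- matrix(0, 7, 2); m[cbind(1:7, states)] <- 1; m
  }
  m_oo <- hard(c(st, 1L, 1L, 2L))   # left node O (O->O)
  m_vo <- hard(c(st, 1L, 2L, 2L))   # left node V with O children (V->O)
  expect_message(
    calls <- classify_transitions(
      structure(list(tr, tr), class = "multiPhylo"), list(m_oo, m_vo)),
    "tied")
  expect_equal(calls$category[calls$key == "A|B"], "O->O")
  expect_true(calls$tie[calls$key == "A|B"])
})

test_that("mismatch calls implement the HPD-interval rule", {
  set.seed(1)
  base <- rnorm(500, 0, 0.1)
  lower <- mismatch_call(base + 2.6, base - 0.1 + rnorm(500, 0, 0.1))
  expect_equal(lower$label, "T_opt-lower")
  higher <- mismatch_call(base - 2.6, base + rnorm(500, 0, 0.1))
  expect_equal(higher$label, "T_opt-higher")
  aligned <- mismatch_call(base, base + rnorm(500, 0, 0.3))
  expect_equal(aligned$label, "aligned")
  expect_error(mismatch_call(rnorm(50), rnorm(50)), ">= 100")
})

test_that("the transition-mismatch contingency test is Pearson's chi-squared", {
  calls <- data.frame(
    category = rep(c("O->O", "O->V"), each = 25),
    label = c(rep("aligned", 20), rep("T_opt-lower", 5),
              rep("aligned", 5), rep("T_opt-lower", 20)))
  out <- transition_mismatch_test(calls)
  expect_equal(out$statistic, 18)
  expect_equal(out$df, 1L)
  expect_equal(out$p_value, pchisq(18, 1, lower.tail = FALSE))

  flat <- data.frame(category = rep(c("O->O", "O->V"), each = 20),
                     label = rep(c("aligned", "T_opt-lower"), 20))
  expect_equal(transition_mismatch_test(flat)$statistic, 0)

  empty <- data.frame(category = rep("O->O", 10),
                      label = rep(c("aligned", "T_opt-lower"), 5))
  held <- transition_mismatch_test(empty)
  expect_true(is.na(held$statistic))
  expect_match(held$status, "withheld")

  # V->V and V->O rows are excluded from the table
  mixed <- rbind(calls, data.frame(category = "V->V", label = "aligned"))
  expect_equal(sum(transition_mismatch_test(mixed)$table), 50)
})

test_that("state agreement counts shared bipartitions", {
  keys <- c("A|B", "C|D", "A|B|C|D")
  s1 <- matrix(c(0.9, 0.1, 0.2, 0.8, 0.6, 0.4), 3, 2, byrow = TRUE)
  expect_equal(state_agreement(keys, s1, keys, s1), 100)
  s2 <- 1 - s1
  expect_equal(state_agreement(keys, s1, keys, s2), 0)
  expect_equal(state_agreement(keys, s1, keys[1:2], s2[1:2, ]), 0)
  expect_error(state_agreement(keys, s1, c("X|Y"), s1[1, , drop = FALSE]),
               "no shared")
})

test_that("subsampled-tip reconstructions still mostly agree with full data", {
  tr <- unit_tree(80, seed = 2)
  Q <- hmm_rate_matrix(rbind(c(0.8, 0.4)))
  d <- sim_discrete(tr, Q, seed = 3)
  full_fit <- fit_hmm(tr, d$tip_states, R = 1, n_restarts = 2, seed = 4)
  full_m <- marginal_states(tr, d$tip_states, full_fit)
  keep <- sample(tr$tip.label, 56)     # drop 30% of tips
  sub_tree <- prune_to_taxa(tr, keep)
  sub_fit <- fit_hmm(sub_tree, d$tip_states[keep], R = 1,
                     n_restarts = 2, seed = 5)
  sub_m <- marginal_states(sub_tree, d$tip_states[keep], sub_fit)
  n_full <- length(tr$tip.label)
  agree <- state_agreement(
    node_keys(tr), full_m[(n_full + 1):(n_full + tr$Nnode), , drop = FALSE],
    node_keys(sub_tree),
    sub_m[(length(keep) + 1):(length(keep) + sub_tree$Nnode), , drop = FALSE])
  expect_gt(agree, 50)
})

test_that("ancestral continuous prediction matches closed forms", {
  # star tree: root conditional mean is the equally weighted tip-effect mean
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  d <- data.frame(species = c("A", "B", "C", "D"),
                  x = c(2, 1, -1, 0.5), y = c(0.3, 1, 2, -2))
  fit <- bpmm(cbind(x, y) ~ 1, data = d, tree = star,
              nitt = 2200, burnin = 200, thin = 4, seed = 6)
  anc <- ancestral_continuous(fit)
  expect_equal(dim(anc$draws)[1], 1L)     # single internal node
  A <- fit$samples$A[[1]]
  b <- fit$samples$b
  # per draw, conditional mean of the root effect given tip effects on a star
  # tree with unit depths is 0 (C_nt = 0 at the root): mean = intercept
  root_draws <- anc$draws[1, "x", ]
  expect_lt(abs(mean(root_draws) - mean(b[, "traitx"])), 0.2)

  # zero-length branch to a tip: node posterior tracks that tip's effect
  tr2 <- read_newick("((A:0.000001,B:1):1,C:2);")
  d2 <- data.frame(species = c("A", "B", "C"), x = c(3, -1, 0))
  fit2 <- bpmm(x ~ 1, data = d2, tree = tr2,
               nitt = 2200, burnin = 200, thin = 4, seed = 7)
  anc2 <- ancestral_continuous(fit2)
  inner <- which(anc2$keys == "A|B")
  A2 <- fit2$samples$A[[1]]
  i_a <- match("A", fit2$meta$species)
  node_eff <- anc2$draws[inner, "x", ] - fit2$samples$b[, 1]
  expect_gt(cor(node_eff, A2[i_a, 1, ]), 0.95)
})

test_that("ancestral node values are recovered on simulated data", {
  tr <- unit_tree(100, seed = 8)
  G <- matrix(c(0.9, 0.5, 0.5, 0.9), 2)
  sim <- sim_correlated_bm(tr, c(x = 30, y = 27), G, diag(0.1, 2), seed = 9)
  d <- cbind(species = rownames(sim$tips), sim$tips)
  fit <- bpmm(cbind(x, y) ~ 1, data = d, tree = tr,
              nitt = 2600, burnin = 600, thin = 4, seed = 10)
  anc <- ancestral_continuous(fit)
  est <- apply(anc$draws[, "x", ], 1, mean)
  truth <- sim$truth$node_values[101:199, "x"]
  expect_gt(cor(est, truth), 0.7)
})
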