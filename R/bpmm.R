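#' Prior for a (co)variance block
#'
#' Inverse-Wishart prior in the parameterisation common to animal-model MCMC
#' software: a block with scale `V` and shape `nu` contributes `V * nu` to the
#' inverse-Wishart scale matrix and `nu` to its degrees of freedom. The default
#' for a k-trait block is `V = diag(k)`, `nu = k - 1 + 0.002`, a weakly
#' informative choice. Supplying `alpha_mu`/`alpha_V` requests parameter
#' expansion (a working scale parameter per trait with a Gaussian prior), which
#' pulls variance draws away from zero less strongly.
#'
#' @param V scale matrix (or scalar).
#' @param nu shape (degrees of freedom); must exceed `dim - 1` for a proper
#'   posterior.
#' @param alpha_mu,alpha_V optional parameter-expansion mean vector and prior
#'   (co)variance of the working parameters.
#' @return list of class `"bpmm_prior_block"`.
#' @export
prior_block <- function(V, nu, alpha_mu = NULL, alpha_V = NULL) {
  V <- as.matrix(V)
  stopifnot(nrow(V) == ncol(V), nu > 0)
  structure(list(V = V, nu = nu, alpha_mu = alpha_mu, alpha_V = alpha_V),
            class = "bpmm_prior_block")
}

default_prior <- function(k) prior_block(diag(k), k - 1 + 0.002)

# inverse-Wishart draw, scale S (not inverted), df nu
riwish <- function(nu, S) {
  k <- nrow(S)
  W <- stats::rWishart(1L, nu, solve(S))[, , 1L]
  solve((W + t(W)) / 2)
}

# conditional posterior mean (and precision chol) of fixed effects given
# everything else: GLS with residual covariance R (x) I within each group.
# Xg, Yg: per-group lists; Y* already has random effects and mev removed.
# Rows of Xg are trait-major (species within trait).
fixef_conditional <- function(Xg, Yg, Rinvg, ridge = 1e-8) {
  p <- ncol(Xg[[1L]])
  P <- diag(ridge, p)
  rhs <- numeric(p)
  for (g in seq_along(Xg)) {
    X <- Xg[[g]]; Y <- Yg[[g]]; Rinv <- Rinvg[[g]]
    n <- nrow(Y); k <- ncol(Y)
    W <- Y %*% Rinv                       # n x k
    for (t in seq_len(k)) {
      rows_t <- (t - 1L) * n + seq_len(n)
      rhs <- rhs + crossprod(X[rows_t, , drop = FALSE], W[, t])
      for (u in seq_len(k)) {
        rows_u <- (u - 1L) * n + seq_len(n)
        P <- P + Rinv[t, u] *
          crossprod(X[rows_t, , drop = FALSE], X[rows_u, , drop = FALSE])
      }
    }
  }
  P <- (P + t(P)) / 2
  cp <- chol(P)
  mean <- backsolve(cp, forwardsolve(t(cp), rhs))
  list(mean = as.vector(mean), chol_prec = cp)
}

draw_mvn_from_cond <- function(cond) {
  cond$mean + backsolve(cond$chol_prec,
                        stats::rnorm(length(cond$mean)))
}

#' Fit a Bayesian phylogenetic mixed model by MCMC
#'
#' Single- or multi-response mixed model whose species random effects covary
#' according to shared ancestry under Brownian motion. Gaussian responses are
#' handled by fully conjugate Gibbs updates (fixed effects, phylogenetic
#' effects, inverse-Wishart covariance blocks, conditional-normal augmentation
#' of missing responses); binomial responses use a logit link with a latent
#' Gaussian residual updated by Metropolis-Hastings.
#'
#' Two designs are supported:
#' \itemize{
#' \item multi-response trait model (`cbind(t1, t2, ...) ~ ...`): one row per
#'   species, unstructured phylogenetic (`G`) and residual (`R`) covariance
#'   across traits, optionally split by a species-level `groups` factor
#'   (block-diagonal covariance, separate matrices per group), per-datum
#'   measurement-error variances (`mev`), missing responses allowed.
#' \item general model: a single response with repeated rows per species,
#'   phylogenetic random intercepts and optional random `slopes` with an
#'   unstructured covariance across terms, an optional non-phylogenetic
#'   species intercept (`species_effect`), and Gaussian or binomial family.
#'   Binomial rows give successes/failures via `cbind(succ, fail)` on the LHS.
#' }
#'
#' The phylogenetic covariance matrix is scaled to unit mean diagonal, so
#' variance components are on the trait scale and phylogenetic heritability is
#' `G/(G + R)` directly.
#'
#' In the fixed-effect formula of a multi-response model the reserved factor
#' `trait` indexes responses; the default design `~ 0 + trait` fits one
#' intercept per response.
#'
#' @param formula model formula; LHS `cbind(...)` for multiple responses (or
#'   binomial successes/failures), RHS the fixed effects.
#' @param data data frame with a species column and model variables.
#' @param tree `"phylo"` covering all data species.
#' @param family `"gaussian"` or `"binomial"`.
#' @param species name of the species column (default `"species"`).
#' @param slopes RHS formula of covariates getting phylogenetic random slopes
#'   (general model only), e.g. `~ temp + I(temp^2)`.
#' @param species_effect add an iid species intercept (general model).
#' @param groups name of a species-level factor splitting the G and R blocks.
#' @param mev name of a column of known sampling variances added per datum.
#' @param prior list with elements `G` and `R` (see [prior_block()]); defaults
#'   are weakly informative.
#' @param nitt,burnin,thin MCMC iterations, burn-in and thinning.
#' @param start optional state from a previous fit (`fit$final_state`) to warm
#'   start from.
#' @param seed integer seed.
#' @param phylo set `FALSE` to drop the phylogenetic block (fixed effects +
#'   residual only), mainly for calibration checks.
#' @param estimate_binom_resid estimate the latent residual variance of a
#'   binomial model instead of fixing it at 1.
#' @param verbose print progress.
#' @return object of class `"bpmm"`.
#' @export
bpmm <- function(formula, data, tree, family = "gaussian",
                 species = "species", slopes = NULL, species_effect = FALSE,
                 groups = NULL, mev = NULL, prior = NULL,
                 nitt = 13000L, burnin = 3000L, thin = 10L,
                 start = NULL, seed = NULL, phylo = TRUE,
                 estimate_binom_resid = FALSE, verbose = FALSE) {
  stopifnot(nitt > burnin, thin >= 1L, burnin >= 0L)
  if (!is.null(seed)) set.seed(seed)
  lhs <- formula[[2L]]
  multi <- is.call(lhs) && identical(as.character(lhs[[1L]]), "cbind")
  resp <- if (multi) vapply(as.list(lhs)[-1L], deparse, character(1L))
  else deparse(lhs)
  if (!species %in% names(data)) stop("no species column '", species, "'")
  sp_all <- as.character(data[[species]])
  unknown <- setdiff(sp_all, tree$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unique(unknown), collapse = ", "))
  if (family == "binomial" && length(resp) != 2L)
    stop("binomial models need cbind(successes, failures) on the LHS")

  trait_model <- family == "gaussian" && is.null(slopes) &&
    !species_effect && anyDuplicated(sp_all) == 0L
  if (trait_model)
    fit <- bpmm_traits(formula,
                       data = data, tree = tree, species = species,
                       groups = groups, mev = mev, prior = prior,
                       nitt = nitt, burnin = burnin, thin = thin,
                       start = start, phylo = phylo, verbose = verbose)
  else
    fit <- bpmm_general(formula, data = data, tree = tree, family = family,
                        species = species, slopes = slopes,
                        species_effect = species_effect, mev = mev,
                        prior = prior, nitt = nitt, burnin = burnin,
                        thin = thin, start = start, phylo = phylo,
                        estimate_binom_resid = estimate_binom_resid,
                        verbose = verbose)
  fit$meta$call <- match.call()
  fit$meta$seed <- seed
  fit
}

# ---------------------------------------------------------------------------
# fast path: multi-response Gaussian trait model, one row per species
# ---------------------------------------------------------------------------
bpmm_traits <- function(formula, data, tree, species, groups, mev,
                        prior, nitt, burnin, thin, start, phylo, verbose) {
  lhs <- formula[[2L]]
  multi <- is.call(lhs) && identical(as.character(lhs[[1L]]), "cbind")
  resp <- if (multi) vapply(as.list(lhs)[-1L], deparse, character(1L))
  else deparse(lhs)
  k <- length(resp)
  sp <- as.character(data[[species]])
  n <- length(sp)
  Y <- as.matrix(data[, resp, drop = FALSE])
  storage.mode(Y) <- "double"
  obs <- !is.na(Y)
  if (any(colSums(obs) == 0L)) stop("a response has no observed values")

  # measurement-error variances: zero where absent or response missing
  Vme <- matrix(0, n, k)
  if (!is.null(mev)) {
    mevc <- if (length(mev) == 1L && is.character(mev))
      stats::setNames(rep(mev, k), resp) else mev
    for (t in seq_len(k)) {
      cn <- mevc[[resp[t]]] %||% mevc[[t]]
      if (!is.null(cn) && !is.na(cn) && cn %in% names(data)) {
        v <- data[[cn]]
        v[is.na(v)] <- 0
        Vme[, t] <- v
      }
    }
    Vme[!obs] <- 0
  }

  grp <- if (is.null(groups)) factor(rep("all", n))
  else factor(as.character(data[[groups]]))
  glev <- levels(grp)
  gidx <- lapply(glev, function(g) which(grp == g))

  # long (trait-major) fixed design
  long <- data[rep(seq_len(n), k), , drop = FALSE]
  long$trait <- factor(rep(resp, each = n), levels = resp)
  rhs <- formula[-2L]
  if (multi && identical(deparse(rhs[[2L]]), "1")) rhs <- ~ 0 + trait
  X <- stats::model.matrix(rhs, long)
  p <- ncol(X)

  pg <- prior$G %||% default_prior(k)
  pr <- prior$R %||% default_prior(k)
  px <- !is.null(pg$alpha_mu)

  # per-group tree covariance (unit mean diagonal) and its eigensystem
  Cfull <- phylo_covariance(tree, tree$tip.label)
  Cfull <- Cfull / mean(diag(Cfull))
  eig <- lapply(gidx, function(ix) {
    Cg <- Cfull[sp[ix], sp[ix], drop = FALSE]
    e <- eigen((Cg + t(Cg)) / 2, symmetric = TRUE)
    e$values <- pmax(e$values, 1e-10)
    e
  })

  # state
  st <- start %||% list()
  b <- st$b %||% numeric(p)
  A <- st$A %||% matrix(0, n, k)            # phylo effects, species x trait
  Eta <- st$Eta %||% A                      # PX working effects
  alpha <- st$alpha %||% lapply(glev, function(g) rep(1, k))
  G <- st$G %||% lapply(glev, function(g) pg$V)
  Geta <- st$Geta %||% G                    # PX working covariances
  R <- st$R %||% lapply(glev, function(g) pr$V)
  M <- st$M %||% matrix(0, n, k)            # mev latents
  Yc <- Y
  Yc[!obs] <- (st$Ymis %||% matrix(rep(colMeans(Y, na.rm = TRUE),
                                       each = n), n, k))[!obs]

  keep <- seq(burnin + thin, nitt, by = thin)
  nS <- length(keep)
  out_b <- matrix(NA_real_, nS, p, dimnames = list(NULL, colnames(X)))
  out_G <- lapply(glev, function(g) array(NA_real_, c(k, k, nS),
                                          dimnames = list(resp, resp, NULL)))
  out_R <- lapply(glev, function(g) array(NA_real_, c(k, k, nS)))
  out_A <- lapply(glev, function(g) array(NA_real_, c(length(gidx[[
    match(g, glev)]]), k, nS)))
  out_Ymis <- if (any(!obs)) matrix(NA_real_, nS, sum(!obs)) else NULL
  names(out_G) <- names(out_R) <- names(out_A) <- glev

  has_mev <- any(Vme > 0)
  mis_rows <- which(rowSums(!obs) > 0L)
  mev_rows <- which(rowSums(Vme > 0) > 0L)
  s_out <- 0L

  for (iter in seq_len(nitt)) {
    Mu <- matrix(X %*% b, n, k) + A
    # --- augment missing responses (per-trait Gibbs scan, vectorised) ---
    if (length(mis_rows)) {
      for (g in seq_along(glev)) {
        Rg <- R[[g]]
        Rinv <- solve(Rg)
        ing <- as.integer(grp) == g
        Ec <- Yc - Mu - M                    # current residuals
        for (t in seq_len(k)) {
          rows <- which(!obs[, t] & ing)
          if (!length(rows)) next
          # e_it | e_i,-t ~ N(-sum_u Rinv[t,u] e_iu / Rinv[t,t] + e_it, 1/Rinv[t,t])
          cv <- 1 / Rinv[t, t]
          cm <- -(Ec[rows, , drop = FALSE] %*% Rinv[, t] -
                    Ec[rows, t] * Rinv[t, t]) * cv
          e_new <- stats::rnorm(length(rows), cm, sqrt(cv))
          Ec[rows, t] <- e_new
          Yc[rows, t] <- Mu[rows, t] + M[rows, t] + e_new
        }
      }
    }
    # --- measurement-error latents (per-trait Gibbs scan, vectorised) ---
    if (has_mev) {
      for (g in seq_along(glev)) {
        Rinv <- solve(R[[g]])
        ing <- as.integer(grp) == g
        Rm <- Yc - Mu                         # residual incl. mev latent
        for (t in seq_len(k)) {
          rows <- which(Vme[, t] > 0 & ing)
          if (!length(rows)) next
          # m_it | m_i,-t, r_i: precision 1/v + Rinv[t,t]
          prec <- 1 / Vme[rows, t] + Rinv[t, t]
          num <- (Rm[rows, , drop = FALSE] - M[rows, , drop = FALSE]) %*%
            Rinv[, t] + M[rows, t] * Rinv[t, t]
          M[rows, t] <- stats::rnorm(length(rows), num / prec, sqrt(1 / prec))
        }
      }
    }
    # --- fixed effects ---
    Ystar <- Yc - A - M
    Rinvs <- lapply(R, solve)
    cond <- fixef_conditional(
      Xg = lapply(gidx, function(ix)
        X[as.vector(outer(ix, (seq_len(k) - 1L) * n, "+")), , drop = FALSE]),
      Yg = lapply(gidx, function(ix) Ystar[ix, , drop = FALSE]),
      Rinvg = Rinvs)
    b <- draw_mvn_from_cond(cond)
    XB <- matrix(X %*% b, n, k)
    # --- phylogenetic effects (eigen decomposition of the tree covariance) ---
    if (phylo) {
      for (g in seq_along(glev)) {
        ix <- gidx[[g]]
        U <- eig[[g]]$vectors; d <- eig[[g]]$values
        Da <- if (px) diag(alpha[[g]], k) else diag(1, k)
        Resid <- Yc[ix, , drop = FALSE] - XB[ix, , drop = FALSE] -
          M[ix, , drop = FALSE]
        Yt <- crossprod(U, Resid)                     # n_g x k
        Rinv <- Rinvs[[g]]
        DRD <- Da %*% Rinv %*% Da
        DRy <- Yt %*% Rinv %*% Da                     # rows: (Da Rinv y~_s)
        Ginv <- solve(if (px) Geta[[g]] else G[[g]])
        ng <- length(ix)
        if (k == 1L) {
          prec <- DRD[1L, 1L] + Ginv[1L, 1L] / d
          Et <- matrix(DRy[, 1L] / prec + stats::rnorm(ng) / sqrt(prec),
                       ng, 1L)
        } else {
          # joint diagonalisation: DRD = V^-T V^-1, Ginv = V^-T Lam V^-1,
          # so each eigencomponent solve becomes a diagonal scaling
          L <- chol((DRD + t(DRD)) / 2 + diag(1e-10, k))
          W <- backsolve(L, t(backsolve(L, t(Ginv), transpose = TRUE)),
                         transpose = TRUE)
          ew <- eigen((W + t(W)) / 2, symmetric = TRUE)
          V <- backsolve(L, ew$vectors)
          lam <- pmax(ew$values, 0)
          Sc <- 1 / (1 + outer(1 / d, lam))        # n_g x k
          Tm <- DRy %*% V
          Et <- (Tm * Sc + sqrt(Sc) * matrix(stats::rnorm(ng * k),
                                             ng, k)) %*% t(V)
        }
        EtaG <- U %*% Et
        Eta[ix, ] <- EtaG
        A[ix, ] <- EtaG %*% Da
        # --- G update (inverse Wishart) on the working scale ---
        # S = sum_s eta~_s eta~_s' / d_s  (eigen-basis quadratic form = Eta' C^-1 Eta)
        S <- crossprod(Et * (1 / sqrt(d)))
        Gnew <- riwish(pg$nu + length(ix), pg$V * pg$nu + S)
        if (px) {
          Geta[[g]] <- Gnew
          # --- working parameters alpha | eta ---
          aV <- if (is.matrix(pg$alpha_V)) pg$alpha_V
          else diag(pg$alpha_V, k)
          Resid2 <- Yc[ix, , drop = FALSE] - XB[ix, , drop = FALSE] -
            M[ix, , drop = FALSE]
          Pa <- solve(aV) + Rinv * crossprod(EtaG)
          ra <- solve(aV, pg$alpha_mu) +
            colSums(EtaG * (Resid2 %*% Rinv))
          cpa <- chol((Pa + t(Pa)) / 2)
          am <- backsolve(cpa, forwardsolve(t(cpa), ra))
          alpha[[g]] <- as.vector(am + backsolve(cpa, stats::rnorm(k)))
          Da <- diag(alpha[[g]], k)
          A[ix, ] <- EtaG %*% Da
          G[[g]] <- Da %*% Gnew %*% Da
        } else {
          G[[g]] <- Gnew
        }
      }
    }
    # --- residual covariance ---
    E <- Yc - XB - A - M
    for (g in seq_along(glev)) {
      ix <- gidx[[g]]
      SS <- crossprod(E[ix, , drop = FALSE])
      R[[g]] <- riwish(pr$nu + length(ix), pr$V * pr$nu + SS)
    }
    # --- store ---
    if (iter >= burnin + thin && (iter - burnin) %% thin == 0L) {
      s_out <- s_out + 1L
      out_b[s_out, ] <- b
      for (g in seq_along(glev)) {
        out_G[[g]][, , s_out] <- G[[g]]
        out_R[[g]][, , s_out] <- R[[g]]
        out_A[[g]][, , s_out] <- A[gidx[[g]], , drop = FALSE]
      }
      if (!is.null(out_Ymis)) out_Ymis[s_out, ] <- Yc[!obs]
    }
    if (verbose && iter %% 1000L == 0L)
      message("iteration ", iter, "/", nitt)
  }

  final <- list(b = b, A = A, Eta = Eta, alpha = alpha, G = G, Geta = Geta,
                R = R, M = M, Ymis = Yc)
  structure(list(
    samples = list(b = out_b, G = out_G, R = out_R, A = out_A,
                   Ymis = out_Ymis),
    meta = list(path = "traits", responses = resp, traits = resp,
                family = rep("gaussian", k), species = sp,
                species_by_group = lapply(gidx, function(ix) sp[ix]),
                groups = glev, group_of = grp, tree = tree,
                fixed = colnames(X), prior = list(G = pg, R = pr),
                nitt = nitt, burnin = burnin, thin = thin,
                obs = obs, formula = formula),
    data = data,
    final_state = final), class = "bpmm")
}

# ---------------------------------------------------------------------------
# general path: single response, repeated rows, slopes, binomial liabilities
# ---------------------------------------------------------------------------
bpmm_general <- function(formula, data, tree, family, species, slopes,
                         species_effect, mev, prior, nitt, burnin, thin,
                         start, phylo, estimate_binom_resid, verbose) {
  lhs <- formula[[2L]]
  binom <- family == "binomial"
  sp <- as.character(data[[species]])
  usp <- unique(sp)
  n_sp <- length(usp)
  spi <- match(sp, usp)
  N <- nrow(data)

  if (binom) {
    mm <- as.list(lhs)[-1L]
    succ <- eval(mm[[1L]], data)
    fail <- eval(mm[[2L]], data)
    size <- succ + fail
    if (any(size < 1L)) stop("binomial rows need at least one trial")
    y <- rep(NA_real_, N)
  } else {
    y <- eval(lhs, data)
  }
  rhs <- formula[-2L]
  X <- stats::model.matrix(rhs, data)
  p <- ncol(X)

  # phylogenetic random-effect design: intercept + optional slopes
  Zr <- matrix(1, N, 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(slopes)) {
    Zs <- stats::model.matrix(slopes, data)
    Zs <- Zs[, setdiff(colnames(Zs), "(Intercept)"), drop = FALSE]
    Zr <- cbind(Zr, Zs)
  }
  q <- ncol(Zr)
  terms <- colnames(Zr)

  vme <- rep(0, N)
  if (!is.null(mev)) {
    vme <- data[[mev]]
    vme[is.na(vme)] <- 0
  }

  pg <- prior$G %||% default_prior(q)
  pr <- prior$R %||% prior_block(1, 0.002)
  pu <- prior$species %||% prior_block(1, 0.002)

  C <- phylo_covariance(tree, tree$tip.label)
  C <- C / mean(diag(C))
  Cg <- C[usp, usp, drop = FALSE]
  Cinv <- solve((Cg + t(Cg)) / 2)

  # dense random design over vec(a), term-major
  Z <- matrix(0, N, q * n_sp)
  for (t in seq_len(q)) Z[cbind(seq_len(N), (t - 1L) * n_sp + spi)] <- Zr[, t]

  st <- start %||% list()
  b <- st$b %||% numeric(p)
  a <- st$a %||% matrix(0, n_sp, q)         # species x term
  G <- st$G %||% pg$V
  u <- st$u %||% numeric(n_sp)
  sig_u <- st$sig_u %||% 1
  sig_e <- st$sig_e %||% (if (binom) 1 else {
    v0 <- stats::var(y, na.rm = TRUE)
    if (is.finite(v0) && v0 > 0) v0 else 1
  })
  if (binom && !estimate_binom_resid) sig_e <- 1
  mlat <- st$mlat %||% rep(0, N)
  obs <- !is.na(y)
  l <- st$l %||% if (binom)
    stats::qlogis((succ + 0.5) / (size + 1)) else ifelse(obs, y, mean(y, na.rm = TRUE))
  prop_sd <- st$prop_sd %||% 1.2
  acc <- 0L; tries <- 0L

  keep <- seq(burnin + thin, nitt, by = thin)
  nS <- length(keep)
  out_b <- matrix(NA_real_, nS, p, dimnames = list(NULL, colnames(X)))
  out_G <- array(NA_real_, c(q, q, nS), dimnames = list(terms, terms, NULL))
  out_R <- array(NA_real_, c(1L, 1L, nS))
  out_A <- array(NA_real_, c(n_sp, q, nS), dimnames = list(usp, terms, NULL))
  out_u <- if (species_effect) matrix(NA_real_, nS, n_sp) else NULL
  out_su <- if (species_effect) numeric(nS) else NULL
  s_out <- 0L

  GinvK <- function(G) kronecker(solve(G), Cinv)
  ZtZ <- crossprod(Z)

  for (iter in seq_len(nitt)) {
    eta <- as.vector(X %*% b + Z %*% as.vector(a)) +
      (if (species_effect) u[spi] else 0) + mlat
    # --- latent responses ---
    if (binom) {
      lp <- stats::rnorm(N, l, prop_sd)
      logr <- stats::dnorm(lp, eta, sqrt(sig_e), log = TRUE) -
        stats::dnorm(l, eta, sqrt(sig_e), log = TRUE) +
        stats::dbinom(succ, size, stats::plogis(lp), log = TRUE) -
        stats::dbinom(succ, size, stats::plogis(l), log = TRUE)
      take <- log(stats::runif(N)) < logr
      l[take] <- lp[take]
      acc <- acc + sum(take); tries <- tries + N
      if (iter <= burnin && iter %% 100L == 0L) {
        rate <- acc / tries
        prop_sd <- prop_sd * exp(rate - 0.44)
        acc <- 0L; tries <- 0L
      }
    } else {
      l[!obs] <- stats::rnorm(sum(!obs), eta[!obs], sqrt(sig_e))
      l[obs] <- y[obs]
      # mev latents: scalar conditional per datum
      has <- vme > 0 & obs
      if (any(has)) {
        r <- l[has] - (eta[has] - mlat[has])
        prec <- 1 / vme[has] + 1 / sig_e
        mlat[has] <- stats::rnorm(sum(has), (r / sig_e) / prec, sqrt(1 / prec))
      }
    }
    # --- fixed effects (weighted normal draw, flat prior) ---
    resid_f <- l - as.vector(Z %*% as.vector(a)) -
      (if (species_effect) u[spi] else 0) - mlat
    P <- crossprod(X) / sig_e + diag(1e-8, p)
    cp <- chol((P + t(P)) / 2)
    mb <- backsolve(cp, forwardsolve(t(cp), crossprod(X, resid_f) / sig_e))
    b <- as.vector(mb + backsolve(cp, stats::rnorm(p)))
    # --- phylogenetic effects ---
    if (phylo) {
      resid_a <- l - as.vector(X %*% b) -
        (if (species_effect) u[spi] else 0) - mlat
      P <- ZtZ / sig_e + GinvK(G)
      cp <- chol((P + t(P)) / 2)
      ma <- backsolve(cp, forwardsolve(t(cp), crossprod(Z, resid_a) / sig_e))
      avec <- as.vector(ma + backsolve(cp, stats::rnorm(q * n_sp)))
      a <- matrix(avec, n_sp, q)
      S <- t(a) %*% Cinv %*% a
      G <- riwish(pg$nu + n_sp, pg$V * pg$nu + S)
    }
    # --- iid species intercepts ---
    if (species_effect) {
      resid_u <- l - as.vector(X %*% b) - as.vector(Z %*% as.vector(a)) - mlat
      su <- as.vector(tapply(resid_u, factor(spi, levels = seq_len(n_sp)),
                             sum, default = 0))
      ni <- tabulate(spi, n_sp)
      prec <- ni / sig_e + 1 / sig_u
      u <- stats::rnorm(n_sp, (su / sig_e) / prec, sqrt(1 / prec))
      sig_u <- riwish(pu$nu + n_sp,
                      as.matrix(pu$V * pu$nu + sum(u^2)))[1L, 1L]
    }
    # --- residual variance ---
    e <- l - as.vector(X %*% b) - as.vector(Z %*% as.vector(a)) -
      (if (species_effect) u[spi] else 0) - mlat
    if (!binom || estimate_binom_resid)
      sig_e <- riwish(pr$nu + N, as.matrix(pr$V * pr$nu + sum(e^2)))[1L, 1L]
    # --- store ---
    if (iter >= burnin + thin && (iter - burnin) %% thin == 0L) {
      s_out <- s_out + 1L
      out_b[s_out, ] <- b
      out_G[, , s_out] <- G
      out_R[, , s_out] <- sig_e
      out_A[, , s_out] <- a
      if (species_effect) { out_u[s_out, ] <- u; out_su[s_out] <- sig_u }
    }
    if (verbose && iter %% 1000L == 0L) message("iteration ", iter, "/", nitt)
  }

  final <- list(b = b, a = a, G = G, u = u, sig_u = sig_u, sig_e = sig_e,
                l = l, mlat = mlat, prop_sd = prop_sd)
  structure(list(
    samples = list(b = out_b, G = list(all = out_G), R = list(all = out_R),
                   A = list(all = out_A), u = out_u, sigma_u = out_su),
    meta = list(path = "general", responses = if (binom)
      paste(deparse(lhs), collapse = "") else deparse(lhs),
      traits = terms, family = family, species = usp,
      species_of_row = sp, groups = "all", tree = tree,
      fixed = colnames(X), prior = list(G = pg, R = pr),
      nitt = nitt, burnin = burnin, thin = thin,
      species_effect = species_effect, formula = formula,
      slopes = slopes),
    data = data,
    final_state = final), class = "bpmm")
}
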