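#' Highest-posterior-density interval
#'
#' Shortest interval containing `prob` of the sample (empirical HPD: the
#' narrowest window over the sorted draws).
#'
#' @param x numeric vector of posterior draws.
#' @param prob interval mass.
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) return(c(x[1L], x[1L]))
  m <- max(1L, min(n - 1L, floor(prob * n)))
  w <- x[(m + 1L):n] - x[seq_len(n - m)]
  i <- which.min(w)
  c(x[i], x[i + m])
}

#' Posterior mode via Gaussian kernel density
#'
#' @param x numeric draws; Silverman bandwidth.
#' @return scalar mode estimate.
#' @export
posterior_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) == 1L) return(x[1L])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' pMCMC: minority tail mass around a reference value
#'
#' The number of draws above or below the reference (whichever is smaller)
#' divided by the total: the single-tail convention. (The doubled two-tail
#' convention is available via `doubled = TRUE`.)
#'
#' @param x numeric draws.
#' @param ref reference value (default 0).
#' @param doubled double the minority tail.
#' @return scalar in `[0, 1]` (`[0, 1]` even when doubled, capped at 1).
#' @export
pmcmc <- function(x, ref = 0, doubled = FALSE) {
  p <- min(mean(x > ref), mean(x < ref))
  if (doubled) p <- min(1, 2 * p)
  p
}

#' Posterior summary: mode, HPD interval, pMCMC
#'
#' @param x numeric vector of posterior draws (>= 100).
#' @param ref reference for pMCMC.
#' @param prob HPD mass.
#' @return list of class `"bpmm_summary_stat"`: `mode`, `ci`, `pmcmc`, `n`.
#' @export
posterior_summary <- function(x, ref = 0, prob = 0.95) {
  stopifnot(length(x) >= 100)
  structure(list(mode = posterior_mode(x), ci = hpd_interval(x, prob),
                 pmcmc = pmcmc(x, ref), n = length(x)),
            class = "bpmm_summary_stat")
}

#' @export
print.bpmm_summary_stat <- function(x, ...) {
  cat(sprintf("PM = %.3f, CI: %.3f, %.3f, pMCMC = %.3g (n = %d)\n",
              x$mode, x$ci[1L], x$ci[2L], x$pmcmc, x$n))
  invisible(x)
}

#' Phylogenetic heritability of a response
#'
#' Per posterior draw, the phylogenetic variance of a trait divided by the
#' total random-effect variance (`H^2 = V_phylo / (V_phylo + V_species +
#' V_resid)`; the species term only exists when it was modelled).
#'
#' @param fit a `"bpmm"`.
#' @param response trait name (defaults to the first).
#' @param group group level when covariance blocks are split.
#' @return list: `draws` (per-sample H^2) and `summary`
#'   ([posterior_summary()]).
#' @export
phylo_heritability <- function(fit, response = fit$meta$traits[1L],
                               group = fit$meta$groups[1L]) {
  t <- match(response, fit$meta$traits)
  if (is.na(t)) stop("unknown response: ", response)
  G <- fit$samples$G[[group]]
  R <- fit$samples$R[[group]]
  vph <- G[t, t, ]
  vre <- if (fit$meta$path == "traits") R[t, t, ] else R[1L, 1L, ]
  vsp <- if (!is.null(fit$samples$sigma_u)) fit$samples$sigma_u else 0
  h2 <- vph / (vph + vsp + vre)
  list(draws = h2, summary = posterior_summary(h2))
}

#' Phylogenetic or residual correlation between two responses
#'
#' @param fit a `"bpmm"` multi-response fit.
#' @param pair character vector of two trait names.
#' @param level `"phylogenetic"` or `"residual"`.
#' @param group group level when blocks are split.
#' @return list: `draws` (per-sample correlation) and `summary`.
#' @export
phylo_correlation <- function(fit, pair, level = c("phylogenetic", "residual"),
                              group = fit$meta$groups[1L]) {
  level <- match.arg(level)
  idx <- match(pair, fit$meta$traits)
  if (anyNA(idx)) stop("unknown trait in pair")
  M <- if (level == "phylogenetic") fit$samples$G[[group]]
  else fit$samples$R[[group]]
  r <- M[idx[1L], idx[2L], ] /
    sqrt(M[idx[1L], idx[1L], ] * M[idx[2L], idx[2L], ])
  list(draws = r, summary = posterior_summary(r))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within variance ratio for one scalar parameter traced by
#' two or more equal-length chains: with chain means spread B/n and mean
#' within-chain variance W, `PSRF = sqrt(((n-1)/n W + B/n (1 + 1/m)) / W)`.
#'
#' @param chains list of numeric vectors (>= 2, equal lengths), or a matrix
#'   with one chain per column.
#' @return scalar PSRF.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2L)
  m <- length(chains)
  if (m < 2L) stop("need at least two chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal lengths")
  means <- vapply(chains, mean, numeric(1L))
  W <- mean(vapply(chains, stats::var, numeric(1L)))
  B_over_n <- stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B_over_n * (1 + 1 / m)) / W)
}

#' Lag-k sample autocorrelation of a thinned chain
#'
#' @param x numeric chain.
#' @param lag integer lag (< length).
#' @return scalar autocorrelation; `NA` with a warning for constant chains.
#' @export
chain_autocorrelation <- function(x, lag = 1L) {
  stopifnot(lag < length(x))
  if (stats::var(x) == 0) {
    warning("constant chain: autocorrelation undefined")
    return(NA_real_)
  }
  stats::acf(x, lag.max = lag, plot = FALSE)$acf[lag + 1L]
}

#' @export
print.bpmm <- function(x, ...) {
  m <- x$meta
  cat("Bayesian phylogenetic mixed model (", m$path, " design)\n", sep = "")
  cat("  responses:", paste(m$responses, collapse = ", "),
      " [", paste(unique(m$family), collapse = "/"), "]\n")
  cat("  species:", length(m$species), "  samples:",
      nrow(x$samples$b), "(nitt", m$nitt, ", burn-in", m$burnin,
      ", thin", m$thin, ")\n")
  invisible(x)
}

#' @export
summary.bpmm <- function(object, ...) {
  b <- object$samples$b
  fx <- t(apply(b, 2L, function(col) {
    s <- posterior_summary(col)
    c(post.mode = s$mode, `l-95% CI` = s$ci[1L], `u-95% CI` = s$ci[2L],
      pMCMC = s$pmcmc)
  }))
  vc <- lapply(object$meta$groups, function(g) {
    G <- object$samples$G[[g]]; R <- object$samples$R[[g]]
    k <- dim(G)[1L]
    data.frame(
      term = object$meta$traits,
      phylo.var = vapply(seq_len(k), function(t) posterior_mode(G[t, t, ]),
                         numeric(1L)),
      resid.var = vapply(seq_len(k), function(t)
        posterior_mode(R[min(t, dim(R)[1L]), min(t, dim(R)[1L]), ]),
        numeric(1L)))
  })
  names(vc) <- object$meta$groups
  out <- list(fixed = fx, vcv = vc, meta = object$meta)
  class(out) <- "summary.bpmm"
  out
}

#' @export
print.summary.bpmm <- function(x, ...) {
  cat("Fixed effects (posterior mode, 95% HPD, pMCMC):\n")
  print(round(x$fixed, 4))
  for (g in names(x$vcv)) {
    cat("\nVariance components",
        if (length(x$vcv) > 1L) paste0("[", g, "]"), ":\n")
    print(x$vcv[[g]], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.bpmm <- function(object, ...) colMeans(object$samples$b)

#' @export
plot.bpmm <- function(x, parameters = colnames(x$samples$b), ...) {
  b <- x$samples$b
  parameters <- intersect(parameters, colnames(b))
  op <- graphics::par(mfrow = c(length(parameters), 1L),
                      mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (pm in parameters)
    graphics::plot(b[, pm], type = "l", ylab = pm, xlab = "", ...)
  invisible(x)
}

#' @export
predict.bpmm <- function(object, ...) {
  m <- object$meta
  b <- colMeans(object$samples$b)
  if (m$path == "traits") {
    n <- length(m$species); k <- length(m$traits)
    Amean <- matrix(0, n, k)
    for (g in m$groups) {
      ix <- which(m$group_of == g)
      Amean[ix, ] <- apply(object$samples$A[[g]], c(1L, 2L), mean)
    }
    long <- object$data[rep(seq_len(n), k), , drop = FALSE]
    long$trait <- factor(rep(m$traits, each = n), levels = m$traits)
    rhs <- m$formula[-2L]
    if (identical(deparse(rhs[[2L]]), "1") && k > 1L) rhs <- ~ 0 + trait
    X <- stats::model.matrix(rhs, long)
    eta <- matrix(X %*% b, n, k) + Amean
    dimnames(eta) <- list(m$species, m$traits)
    eta
  } else {
    stop("predict is implemented for the multi-response trait design; ",
         "use derive_topt()/predicted_success_at() for hatching models")
  }
}

#' @export
residuals.bpmm <- function(object, ...) {
  if (object$meta$path != "traits")
    stop("residuals are defined for the trait design")
  Y <- as.matrix(object$data[, object$meta$traits, drop = FALSE])
  Y - predict(object)
}
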