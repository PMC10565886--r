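#' Fit the phylogenetic quadratic hatching-success model
#'
#' Binomial (logit) mixed model of hatched/set counts on incubation
#' temperature with fixed linear and quadratic temperature effects and
#' phylogenetic random intercepts and slopes for both terms, their 3x3
#' covariance unstructured so curvature and slope can covary across the tree.
#' Temperature is centred at the grand mean and scaled by its SD inside the
#' sampler (decorrelating the linear and quadratic columns); every reported
#' quantity is back-transformed to degrees C.
#'
#' @param records data frame: `species`, `temperature` (degrees C), `n_eggs`,
#'   `n_hatched` (and anything else, ignored). Every species must have >= 3
#'   distinct temperatures.
#' @param tree `"phylo"` covering the species.
#' @param prior optional prior list (see [bpmm()]).
#' @param nitt,burnin,thin MCMC settings.
#' @param seed integer seed.
#' @param ... further arguments to [bpmm()].
#' @return a `"bpmm"` with `meta$temp_scaling = c(center, scale)`.
#' @export
fit_hatching_model <- function(records, tree, prior = NULL,
                               nitt = 13000L, burnin = 3000L, thin = 10L,
                               seed = NULL, ...) {
  need <- c("species", "temperature", "n_eggs", "n_hatched")
  stopifnot(all(need %in% names(records)))
  ntemp <- tapply(records$temperature, records$species,
                  function(x) length(unique(x)))
  bad <- names(ntemp)[ntemp < 3L]
  if (length(bad))
    stop("species with fewer than 3 distinct temperatures: ",
         paste(bad, collapse = ", "))
  ctr <- mean(records$temperature)
  scl <- stats::sd(records$temperature)
  if (scl == 0) stop("no temperature variation")
  d <- records
  d$temp_s <- (d$temperature - ctr) / scl
  d$n_fail <- d$n_eggs - d$n_hatched
  if (any(d$n_fail < 0)) stop("n_hatched exceeds n_eggs")
  fit <- bpmm(cbind(n_hatched, n_fail) ~ temp_s + I(temp_s^2),
              data = d, tree = tree, family = "binomial",
              slopes = ~ temp_s + I(temp_s^2), prior = prior,
              nitt = nitt, burnin = burnin, thin = thin, seed = seed, ...)
  fit$meta$temp_scaling <- c(center = ctr, scale = scl)
  fit
}

# per-draw total (fixed + species) coefficients on the scaled-temperature scale
topt_coefs <- function(fit, species) {
  if (is.null(fit$meta$temp_scaling))
    stop("fit was not produced by fit_hatching_model()")
  i <- match(species, fit$meta$species)
  if (is.na(i)) stop("species not in fit: ", species)
  b <- fit$samples$b
  A <- fit$samples$A[[1L]]
  cols <- c("(Intercept)", "temp_s", "I(temp_s^2)")
  if (!all(cols %in% colnames(b))) stop("unexpected fixed-effect names")
  list(u = b[, "(Intercept)"] + A[i, 1L, ],
       beta = b[, "temp_s"] + A[i, 2L, ],
       gamma = b[, "I(temp_s^2)"] + A[i, 3L, ])
}

#' Derive a species' embryonic thermal optimum from a hatching-model chain
#'
#' Per posterior draw the vertex of the species' latent quadratic,
#' `T_opt = -(beta_f + beta_sp) / (2 (gamma_f + gamma_sp))`, back-transformed
#' to degrees C. Draws with non-negative total curvature have no interior
#' optimum and are excluded and counted; the estimate is only usable
#' (`concave = TRUE`) when at least 95% of draws are concave.
#'
#' @param fit hatching-model `"bpmm"` from [fit_hatching_model()].
#' @param species species label.
#' @param min_concave concavity threshold (default 0.95).
#' @return list: `species`, `draws` (retained T_opt draws, degrees C),
#'   `estimate` (posterior mean), `vi` (their variance), `concave` (flag),
#'   `prop_concave`.
#' @export
derive_topt <- function(fit, species, min_concave = 0.95) {
  cf <- topt_coefs(fit, species)
  ok <- cf$gamma < 0
  prop <- mean(ok)
  sc <- fit$meta$temp_scaling
  draws <- sc["center"] + sc["scale"] *
    (-cf$beta[ok] / (2 * cf$gamma[ok]))
  names(draws) <- NULL
  concave <- prop >= min_concave
  list(species = species, draws = draws,
       estimate = if (concave) mean(draws) else NA_real_,
       vi = if (concave) stats::var(draws) else NA_real_,
       concave = concave, prop_concave = prop)
}

#' T_opt table for every species in a hatching-model fit
#'
#' @inheritParams derive_topt
#' @return data frame: `species`, `topt`, `vi`, `concave`, `prop_concave`,
#'   `n_temperatures`. Non-concave species carry `NA` estimates.
#' @export
topt_table <- function(fit, min_concave = 0.95) {
  recs <- fit$data
  ntemp <- tapply(recs$temperature, recs$species,
                  function(x) length(unique(x)))
  out <- do.call(rbind, lapply(fit$meta$species, function(s) {
    tp <- derive_topt(fit, s, min_concave)
    data.frame(species = s, topt = tp$estimate, vi = tp$vi,
               concave = tp$concave, prop_concave = tp$prop_concave,
               n_temperatures = as.integer(ntemp[[s]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Posterior hatching probability at a temperature
#'
#' Inverse-logit of the species' latent quadratic evaluated per posterior draw
#' at the given temperature (degrees C).
#'
#' @param fit hatching-model `"bpmm"`.
#' @param species species label.
#' @param temperature degrees C (scalar).
#' @return numeric vector of per-draw probabilities.
#' @export
predicted_success_at <- function(fit, species, temperature) {
  cf <- topt_coefs(fit, species)
  sc <- fit$meta$temp_scaling
  ts <- (temperature - sc["center"]) / sc["scale"]
  unname(stats::plogis(cf$u + cf$beta * ts + cf$gamma * ts^2))
}
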