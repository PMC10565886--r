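#' Hedges' g with heteroscedastic variances (SMDH)
#'
#' Standardized mean difference between gravid and non-gravid preferred body
#' temperature, without assuming equal population variances (Bonett 2008
#' convention). Writing `s*^2 = (sd_g^2 + sd_ng^2)/2` (the unweighted average of
#' the two group variances, not the df-weighted pooled variance) and
#' `m = n_g + n_ng - 2`:
#'
#'   d  = (mean_g - mean_ng) / s*
#'   J  = Gamma(m/2) / ( sqrt(m/2) * Gamma((m-1)/2) )   (exact small-sample factor;
#'                                                       ~ 1 - 3/(4m - 1))
#'   g  = J * d
#'   var(g) = g^2 (sd_g^4/(n_g-1) + sd_ng^4/(n_ng-1)) / (8 s*^4)
#'            + (sd_g^2/(n_g-1) + sd_ng^2/(n_ng-1)) / s*^2
#'
#' Positive g means gravid females run warmer than non-gravid females.
#'
#' @param records data frame with columns `species`, `mean_g`, `sd_g`, `n_g`,
#'   `mean_ng`, `sd_ng`, `n_ng`, and optionally `study_type`.
#' @return data frame: `species`, `g`, `vi` (sampling variance), `study_type`.
#' @export
hedges_g <- function(records) {
  need <- c("species", "mean_g", "sd_g", "n_g", "mean_ng", "sd_ng", "n_ng")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  with(records, {
    if (any(n_g < 2 | n_ng < 2)) stop("group sample sizes must be >= 2")
    if (any(sd_g < 0 | sd_ng < 0)) stop("negative SD")
    if (any(sd_g == 0 & sd_ng == 0))
      stop("zero SD in both groups: standardized difference undefined")
    s2 <- (sd_g^2 + sd_ng^2) / 2
    m <- n_g + n_ng - 2
    J <- exp(lgamma(m / 2) - log(sqrt(m / 2)) - lgamma((m - 1) / 2))
    g <- J * (mean_g - mean_ng) / sqrt(s2)
    vi <- g^2 * (sd_g^4 / (n_g - 1) + sd_ng^4 / (n_ng - 1)) / (8 * s2^2) +
      (sd_g^2 / (n_g - 1) + sd_ng^2 / (n_ng - 1)) / s2
    data.frame(species = species, g = g, vi = vi,
               study_type = if ("study_type" %in% names(records))
                 records$study_type else NA_character_,
               stringsAsFactors = FALSE)
  })
}

#' Pool per-study effect sizes into one effect per species
#'
#' Fixed-effect inverse-variance pooling: `g = sum(g_i/v_i) / sum(1/v_i)`,
#' `v = 1 / sum(1/v_i)`. A species with a single study passes through
#' unchanged. When studies of both types are pooled the study type of the
#' pooled record is `"mixed"`.
#'
#' @param effects data frame as returned by [hedges_g()].
#' @return data frame with one row per species: `species`, `g`, `vi`,
#'   `study_type`, `n_studies`.
#' @export
pool_effects <- function(effects) {
  stopifnot(nrow(effects) >= 1)
  out <- lapply(split(effects, effects$species), function(d) {
    w <- 1 / d$vi
    st <- unique(d$study_type)
    data.frame(species = d$species[1L],
               g = sum(w * d$g) / sum(w),
               vi = 1 / sum(w),
               study_type = if (length(st) == 1L) st else "mixed",
               n_studies = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
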